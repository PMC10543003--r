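#' Read a protein intensity table
#'
#' Two dialects are supported. `"generic"`: a TSV whose first column holds
#' protein ids and whose remaining columns are numeric sample intensities.
#' `"proteinGroups"`: a MaxQuant-style proteinGroups export, from which the
#' `Majority protein IDs`, `LFQ intensity <sample>` and `Unique peptides`
#' columns are taken. Contaminant and reverse-decoy rows (ids prefixed
#' `CON__` / `REV__`) are dropped with a message.
#'
#' @param path file path.
#' @param dialect `"generic"` (default) or `"proteinGroups"`.
#' @return list with `abundance` (numeric matrix, proteins x samples),
#'   `uniquePeptides` (named integer vector or `NULL`), `dropped`
#'   (contaminant/decoy ids removed) and `state` (from a `<path>.json`
#'   sidecar if present, else `"raw"`).
#' @export
readIntensityTable <- function(path, dialect = c("generic", "proteinGroups")) {
  dialect <- match.arg(dialect)
  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (dialect == "proteinGroups") {
    idCol <- "Majority protein IDs"
    stopIfNot(idCol %in% colnames(tab),
              "proteinGroups file must have a 'Majority protein IDs' column")
    valCols <- grep("^LFQ intensity ", colnames(tab), value = TRUE)
    stopIfNot(length(valCols) > 0, "no 'LFQ intensity <sample>' columns found")
    ids <- tab[[idCol]]
    up <- if ("Unique peptides" %in% colnames(tab))
      suppressWarnings(as.integer(tab[["Unique peptides"]])) else NULL
    sampleIds <- sub("^LFQ intensity ", "", valCols)
  } else {
    ids <- tab[[1]]
    valCols <- colnames(tab)[-1]
    sampleIds <- valCols
    up <- NULL
  }
  dup <- unique(ids[duplicated(ids)])
  stopIfNot(length(dup) == 0,
            paste0("duplicate protein id(s): ", paste(dup, collapse = ", ")))
  contaminant <- grepl("^(CON__|REV__)", ids)
  if (any(contaminant))
    message(sum(contaminant), " contaminant/decoy row(s) dropped")
  m <- matrix(NA_real_, sum(!contaminant), length(valCols),
              dimnames = list(ids[!contaminant], sampleIds))
  keepRows <- which(!contaminant)
  for (j in seq_along(valCols)) {
    raw <- tab[[valCols[j]]][keepRows]
    empty <- is.na(raw) | raw == "" | raw == "NA"
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !empty)
    if (length(bad))
      stop("non-numeric value '", raw[bad[1]], "' at row '",
           rownames(m)[bad[1]], "', column '", valCols[j], "'",
           call. = FALSE)
    m[, j] <- num
  }
  state <- "raw"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- fromJSON(sidecar)
    if (!is.null(meta$state)) state <- meta$state
  }
  if (!is.null(up)) up <- setNames(up, ids)[rownames(m)]
  list(abundance = m, uniquePeptides = up,
       dropped = ids[contaminant], state = state)
}

#' Write a protein intensity table with a state sidecar
#'
#' Writes the matrix as TSV (`protein` first column) plus a `<path>.json`
#' sidecar recording the processing state, so tables round-trip through
#' [readIntensityTable()] with their state intact.
#'
#' @param x an [AbundanceExperiment] or numeric matrix.
#' @param path output TSV path.
#' @param state processing state recorded in the sidecar (defaults to the
#'   experiment's state).
#' @return `path`, invisibly.
#' @export
writeIntensityTable <- function(x, path, state = NULL) {
  if (is(x, "AbundanceExperiment")) {
    state <- state %||% abundanceState(x)
    x <- abundanceValues(x)
  }
  df <- data.frame(protein = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_json(list(state = state %||% "raw"), paste0(path, ".json"),
             auto_unbox = TRUE)
  invisible(path)
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample`, `batch`, `timePoint`, `phase`
#'   and optionally `replicate`.
#' @return data.frame with samples as rownames.
#' @export
readSampleMetadata <- function(path) {
  tab <- read.delim(path, colClasses = "character")
  stopIfNot(all(c("sample", "batch", "timePoint", "phase") %in%
                  colnames(tab)),
            "metadata needs columns sample, batch, timePoint, phase")
  if ("replicate" %in% colnames(tab))
    tab$replicate <- as.integer(tab$replicate)
  rownames(tab) <- tab$sample
  tab$sample <- NULL
  tab
}

#' Write sample metadata
#'
#' @param x an [AbundanceExperiment] or data.frame with sample rownames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeSampleMetadata <- function(x, path) {
  cd <- if (is(x, "AbundanceExperiment")) as.data.frame(colData(x)) else x
  df <- data.frame(sample = rownames(cd), cd, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble an AbundanceExperiment from files
#'
#' @param intensityPath intensity TSV (see [readIntensityTable()]).
#' @param metadataPath sample-metadata TSV (see [readSampleMetadata()]).
#' @param dialect passed to [readIntensityTable()].
#' @return An [AbundanceExperiment].
#' @export
loadExperiment <- function(intensityPath, metadataPath,
                           dialect = c("generic", "proteinGroups")) {
  tab <- readIntensityTable(intensityPath, dialect)
  cd <- readSampleMetadata(metadataPath)
  stopIfNot(all(colnames(tab$abundance) %in% rownames(cd)),
            "metadata must cover all samples in the intensity table")
  AbundanceExperiment(tab$abundance, cd[colnames(tab$abundance), ],
                      state = tab$state, uniquePeptides = tab$uniquePeptides)
}
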