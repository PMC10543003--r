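#' Container classes
#'
#' `fermprot` stores protein-by-sample quantifications in an
#' `AbundanceExperiment`, a thin extension of
#' [SummarizedExperiment::SummarizedExperiment] that carries a processing
#' `state` tag recording which normalisation stage the values represent.
#' Sample annotation (batch, time point, fermentation phase, replicate) lives
#' in `colData`; per-protein metadata such as unique-peptide counts lives in
#' `rowData`.
#'
#' @name AbundanceExperiment-class
#' @aliases AbundanceExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowData<- colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @exportClass AbundanceExperiment
NULL

ABUNDANCE_STATES <- c("raw", "ppm", "replicate_summed", "log2_centered",
                      "row_mean_normalized")

setClass("AbundanceExperiment",
         contains = "SummarizedExperiment")

setValidity("AbundanceExperiment", function(object) {
  msg <- character()
  st <- metadata(object)$state
  if (is.null(st) || length(st) != 1L || !st %in% ABUNDANCE_STATES)
    msg <- c(msg, paste0("metadata(x)$state must be one of: ",
                         paste(ABUNDANCE_STATES, collapse = ", ")))
  if (!"abundance" %in% names(assays(object)))
    msg <- c(msg, "assay 'abundance' is required")
  else {
    a <- assay(object, "abundance")
    if (!is.numeric(a))
      msg <- c(msg, "abundance values must be numeric")
    else if (!is.null(st) && isTRUE(st %in% c("raw", "ppm", "replicate_summed")) &&
             any(a < 0, na.rm = TRUE))
      msg <- c(msg, paste0("state '", st, "' requires non-negative values"))
  }
  required <- c("batch", "timePoint", "phase")
  missing <- setdiff(required, colnames(colData(object)))
  if (length(missing))
    msg <- c(msg, paste0("colData is missing column(s): ",
                         paste(missing, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Build an AbundanceExperiment
#'
#' @param abundance numeric matrix, proteins in rows, samples in columns.
#'   Missing values are `NA`, never zero stand-ins.
#' @param colData data.frame (or DataFrame) with one row per sample and at
#'   least columns `batch`, `timePoint`, `phase`; a `replicate` column is
#'   required for per-replicate data.
#' @param state processing-state tag, one of `"raw"`, `"ppm"`,
#'   `"replicate_summed"`, `"log2_centered"`, `"row_mean_normalized"`.
#' @param uniquePeptides optional integer vector (one per protein) of unique
#'   peptide identifications, used by [detectionFilter()].
#' @return An `AbundanceExperiment`.
#' @examples
#' m <- matrix(2^rnorm(12, 20), 3, 4,
#'             dimnames = list(paste0("P", 1:3), paste0("s", 1:4)))
#' cd <- data.frame(batch = "B1", timePoint = rep(c("6h", "24h"), each = 2),
#'                  phase = "fermentation", replicate = rep(1:2, 2))
#' AbundanceExperiment(m, cd)
#' @export
AbundanceExperiment <- function(abundance, colData, state = "raw",
                                uniquePeptides = NULL) {
  if (!is.matrix(abundance)) abundance <- as.matrix(abundance)
  cd <- as(colData, "DataFrame")
  if (is.null(rownames(cd)) || nrow(cd) != ncol(abundance))
    rownames(cd) <- colnames(abundance)
  se <- SummarizedExperiment(assays = list(abundance = abundance),
                             colData = cd)
  metadata(se)$state <- state
  if (!is.null(uniquePeptides))
    rowData(se)$uniquePeptides <- as.integer(uniquePeptides)
  new("AbundanceExperiment", se)
}

#' Processing state of an AbundanceExperiment
#'
#' @param x an `AbundanceExperiment`.
#' @return The state tag (character scalar).
#' @export
abundanceState <- function(x) metadata(x)$state

#' @rdname abundanceState
#' @param value new state tag.
#' @export
`abundanceState<-` <- function(x, value) {
  metadata(x)$state <- value
  validObject(x)
  x
}

#' Abundance values
#'
#' Accessor for the abundance assay matrix.
#' @param x an `AbundanceExperiment`.
#' @return Numeric matrix, proteins x samples.
#' @export
abundanceValues <- function(x) assay(x, "abundance")

# Sample grouping key: one group per (batch, time point).
timeGroups <- function(x) {
  cd <- colData(x)
  paste(cd$batch, cd$timePoint, sep = ":")
}

setMethod("show", "AbundanceExperiment", function(object) {
  cat("AbundanceExperiment [state: ", abundanceState(object), "]\n", sep = "")
  cat(nrow(object), " proteins x ", ncol(object), " samples; ",
      length(unique(timeGroups(object))), " time point(s), batches: ",
      paste(unique(colData(object)$batch), collapse = ", "), "\n", sep = "")
  miss <- sum(is.na(assay(object, "abundance")))
  cat("missing values: ", miss, " (",
      round(100 * miss / length(assay(object, "abundance")), 1), "%)\n",
      sep = "")
})

#' Pairwise correlation matrix with overlap counts
#'
#' Symmetric Pearson correlation matrix over samples or proteins, together
#' with the number of pairwise-complete observations behind every entry.
#' Entries backed by fewer than the minimum overlap, or by a zero-variance
#' vector, are `NA`.
#'
#' @slot r numeric matrix of correlations in `[-1, 1]` (or `NA`).
#' @slot n integer matrix of pairwise-complete overlap counts.
#' @exportClass CorrelationMatrix
setClass("CorrelationMatrix",
         representation(r = "matrix", n = "matrix"))

setValidity("CorrelationMatrix", function(object) {
  msg <- character()
  r <- object@r; n <- object@n
  if (!identical(dim(r), dim(n)))
    msg <- c(msg, "r and n must have identical dimensions")
  if (nrow(r) != ncol(r)) msg <- c(msg, "r must be square")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (nrow(r) && max(abs(r - t(r)), na.rm = TRUE) > 1e-12)
    msg <- c(msg, "r must be symmetric")
  if (length(msg)) msg else TRUE
})

#' @describeIn CorrelationMatrix-class correlation values
#' @param x a `CorrelationMatrix`.
#' @export
corValues <- function(x) x@r

#' @describeIn CorrelationMatrix-class pairwise overlap counts
#' @export
corOverlap <- function(x) x@n

setMethod("show", "CorrelationMatrix", function(object) {
  cat("CorrelationMatrix over ", nrow(object@r), " items; ",
      sum(is.na(object@r[upper.tri(object@r)])), " undefined pair(s)\n",
      sep = "")
})

#' Pathway model: pathways, reactions, measurable entities
#'
#' A pathway is a named set of reactions; each reaction is linked to the set
#' of measurable entities (protein/gene identifiers) that catalyse or carry
#' it. This is the input structure for differential pathway perturbation
#' scoring ([pathwayDpps()], [rankPathways()]).
#'
#' @slot pathways named list; each element is `list(name = <character>,
#'   reactions = <named list of character entity-id vectors>)`.
#' @exportClass PathwayModel
setClass("PathwayModel", representation(pathways = "list"))

setValidity("PathwayModel", function(object) {
  msg <- character()
  pw <- object@pathways
  if (is.null(names(pw)) || any(names(pw) == "") || anyDuplicated(names(pw)))
    msg <- c(msg, "pathways must have unique non-empty names")
  for (id in names(pw)) {
    p <- pw[[id]]
    if (!is.list(p) || !all(c("name", "reactions") %in% names(p))) {
      msg <- c(msg, paste0("pathway '", id, "' must have $name and $reactions"))
      next
    }
    if (length(p$reactions) < 1L)
      msg <- c(msg, paste0("pathway '", id, "' must have at least 1 reaction"))
    if (is.null(names(p$reactions)) || anyDuplicated(names(p$reactions)))
      msg <- c(msg, paste0("pathway '", id, "' reactions must be uniquely named"))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname PathwayModel-class
#' @param pathways named list of `list(name, reactions)` entries; `reactions`
#'   is a named list mapping reaction ids to character vectors of entity ids
#'   (possibly empty).
#' @return A `PathwayModel`.
#' @export
PathwayModel <- function(pathways) {
  pathways <- lapply(pathways, function(p) {
    p$reactions <- lapply(p$reactions, as.character)
    p$name <- as.character(p$name %||% "")
    p[c("name", "reactions")]
  })
  new("PathwayModel", pathways = pathways)
}

#' @describeIn PathwayModel-class pathway identifiers
#' @param x a `PathwayModel`.
#' @export
pathwayIds <- function(x) names(x@pathways)

#' @describeIn PathwayModel-class reactions (named list of entity-id vectors)
#'   of one pathway
#' @param pathway pathway identifier.
#' @export
pathwayReactions <- function(x, pathway) {
  stopIfNot(pathway %in% names(x@pathways),
            paste0("unknown pathway: ", pathway))
  x@pathways[[pathway]]$reactions
}

setMethod("show", "PathwayModel", function(object) {
  nr <- vapply(object@pathways, function(p) length(p$reactions), integer(1))
  cat("PathwayModel: ", length(object@pathways), " pathway(s), ",
      sum(nr), " reaction(s)\n", sep = "")
})

#' Protein-complex catalog
#'
#' Named protein sets representing annotated complexes. Variants of one
#' complex are kept as discrete entries. Every complex has at least two
#' members.
#'
#' @slot complexes named list of character member vectors.
#' @exportClass ComplexCatalog
setClass("ComplexCatalog", representation(complexes = "list"))

setValidity("ComplexCatalog", function(object) {
  msg <- character()
  cx <- object@complexes
  if (is.null(names(cx)) || any(names(cx) == "") || anyDuplicated(names(cx)))
    msg <- c(msg, "complexes must have unique non-empty names")
  sizes <- vapply(cx, function(m) length(unique(m)), integer(1))
  if (length(sizes) && any(sizes < 2L))
    msg <- c(msg, "every complex must have >= 2 distinct members")
  if (length(msg)) msg else TRUE
})

#' @rdname ComplexCatalog-class
#' @param complexes named list of character vectors of member protein ids.
#' @return A `ComplexCatalog`.
#' @export
ComplexCatalog <- function(complexes) {
  new("ComplexCatalog", complexes = lapply(complexes, as.character))
}

#' @describeIn ComplexCatalog-class member sets as a named list
#' @param x a `ComplexCatalog`.
#' @export
complexMembers <- function(x) x@complexes

setMethod("show", "ComplexCatalog", function(object) {
  sizes <- lengths(object@complexes)
  cat("ComplexCatalog: ", length(sizes), " complex(es), member counts ",
      if (length(sizes)) paste0(min(sizes), "-", max(sizes)) else "-",
      "\n", sep = "")
})

#' Subcellular localization map
#'
#' Protein-to-compartment annotation. A protein localized to several
#' compartments is annotated in all of them, so no information is lost when
#' compartment-wise correlation distributions are formed.
#'
#' @slot locations named list mapping protein ids to character vectors of
#'   compartments (each protein maps to at least one).
#' @exportClass LocalizationMap
setClass("LocalizationMap", representation(locations = "list"))

setValidity("LocalizationMap", function(object) {
  msg <- character()
  loc <- object@locations
  if (length(loc) && (is.null(names(loc)) || any(names(loc) == "")))
    msg <- c(msg, "locations must be named by protein id")
  if (length(loc) && any(lengths(loc) < 1L))
    msg <- c(msg, "every protein must map to >= 1 compartment")
  if (length(msg)) msg else TRUE
})

#' @rdname LocalizationMap-class
#' @param locations named list (protein id -> compartments).
#' @return A `LocalizationMap`.
#' @export
LocalizationMap <- function(locations) {
  new("LocalizationMap", locations = lapply(locations, as.character))
}

#' @describeIn LocalizationMap-class protein -> compartments list
#' @param x a `LocalizationMap`.
#' @export
proteinLocations <- function(x) x@locations

setMethod("show", "LocalizationMap", function(object) {
  comps <- unique(unlist(object@locations, use.names = FALSE))
  cat("LocalizationMap: ", length(object@locations), " protein(s) over ",
      length(comps), " compartment(s)\n", sep = "")
})
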