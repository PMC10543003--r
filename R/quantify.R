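#' Convert PSM counts to ppm abundances
#'
#' Spectral-count quantification: per sample, every peptide-spectrum match
#' is weighted by its peptide length and the protein's correction factor
#' (the reciprocal of its detectable length), the per-protein weights are
#' scaled by 1,000,000 and divided by the sample total, so each sample
#' column sums to one million ppm.
#'
#' Two input granularities are supported. With peptide-level counts
#' (`peptides` given, rows of `counts` are peptide sequences) the weight is
#' `sum(PSM x length) x factor` exactly. With protein-level counts (rows of
#' `counts` are protein ids, `detectableLength` given) the per-PSM peptide
#' identity is unknown and the weight is the length-normalized spectral
#' count `PSM x factor`, the convention under which counts proportional to
#' abundance x detectable length invert to relative abundance.
#'
#' @param counts non-negative integer matrix of PSM counts (peptides x
#'   samples or proteins x samples).
#' @param detectableLength named per-protein detectable lengths (protein
#'   level input; see [detectableLengths()]).
#' @param peptides peptide table from [peptideTable()] (peptide-level
#'   input); only in-range peptides contribute.
#' @return Numeric matrix of ppm abundances (proteins x samples). Proteins
#'   without a defined correction factor are excluded with a warning.
#'   Samples with zero total weight give an all-`NA` column with a warning.
#' @examples
#' pt <- data.frame(protein = c("A", "B"),
#'                  peptide = c("AAAAAAAAAA", "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCC"),
#'                  length = c(10L, 30L), inRange = TRUE)
#' counts <- matrix(c(3L, 1L), 2, 1,
#'                  dimnames = list(pt$peptide, "s1"))
#' psmToPpm(counts, peptides = pt)  # A: 750000, B: 250000
#' @export
psmToPpm <- function(counts, detectableLength = NULL, peptides = NULL) {
  stopIfNot(is.matrix(counts) && !is.null(rownames(counts)),
            "counts must be a matrix with rownames")
  stopIfNot(all(counts >= 0, na.rm = TRUE), "counts must be non-negative")
  if (!is.null(peptides)) {
    stopIfNot(all(c("protein", "peptide", "length", "inRange") %in%
                    colnames(peptides)),
              "peptides must come from peptideTable()")
    idx <- match(rownames(counts), peptides$peptide)
    stopIfNot(!anyNA(idx), "every counted peptide must map to a protein")
    pep <- peptides[idx, ]
    dl <- vapply(split(peptides$length[peptides$inRange],
                       peptides$protein[peptides$inRange]), sum, numeric(1))
    keep <- pep$inRange & pep$protein %in% names(dl)
    dropped <- setdiff(unique(pep$protein), unique(pep$protein[keep]))
    if (length(dropped))
      warning(length(dropped), " protein(s) without a defined correction ",
              "factor excluded from ppm")
    prot <- sort(unique(pep$protein[keep]))
    contrib <- counts[keep, , drop = FALSE] * pep$length[keep] /
      dl[pep$protein[keep]]
    weight <- rowsum(contrib, pep$protein[keep])[prot, , drop = FALSE]
  } else {
    stopIfNot(!is.null(detectableLength),
              "give either 'peptides' or 'detectableLength'")
    stopIfNot(all(rownames(counts) %in% names(detectableLength)),
              "detectableLength must cover all proteins in 'counts'")
    dl <- detectableLength[rownames(counts)]
    drop <- dl <= 0 | is.na(dl)
    if (any(drop))
      warning(sum(drop), " protein(s) without a defined correction factor ",
              "excluded from ppm")
    weight <- counts[!drop, , drop = FALSE] / dl[!drop]
  }
  tot <- colSums(weight, na.rm = TRUE)
  zero <- tot <= 0
  if (any(zero)) {
    warning(sum(zero), " sample(s) with zero total weight: ppm undefined, ",
            "column(s) flagged missing")
    tot[zero] <- NA_real_
  }
  sweep(weight, 2, tot, "/") * 1e6
}

#' Detection filters: unique peptides and both-replicate rule
#'
#' Drops proteins identified by fewer than `minUniquePeptides` unique
#' peptides, and masks (sets `NA`) any value at a time point where the
#' protein was not observed in both replicates, so that downstream testing
#' only sees concordantly detected measurements. The protein is retained at
#' other time points where both replicates detect it.
#'
#' @param x an [AbundanceExperiment] with per-replicate columns and
#'   `rowData(x)$uniquePeptides`.
#' @param minUniquePeptides minimum unique peptide count (default 2).
#' @param strict if `TRUE`, a time point without exactly two replicates is
#'   an error; if `FALSE` (default) it is kept unmasked with a warning.
#' @return The filtered `AbundanceExperiment` (state unchanged).
#' @export
detectionFilter <- function(x, minUniquePeptides = 2, strict = FALSE) {
  stopIfNot(is(x, "AbundanceExperiment"), "x must be an AbundanceExperiment")
  up <- rowData(x)$uniquePeptides
  if (!is.null(up) && minUniquePeptides > 0)
    x <- x[!is.na(up) & up >= minUniquePeptides, ]
  a <- abundanceValues(x)
  grp <- timeGroups(x)
  for (g in unique(grp)) {
    cols <- which(grp == g)
    if (length(cols) != 2L) {
      msg <- paste0("time point '", g, "' has ", length(cols),
                    " replicate(s), not 2")
      if (strict) stop(msg, call. = FALSE)
      warning(msg, "; both-replicate rule not applied there")
      next
    }
    obs <- !is.na(a[, cols, drop = FALSE])
    partial <- rowSums(obs) == 1L
    a[partial, cols] <- NA
  }
  assays(x)$abundance <- a
  x
}

#' Sum replicate columns per time point
#'
#' Collapses per-replicate columns to one column per (batch, time point),
#' summing non-missing values; a single observed replicate stands alone, so
#' summing maximizes the number of proteins retained. A value is missing
#' only when missing in every replicate.
#'
#' @param x an [AbundanceExperiment] with per-replicate columns (state
#'   `"raw"`, `"ppm"` or `"replicate_summed"`).
#' @return An `AbundanceExperiment` with state `"replicate_summed"`, one
#'   column per time point, in the original time-point order.
#' @export
sumReplicates <- function(x) {
  stopIfNot(is(x, "AbundanceExperiment"), "x must be an AbundanceExperiment")
  a <- abundanceValues(x)
  grp <- timeGroups(x)
  keys <- unique(grp)
  out <- matrix(NA_real_, nrow(a), length(keys),
                dimnames = list(rownames(a), keys))
  for (i in seq_along(keys)) {
    cols <- which(grp == keys[i])
    block <- a[, cols, drop = FALSE]
    allNA <- rowSums(!is.na(block)) == 0L
    s <- rowSums(block, na.rm = TRUE)
    s[allNA] <- NA_real_
    out[, i] <- s
  }
  first <- match(keys, grp)
  cd <- data.frame(batch = colData(x)$batch[first],
                   timePoint = colData(x)$timePoint[first],
                   phase = colData(x)$phase[first],
                   replicate = NA_integer_,
                   row.names = keys)
  res <- AbundanceExperiment(out, cd, state = "replicate_summed")
  rowData(res) <- rowData(x)
  res
}

#' Log2 transform and median centering
#'
#' Label-free intensities are log-normally distributed; log2 transformation
#' yields approximately normal values and subtracting each column's median
#' equalizes variances across samples. Zeros are treated as missing.
#'
#' @param x an [AbundanceExperiment] (or bare numeric matrix) of positive
#'   or missing abundances.
#' @return Same shape, state `"log2_centered"`; every column's median over
#'   non-missing entries is 0.
#' @export
log2MedianCenter <- function(x) {
  a <- if (is(x, "AbundanceExperiment")) abundanceValues(x) else x
  if (any(a < 0, na.rm = TRUE))
    stop("negative abundance value: log2 transform undefined", call. = FALSE)
  a[a == 0] <- NA_real_
  la <- log2(a)
  meds <- apply(la, 2, median, na.rm = TRUE)
  la <- sweep(la, 2, meds, "-")
  if (is(x, "AbundanceExperiment")) {
    assays(x)$abundance <- la
    metadata(x)$state <- "log2_centered"
    x
  } else la
}

#' Normalize each protein to its mean abundance over time
#'
#' Expresses every entry as the log2 ratio of the value to the protein's
#' mean over non-missing samples. This is the representation the trajectory
#' clustering and the pathway perturbation scores operate on.
#'
#' @param x an [AbundanceExperiment] (exp-scale values, e.g. state
#'   `"replicate_summed"`) or bare positive matrix.
#' @return Same shape, state `"row_mean_normalized"`. All-missing rows are
#'   dropped with a warning.
#' @export
rowMeanNormalize <- function(x) {
  a <- if (is(x, "AbundanceExperiment")) abundanceValues(x) else x
  if (any(a < 0, na.rm = TRUE))
    stop("negative abundance value: log ratio undefined", call. = FALSE)
  a[a == 0] <- NA_real_
  allNA <- rowSums(!is.na(a)) == 0L
  if (any(allNA)) {
    warning(sum(allNA), " all-missing row(s) dropped")
    a <- a[!allNA, , drop = FALSE]
    if (is(x, "AbundanceExperiment")) x <- x[!allNA, ]
  }
  rm <- rowMeans(a, na.rm = TRUE)
  out <- log2(a / rm)
  if (is(x, "AbundanceExperiment")) {
    assays(x)$abundance <- out
    metadata(x)$state <- "row_mean_normalized"
    x
  } else out
}
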