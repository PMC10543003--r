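#' Pairwise Pearson correlation between samples
#'
#' Computes Pearson r over pairwise-complete protein values for every pair
#' of sample columns, recording the overlap behind each entry. Pairs with
#' fewer than `minOverlap` shared proteins, and pairs involving a
#' zero-variance vector, are reported missing (`NA`), with a warning.
#'
#' @param x an [AbundanceExperiment] or numeric matrix (items in columns).
#' @param minOverlap minimum pairwise-complete observations (default 3).
#' @return A [CorrelationMatrix].
#' @export
sampleCorrelation <- function(x, minOverlap = 3) {
  a <- if (is(x, "AbundanceExperiment")) abundanceValues(x) else x
  stopIfNot(ncol(a) >= 2, "need at least 2 samples")
  pairwiseCorrelation(a, minOverlap)
}

# core: columns of `a` are the correlated items
pairwiseCorrelation <- function(a, minOverlap = 3) {
  n <- crossprod(!is.na(a))
  r <- suppressWarnings(cor(a, use = "pairwise.complete.obs"))
  low <- n < minOverlap
  nUndef <- sum(is.na(r[upper.tri(r)]) & !low[upper.tri(low)])
  if (nUndef > 0)
    warning(nUndef, " pair(s) with zero variance: correlation undefined")
  if (any(low[upper.tri(low)]))
    warning(sum(low[upper.tri(low)]),
            " pair(s) below the minimum overlap of ", minOverlap)
  r[low] <- NA_real_
  # diagonal is 1 wherever the vector has variance and enough observations
  dvar <- apply(a, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) >= minOverlap && var(v) > 0
  })
  diag(r) <- ifelse(dvar, 1, NA_real_)
  storage.mode(n) <- "integer"
  new("CorrelationMatrix", r = r, n = n)
}

#' Replicate quality control
#'
#' Per time point: the Pearson correlation between the two replicates
#' (computed on log2 intensities when the data are on the raw scale) and
#' the number of proteins detected in exactly one of the two replicates.
#'
#' @param x an [AbundanceExperiment] with per-replicate columns.
#' @param log2Transform log2-transform before correlating (default `TRUE`
#'   for exp-scale states, `FALSE` otherwise).
#' @return data.frame with columns `batch`, `timePoint`, `r`, `nOverlap`,
#'   `singleReplicate`.
#' @export
replicateQC <- function(x, log2Transform = abundanceState(x) %in%
                          c("raw", "ppm", "replicate_summed")) {
  stopIfNot(is(x, "AbundanceExperiment"), "x must be an AbundanceExperiment")
  a <- abundanceValues(x)
  if (log2Transform) {
    a[a == 0] <- NA_real_
    a <- log2(a)
  }
  grp <- timeGroups(x)
  keys <- unique(grp)
  cd <- colData(x)
  out <- lapply(keys, function(g) {
    cols <- which(grp == g)
    stopIfNot(length(cols) == 2L,
              paste0("time point '", g, "' does not have 2 replicates"))
    v1 <- a[, cols[1]]; v2 <- a[, cols[2]]
    both <- !is.na(v1) & !is.na(v2)
    r <- if (sum(both) >= 3) suppressWarnings(cor(v1[both], v2[both]))
         else NA_real_
    data.frame(batch = cd$batch[cols[1]], timePoint = cd$timePoint[cols[1]],
               r = r, nOverlap = sum(both),
               singleReplicate = sum(xor(!is.na(v1), !is.na(v2))))
  })
  do.call(rbind, out)
}

#' Pairwise Pearson correlation between proteins
#'
#' Protein-by-protein correlation across all samples (both batches), the
#' structure behind the global co-expression similarity matrix and all
#' complex/compartment co-regulation summaries.
#'
#' @param x an [AbundanceExperiment] or numeric matrix (proteins in rows).
#' @param subset optional protein ids to restrict to.
#' @param minOverlap minimum shared samples per pair (default 3).
#' @return A [CorrelationMatrix] over proteins.
#' @export
proteinCorrelation <- function(x, subset = NULL, minOverlap = 3) {
  a <- if (is(x, "AbundanceExperiment")) abundanceValues(x) else x
  if (!is.null(subset)) {
    stopIfNot(all(subset %in% rownames(a)), "unknown protein id(s) in subset")
    a <- a[subset, , drop = FALSE]
  }
  stopIfNot(nrow(a) >= 2, "need at least 2 proteins")
  pairwiseCorrelation(t(a), minOverlap)
}
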