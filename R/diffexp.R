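#' Pairwise t-test between two time points
#'
#' Two-sided t-test on log2-centered abundances for every protein, between
#' the replicate groups of two time points. The default is the pooled
#' (equal-variance) Student test; Welch is available. Proteins with fewer
#' than two non-missing values in either group are excluded, never imputed.
#' Zero pooled variance gives a missing p (flagged), excluded from the
#' multiple-testing adjustment. A protein is called differentially
#' expressed (DEP) when its Benjamini-Hochberg q-value is below `fdr` and
#' its absolute log2 fold change is at least `lfcGate`.
#'
#' @param x an [AbundanceExperiment] with state `"log2_centered"` (values
#'   already on the log2 scale), or a numeric matrix of log2 values.
#' @param groupA,groupB time-point keys `"batch:label"` (for an
#'   `AbundanceExperiment`) or column indices/names (matrix input).
#' @param varEqual pooled-variance Student test (default `TRUE`); `FALSE`
#'   gives Welch.
#' @param fdr FDR level for the DEP call (default 0.05).
#' @param lfcGate minimum |log2FC| for the DEP call (default 1).
#' @return data.frame with columns `protein`, `nA`, `nB`, `log2FC`
#'   (`mean(A) - mean(B)`), `t`, `df`, `p`, `q`, `dep`, `zeroVariance`,
#'   `excluded`.
#' @export
pairwiseTTest <- function(x, groupA, groupB, varEqual = TRUE,
                          fdr = 0.05, lfcGate = 1) {
  if (is(x, "AbundanceExperiment")) {
    grp <- timeGroups(x)
    stopIfNot(all(c(groupA, groupB) %in% grp),
              "groupA/groupB must be time-point keys 'batch:label'")
    a <- abundanceValues(x)
    A <- a[, grp == groupA, drop = FALSE]
    B <- a[, grp == groupB, drop = FALSE]
  } else {
    A <- x[, groupA, drop = FALSE]
    B <- x[, groupB, drop = FALSE]
  }
  rowTTest(A, B, varEqual = varEqual, fdr = fdr, lfcGate = lfcGate)
}

# Vectorized per-row two-sample t-test on two aligned matrices.
rowTTest <- function(A, B, varEqual = TRUE, fdr = 0.05, lfcGate = 1) {
  stopIfNot(nrow(A) == nrow(B), "A and B must have the same rows")
  nA <- rowSums(!is.na(A)); nB <- rowSums(!is.na(B))
  mA <- rowMeans(A, na.rm = TRUE); mB <- rowMeans(B, na.rm = TRUE)
  vA <- rowSums((A - mA)^2, na.rm = TRUE) / pmax(nA - 1, 1)
  vB <- rowSums((B - mB)^2, na.rm = TRUE) / pmax(nB - 1, 1)
  excluded <- nA < 2 | nB < 2
  if (varEqual) {
    df <- nA + nB - 2
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / df
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
  } else {
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  }
  zeroVar <- !excluded & se == 0
  tstat <- (mA - mB) / se
  tstat[excluded | zeroVar] <- NA_real_
  p <- 2 * pt(-abs(tstat), df)
  p[excluded | zeroVar] <- NA_real_
  q <- bhAdjust(p)
  lfc <- mA - mB
  lfc[excluded] <- NA_real_
  data.frame(protein = rownames(A) %||% as.character(seq_len(nrow(A))),
             nA = nA, nB = nB, log2FC = lfc, t = tstat, df = df, p = p,
             q = q, dep = !is.na(q) & q < fdr & abs(lfc) >= lfcGate,
             zeroVariance = zeroVar, excluded = excluded,
             row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]). Missing p-values stay missing and do not count
#' toward the number of tests.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return q-values, order-preserving and capped at 1.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

# enumerate time-point pairs under a comparison scheme
timePairScheme <- function(x, pairs = c("all", "consecutive", "matched")) {
  pairs <- match.arg(pairs)
  grp <- unique(timeGroups(x))
  cd <- colData(x)
  first <- match(grp, timeGroups(x))
  batch <- cd$batch[first]; label <- cd$timePoint[first]
  out <- switch(pairs,
    all = {
      idx <- which(upper.tri(matrix(0, length(grp), length(grp))),
                   arr.ind = TRUE)
      data.frame(A = grp[idx[, 1]], B = grp[idx[, 2]])
    },
    consecutive = do.call(rbind, lapply(unique(batch), function(b) {
      g <- grp[batch == b]
      if (length(g) < 2) return(NULL)
      data.frame(A = g[-length(g)], B = g[-1])
    })),
    matched = {
      shared <- intersect(label[batch == unique(batch)[1]],
                          label[batch == unique(batch)[2]])
      data.frame(A = paste(unique(batch)[1], shared, sep = ":"),
                 B = paste(unique(batch)[2], shared, sep = ":"))
    })
  stopIfNot(!is.null(out) && nrow(out) >= 1, "no time-point pairs to compare")
  out
}

#' DEP counts for every time-point pair
#'
#' Runs [pairwiseTTest()] for each pair of time points under a comparison
#' scheme and tabulates the differentially expressed proteins, giving the
#' symmetric count matrix summarizing how much the proteome moved between
#' any two sampled states.
#'
#' @inheritParams pairwiseTTest
#' @param pairs `"all"` (all time-point pairs), `"consecutive"` (adjacent
#'   time points within each batch) or `"matched"` (same labels across the
#'   two batches).
#' @param scope `"pairwise"` applies BH within each comparison (default);
#'   `"global"` adjusts all comparisons jointly.
#' @return list with `counts` (symmetric integer matrix over time points,
#'   zero diagonal) and `tables` (named list of per-comparison DEP tables).
#' @export
depCountMatrix <- function(x, pairs = c("all", "consecutive", "matched"),
                           varEqual = TRUE, fdr = 0.05, lfcGate = 1,
                           scope = c("pairwise", "global")) {
  scope <- match.arg(scope)
  stopIfNot(length(unique(timeGroups(x))) >= 2, "need at least 2 time points")
  pr <- timePairScheme(x, pairs)
  grp <- unique(timeGroups(x))
  counts <- matrix(0L, length(grp), length(grp), dimnames = list(grp, grp))
  tables <- vector("list", nrow(pr))
  names(tables) <- paste(pr$A, "vs", pr$B)
  for (i in seq_len(nrow(pr))) {
    tables[[i]] <- pairwiseTTest(x, pr$A[i], pr$B[i], varEqual = varEqual,
                                 fdr = fdr, lfcGate = lfcGate)
  }
  if (scope == "global") {
    allP <- unlist(lapply(tables, `[[`, "p"))
    allQ <- bhAdjust(allP)
    off <- 0L
    for (i in seq_along(tables)) {
      m <- nrow(tables[[i]])
      tables[[i]]$q <- allQ[off + seq_len(m)]
      tables[[i]]$dep <- !is.na(tables[[i]]$q) & tables[[i]]$q < fdr &
        abs(tables[[i]]$log2FC) >= lfcGate
      off <- off + m
    }
  }
  for (i in seq_len(nrow(pr))) {
    nDep <- sum(tables[[i]]$dep, na.rm = TRUE)
    counts[pr$A[i], pr$B[i]] <- counts[pr$B[i], pr$A[i]] <- nDep
  }
  list(counts = counts, tables = tables)
}
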