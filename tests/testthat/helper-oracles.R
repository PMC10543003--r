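# Independent brute-force oracles. These deliberately avoid the code paths
# they check: loops instead of vectorization, enumeration instead of closed
# forms.

# tryptic cleavage via a lookaround regular expression
oracleDigest <- function(seq) {
  strsplit(seq, "(?<=[KR])(?!P)", perl = TRUE)[[1]]
}

# ppm from peptide-level PSM counts: plain loops over peptides and samples
oraclePpm <- function(counts, pepTable) {
  proteins <- sort(unique(pepTable$protein))
  dl <- sapply(proteins, function(pr) {
    s <- 0
    for (i in seq_len(nrow(pepTable)))
      if (pepTable$protein[i] == pr && pepTable$inRange[i])
        s <- s + pepTable$length[i]
    s
  })
  proteins <- proteins[dl > 0]
  out <- matrix(0, length(proteins), ncol(counts),
                dimnames = list(proteins, colnames(counts)))
  for (j in seq_len(ncol(counts))) {
    for (pr in proteins) {
      w <- 0
      for (i in seq_len(nrow(pepTable))) {
        if (pepTable$protein[i] != pr || !pepTable$inRange[i]) next
        row <- match(pepTable$peptide[i], rownames(counts))
        if (is.na(row)) next
        w <- w + counts[row, j] * pepTable$length[i] * (1 / dl[pr])
      }
      out[pr, j] <- w
    }
    out[, j] <- out[, j] * 1e6 / sum(out[, j])
  }
  out
}

# two-pass Pearson correlation on the complete cases of two vectors
oraclePearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# BH step-up, written from the definition
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cands <- Inf
    for (j in seq_len(m)) {
      if (p[o[j]] >= p[o[i]]) cands <- min(cands, p[o[j]] * m / j)
    }
    q[o[i]] <- min(1, cands)
  }
  q
}

# hypergeometric upper tail by summation over the support
oracleHyper <- function(k, K, N, n) {
  tot <- 0
  for (j in seq(k, min(K, n)))
    tot <- tot + choose(K, j) * choose(N - K, n - j)
  tot / choose(N, n)
}

# O(n^3) average-linkage agglomeration; returns the cophenetic matrix
oracleAverageLinkCophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestD <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      dd <- mean(d[clusters[[a]], clusters[[b]]])
      if (dd < bestD - 1e-15) { bestD <- dd; best <- c(a, b) }
    }
    ia <- clusters[[best[1]]]; ib <- clusters[[best[2]]]
    coph[ia, ib] <- coph[ib, ia] <- bestD
    clusters[[best[1]]] <- c(ia, ib)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# DRPS by exhaustive enumeration of sample pairs per entity
oracleDrps <- function(values) {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  best <- 0
  for (i in seq_len(nrow(values))) {
    v <- values[i, ]
    v <- v[!is.na(v)]
    if (length(v) < 2) next
    for (a in seq_along(v)) for (b in seq_along(v))
      best <- max(best, abs(v[a] - v[b]))
  }
  best
}

# quick experiment construction for tests
makeExperiment <- function(values, batch = "B1",
                           timePoint = rep(seq_len(ncol(values) / 2), each = 2),
                           replicate = rep(1:2, ncol(values) / 2),
                           state = "raw", uniquePeptides = NULL) {
  cd <- data.frame(batch = batch, timePoint = as.character(timePoint),
                   phase = "fermentation", replicate = replicate)
  rownames(cd) <- colnames(values) %||%
    paste0("s", seq_len(ncol(values)))
  colnames(values) <- rownames(cd)
  fermprot::AbundanceExperiment(values, cd, state = state,
                                uniquePeptides = uniquePeptides)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

colData <- SummarizedExperiment::colData
rowData <- SummarizedExperiment::rowData

randomProteinSequence <- function(len, krBoost = 0.15) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  pr <- rep((1 - krBoost) / 18, 20)
  pr[aa %in% c("K", "R")] <- krBoost / 2
  paste(sample(aa, len, replace = TRUE, prob = pr), collapse = "")
}
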