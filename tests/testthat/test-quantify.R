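test_that("ppm normalization reproduces the worked spectral-count example", {
  pt <- data.frame(protein = c("A", "B"),
                   peptide = c(strrep("A", 10), strrep("C", 30)),
                   length = c(10L, 30L), inRange = TRUE)
  counts <- matrix(c(3L, 1L), 2, 1, dimnames = list(pt$peptide, "s1"))
  ppm <- psmToPpm(counts, peptides = pt)
  expect_equal(ppm["A", 1], 750000)
  expect_equal(ppm["B", 1], 250000)
  # one protein self-normalizes to a million; zero PSMs give zero ppm
  one <- psmToPpm(counts[1, , drop = FALSE], peptides = pt)
  expect_equal(unname(one[1, 1]), 1e6)
  counts0 <- counts; counts0["AAAAAAAAAA", 1] <- 0L
  expect_equal(psmToPpm(counts0, peptides = pt)["A", 1], 0)
})

test_that("every ppm column sums to one million and scale invariance holds", {
  set.seed(5)
  dl <- setNames(sample(50:400, 80), sprintf("P%02d", 1:80))
  counts <- matrix(rpois(80 * 4, 30), 80, 4,
                   dimnames = list(names(dl), paste0("s", 1:4)))
  ppm <- psmToPpm(counts, detectableLength = dl)
  expect_equal(unname(colSums(ppm)), rep(1e6, 4), tolerance = 1e-6)
  # multiplying one sample's counts by a constant leaves ppm unchanged
  scaled <- counts; scaled[, 2] <- scaled[, 2] * 7L
  expect_equal(psmToPpm(scaled, detectableLength = dl), ppm,
               tolerance = 1e-12)
})

test_that("peptide-level ppm matches the brute-force per-peptide oracle", {
  set.seed(6)
  for (i in 1:30) {
    nProt <- sample(2:8, 1)
    peps <- do.call(rbind, lapply(seq_len(nProt), function(p) {
      k <- sample(1:4, 1)
      lens <- sample(3:50, k)
      data.frame(protein = sprintf("P%d", p),
                 peptide = vapply(seq_len(k), function(j)
                   paste0(strrep("A", lens[j]), sprintf("X%d_%d", p, j)),
                   character(1)),
                 length = lens, inRange = lens >= 7 & lens <= 40)
    }))
    # keep only proteins with at least one in-range peptide
    ok <- unique(peps$protein[peps$inRange])
    peps <- peps[peps$protein %in% ok, ]
    counts <- matrix(rpois(nrow(peps) * 3, 5), nrow(peps), 3,
                     dimnames = list(peps$peptide, paste0("s", 1:3)))
    got <- psmToPpm(counts, peptides = peps)
    want <- oraclePpm(counts, peps)
    expect_equal(got, want[rownames(got), , drop = FALSE],
                 tolerance = 1e-9)
  }
})

test_that("detection filter enforces unique peptides and both replicates", {
  m <- matrix(10, 4, 4, dimnames = list(paste0("P", 1:4), NULL))
  m[2, 1] <- NA              # P2 seen in one replicate of time point 1
  m[3, 3] <- m[3, 4] <- NA   # P3 absent at time point 2
  se <- makeExperiment(m, uniquePeptides = c(2L, 3L, 2L, 1L))
  filt <- detectionFilter(se)
  a <- abundanceValues(filt)
  expect_false("P4" %in% rownames(a))     # one unique peptide: removed
  expect_true(all(is.na(a["P2", 1:2])))   # masked where single-replicate
  expect_false(anyNA(a["P2", 3:4]))       # retained where concordant
  expect_identical(a["P1", ], setNames(rep(10, 4), colnames(a)))
  expect_error(detectionFilter(se[, 1:3], strict = TRUE), "replicate")
})

test_that("replicate summing keeps single-replicate observations", {
  m <- matrix(c(5, 7, 5, NA, NA, NA), 3, 2, byrow = TRUE,
              dimnames = list(paste0("P", 1:3), NULL))
  se <- makeExperiment(m, timePoint = c(1, 1), replicate = 1:2)
  s <- sumReplicates(se)
  expect_identical(abundanceState(s), "replicate_summed")
  expect_equal(unname(abundanceValues(s)[, 1]), c(12, 5, NA))
})

test_that("log2 median centering zeroes each column median", {
  m <- matrix(c(2, 8, 32), 3, 2, dimnames = list(paste0("P", 1:3), NULL))
  se <- makeExperiment(m, timePoint = c(1, 1), replicate = 1:2)
  cc <- log2MedianCenter(se)
  expect_identical(abundanceState(cc), "log2_centered")
  expect_equal(unname(abundanceValues(cc)[, 1]), c(-2, 0, 2))
  # identical values center to zero; zeros are treated as missing
  flat <- log2MedianCenter(matrix(c(4, 4, 4, 0), 4, 1))
  expect_equal(flat[1:3, 1], rep(0, 3))
  expect_true(is.na(flat[4, 1]))
  expect_error(log2MedianCenter(matrix(-1, 1, 1)), "negative")
  set.seed(7)
  r <- log2MedianCenter(matrix(2^rnorm(60, 10, 3), 12, 5))
  expect_equal(unname(apply(r, 2, median, na.rm = TRUE)), rep(0, 5),
               tolerance = 1e-9)
})

test_that("row-mean normalization gives log2 ratios to the row mean", {
  m <- matrix(c(4, 4, 4, 2, 4, 8), 2, 3, byrow = TRUE,
              dimnames = list(c("P1", "P2"), paste0("s", 1:3)))
  r <- rowMeanNormalize(m)
  expect_equal(unname(r["P1", ]), c(0, 0, 0))
  expect_equal(unname(r["P2", ]), log2(c(2, 4, 8) / (14 / 3)),
               tolerance = 1e-12)
  # scale invariance: a constant multiple shifts rows, ratios unchanged
  expect_equal(rowMeanNormalize(m * 16), r, tolerance = 1e-12)
  expect_warning(rowMeanNormalize(matrix(NA_real_, 1, 2)), "all-missing")
})
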