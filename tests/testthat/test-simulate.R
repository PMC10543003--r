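test_that("simulation is deterministic under a fixed seed", {
  cfg <- simulationConfig(nProteins = 120L, seed = 11L,
                          trajectoryClasses = NULL, batchShift = NULL,
                          complexPlan = data.frame(size = c(4L, 5L),
                                                   loading = 0.8))
  s1 <- simulateTimecourse(cfg)
  s2 <- simulateTimecourse(cfg)
  expect_identical(abundanceValues(s1$experiment),
                   abundanceValues(s2$experiment))
  expect_identical(s1$truth, s2$truth)
  # RNG state of the caller is untouched
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(simulateTimecourse(cfg))
  expect_identical(rnorm(3), before)
})

test_that("zero-noise, zero-dropout replicates are identical with r = 1", {
  cfg <- simulationConfig(nProteins = 80L, replicateNoiseSd = 0,
                          dropoutRate = 0, trajectoryClasses = NULL,
                          batchShift = NULL, complexPlan = NULL, seed = 2L)
  sim <- simulateTimecourse(cfg)
  a <- abundanceValues(sim$experiment)
  grp <- paste(colData(sim$experiment)$batch,
               colData(sim$experiment)$timePoint)
  for (g in unique(grp)) {
    cols <- which(grp == g)
    expect_identical(a[, cols[1]], a[, cols[2]])
  }
  qc <- replicateQC(sim$experiment)
  expect_true(all(abs(qc$r - 1) < 1e-12))
  expect_true(all(qc$singleReplicate == 0))
})

test_that("planted structure is disjoint and reflected in the truth object", {
  cfg <- simulationConfig(nProteins = 300L, seed = 4L,
                          trajectoryClasses = data.frame(
                            shape = c("early_peak", "late_rise"),
                            n = c(40L, 30L), effect = 2),
                          batchShift = list(n = 10L, shift = 1,
                                            batch = "B15"),
                          complexPlan = data.frame(size = rep(4L, 3),
                                                   loading = 0.9))
  truth <- simulateTimecourse(cfg)$truth
  planted <- names(truth$trajectoryClass)[!is.na(truth$trajectoryClass)]
  expect_length(planted, 70L)
  expect_equal(sum(truth$trajectoryClass == "early_peak", na.rm = TRUE), 40L)
  # trajectory members, shift members and complex members never overlap
  expect_length(intersect(planted, truth$batchShift), 0L)
  expect_length(intersect(planted, unlist(truth$complexes)), 0L)
  expect_length(intersect(truth$batchShift, unlist(truth$complexes)), 0L)
  # zero-noise run reproduces the planted surface exactly after log2
  cfg0 <- simulationConfig(nProteins = 300L, seed = 4L,
                           replicateNoiseSd = 0, dropoutRate = 0,
                           trajectoryClasses = data.frame(
                             shape = c("early_peak", "late_rise"),
                             n = c(40L, 30L), effect = 2),
                           batchShift = list(n = 10L, shift = 1,
                                             batch = "B15"),
                           complexPlan = data.frame(size = rep(4L, 3),
                                                    loading = 0.9))
  sim0 <- simulateTimecourse(cfg0)
  a <- log2(abundanceValues(sim0$experiment))
  rep1 <- a[, colData(sim0$experiment)$replicate == 1]
  colnames(rep1) <- sub(":r1$", "", colnames(rep1))
  expect_equal(unname(rep1), unname(sim0$truth$plantedLog2),
               tolerance = 1e-12)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(simulationConfig(nProteins = 0), "nProteins")
  expect_error(simulationConfig(dropoutRate = 1), "dropoutRate")
  expect_error(simulationConfig(replicateNoiseSd = -1), "replicateNoiseSd")
  expect_error(simulationConfig(nProteins = 10L), "planted")
})

test_that("simulated FASTA matches the requested ids and K/R control", {
  cfg <- simulationConfig(nProteins = 10L, trajectoryClasses = NULL,
                          batchShift = NULL, complexPlan = NULL, seed = 8L)
  fa <- simulateProteinFasta(cfg)
  expect_length(fa, 10L)
  expect_identical(names(fa), sprintf("P%04d", 1:10))
  # no cleavage sites at K/R frequency 0: digest is the whole protein
  cfg0 <- simulationConfig(nProteins = 5L, krFrequency = 0,
                           trajectoryClasses = NULL, batchShift = NULL,
                           complexPlan = NULL, seed = 8L)
  fa0 <- simulateProteinFasta(cfg0)
  peps <- peptideTable(fa0)
  expect_equal(nrow(peps), 5L)
  expect_identical(peps$peptide, unname(as.character(fa0)))
  # default K/R frequency 0.1 gives mean tryptic peptide length near 10
  cfgL <- simulationConfig(nProteins = 300L, trajectoryClasses = NULL,
                           batchShift = NULL, complexPlan = NULL, seed = 9L)
  lens <- peptideTable(simulateProteinFasta(cfgL))$length
  expect_gt(mean(lens), 8.5)
  expect_lt(mean(lens), 11.5)
})

test_that("PSM sampling respects depth, degenerate cases and expected ratios", {
  ab <- matrix(c(3, 1), 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  dl <- c(A = 10, B = 30)
  counts <- simulatePsmCounts(ab, dl, depth = 1000L, seed = 1L)
  expect_equal(unname(colSums(counts)), c(1000, 1000))
  # single protein receives everything
  one <- simulatePsmCounts(ab[1, , drop = FALSE], dl, depth = 500L, seed = 1L)
  expect_identical(unname(one[1, ]), c(500L, 500L))
  # abundance x length ratio 3:1 recovered within 1% at large depth
  ab2 <- matrix(c(3, 1), 2, 1, dimnames = list(c("A", "B"), "s1"))
  big <- simulatePsmCounts(ab2, c(A = 10, B = 10), depth = 1000000L,
                           seed = 2L)
  expect_equal(big["A", 1] / big["B", 1], 3, tolerance = 0.01)
  # zero detectable length with non-zero abundance warns and gets no PSMs
  expect_warning(
    z <- simulatePsmCounts(ab, c(A = 10, B = 0), depth = 100L, seed = 3L),
    "zero detectable length")
  expect_identical(unname(z["B", ]), c(0L, 0L))
})

test_that("ppm on simulated PSM counts recovers relative true abundance", {
  cfg <- simulationConfig(nProteins = 150L, trajectoryClasses = NULL,
                          batchShift = NULL, complexPlan = NULL, seed = 31L)
  fa <- simulateProteinFasta(cfg)
  dl <- suppressWarnings(detectableLengths(fa))
  ab <- matrix(2^rnorm(150 * 2, 20, 2), 150, 2,
               dimnames = list(names(fa), c("s1", "s2")))
  counts <- simulatePsmCounts(ab, dl, depth = 200000L, seed = 32L)
  ppm <- suppressWarnings(psmToPpm(counts, detectableLength = dl))
  for (j in 1:2)
    expect_gt(cor(ppm[, j], ab[rownames(ppm), j], method = "spearman"),
              0.99)
})
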