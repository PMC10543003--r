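test_that("two-fold filter keeps rows reaching the gate in any time point", {
  m <- rbind(flat = c(0, 0, 0),
             edge = c(1, 0, 0),     # exactly two-fold: retained (inclusive)
             below = c(0.9, -0.9, 0.5),
             strong = c(-2, 0, 1.5))
  colnames(m) <- paste0("s", 1:3)
  kept <- twofoldFilter(m)
  expect_identical(rownames(kept), c("edge", "strong"))
})

test_that("correlation-distance average-linkage tree behaves as expected", {
  set.seed(30)
  base <- rnorm(6)
  m <- rbind(a = base, b = base,             # identical rows merge at 0
             c = -base,                      # anticorrelated: distance 2
             d = rnorm(6), e = rnorm(6))
  tree <- hclusterProteins(m)
  first <- tree$merge[1, ]
  expect_setequal(first, c(-1, -2))
  expect_equal(tree$height[1], 0, tolerance = 1e-12)
  r <- cor(t(m))
  expect_equal(1 - r["a", "c"], 2, tolerance = 1e-12)
  expect_error(hclusterProteins(m[1, , drop = FALSE]), "at least 2")
  expect_warning(hclusterProteins(rbind(m, z = rep(1, 6))), "zero-variance")
})

test_that("average linkage matches an O(n^3) agglomeration oracle", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    m <- matrix(rnorm(n * 8), n, 8,
                dimnames = list(paste0("r", seq_len(n)), NULL))
    d <- dist(m)
    hc <- hclusterProteins(m, distance = "euclidean")
    expect_equal(unname(as.matrix(cophenetic(hc))),
                 unname(oracleAverageLinkCophenetic(d)), tolerance = 1e-10)
  }
})

test_that("node-depth cut handles root, balanced and caterpillar trees", {
  # balanced 8-leaf tree from two tight quartets of tight pairs
  pts <- c(0, 0.001, 0.1, 0.101, 10, 10.001, 10.1, 10.101)
  m <- matrix(pts, 8, 2)
  rownames(m) <- letters[1:8]
  tree <- hclusterProteins(m, distance = "euclidean")
  expect_equal(nrow(cutByNodeDepth(tree, depth = 0) ), 8)
  expect_equal(length(unique(cutByNodeDepth(tree, 0)$cluster)), 1)
  d3 <- cutByNodeDepth(tree, depth = 3)
  expect_equal(length(unique(d3$cluster)), 8)
  expect_true(all(table(d3$cluster) == 1))
  # caterpillar: leaves join one by one; depth 2 gives 3 clusters
  cat <- matrix(c(0, 0.1, 1, 4), 4, 1)
  rownames(cat) <- c("w", "x", "y", "z")
  ct <- hclusterProteins(cat, distance = "euclidean")
  d2 <- cutByNodeDepth(ct, depth = 2)
  expect_equal(length(unique(d2$cluster)), 3)
  # partition property: every leaf appears exactly once
  expect_setequal(d2$protein, c("w", "x", "y", "z"))
  expect_identical(cutByNodeDepth(ct, 2), cutByNodeDepth(ct, 2))
})

test_that("oversized clusters are re-cut at the subset depth", {
  set.seed(32)
  # one big tight blob plus a small distant one
  m <- rbind(matrix(rnorm(40 * 3, 0, 1), 40, 3),
             matrix(rnorm(5 * 3, 50, 0.1), 5, 3))
  rownames(m) <- sprintf("p%02d", 1:45)
  tree <- hclusterProteins(m, distance = "euclidean")
  cut <- cutByNodeDepth(tree, depth = 1, subsetThreshold = 20,
                        subsetDepth = 3)
  expect_setequal(cut$protein, rownames(m))
  expect_true(any(grepl("\\.", cut$cluster)))          # sub-labels present
  expect_true(all(cut$nodeDepth %in% c(1, 3)))
  sizes <- table(cut$cluster)
  expect_true(all(sizes[grepl("\\.", names(sizes))] <= 40))
})

test_that("hypergeometric enrichment matches closed forms and enumeration", {
  universe <- sprintf("g%02d", 1:20)
  term <- universe[1:5]
  res <- enrichTerms(universe[1:5], list(hit = term), universe)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  # no overlap: p near 1; term = universe: p = 1
  res0 <- enrichTerms(universe[6:10], list(hit = term, all = universe),
                      universe)
  expect_equal(res0$p[res0$term == "all"], 1)
  expect_gt(res0$p[res0$term == "hit"], 0.9)
  expect_error(enrichTerms("g01", list(t = "g01"), character(0)), "universe")
  expect_error(enrichTerms("zz", list(t = "g01"), universe), "subset")
  set.seed(33)
  for (i in 1:25) {
    N <- sample(8:25, 1)
    uni <- sprintf("u%02d", seq_len(N))
    term <- sample(uni, sample(1:N, 1))
    clus <- sample(uni, sample(1:N, 1))
    p <- enrichTerms(clus, list(tm = term), uni)$p
    k <- length(intersect(term, clus))
    expect_equal(p, oracleHyper(k, length(term), N, length(clus)),
                 tolerance = 1e-12)
  }
})

test_that("GMT round trip and Newick export work", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\t-\tg2\tg4"), gmt)
  sets <- readGmt(gmt)
  expect_identical(sets, list(setA = c("g1", "g2", "g3"),
                              setB = c("g2", "g4")))
  m <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("p", 1:4), NULL))
  nwk <- tempfile(fileext = ".nwk")
  writeNewick(hclusterProteins(m, distance = "euclidean"), nwk)
  tr <- ape::read.tree(nwk)
  expect_setequal(tr$tip.label, paste0("p", 1:4))
})
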