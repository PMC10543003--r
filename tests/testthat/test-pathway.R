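test_that("DRPS is the largest abundance span over measured entities", {
  expect_equal(reactionDrps(matrix(1, 3, 4)), 0)
  e <- rbind(e1 = c(1, 4, 2), e2 = c(0, 0, 5))
  expect_equal(reactionDrps(e), 5)
  expect_equal(reactionDrps(matrix(3, 1, 1)), 0)   # single sample: no pair
  expect_equal(reactionDrps(NULL), 0)
  expect_equal(reactionDrps(c(1, NA, 4)), 3)       # missing values skipped
})

test_that("DPPS is the root-mean-square of reaction scores", {
  vals <- rbind(a = c(0, 3), b = c(0, 4), c = c(1, 1))
  colnames(vals) <- c("s1", "s2")
  m1 <- PathwayModel(list(p = list(name = "p",
                                   reactions = list(r1 = "a"))))
  expect_equal(pathwayDpps(m1, "p", vals), 3)  # sqrt(3^2 / 1)
  m2 <- PathwayModel(list(p = list(name = "p",
                                   reactions = list(r1 = "a", r2 = "b"))))
  expect_equal(pathwayDpps(m2, "p", vals), sqrt(12.5), tolerance = 1e-12)
  # an unmeasured reaction scores 0 but stays in the denominator
  m3 <- PathwayModel(list(p = list(name = "p",
                                   reactions = list(r1 = "a", r2 = "b",
                                                    r3 = "zz"))))
  expect_equal(pathwayDpps(m3, "p", vals), sqrt(25 / 3), tolerance = 1e-12)
  expect_error(PathwayModel(list(p = list(name = "p",
                                          reactions = list()))),
               "at least 1 reaction")
})

test_that("DRPS/DPPS match exhaustive oracles on random models", {
  set.seed(40)
  for (i in 1:60) {
    nE <- sample(1:5, 1); nS <- sample(1:10, 1)
    vals <- matrix(rnorm(nE * nS), nE, nS,
                   dimnames = list(sprintf("e%d", seq_len(nE)), NULL))
    expect_equal(reactionDrps(vals), oracleDrps(vals), tolerance = 1e-12)
    # max-over-pairs equals max - min
    v <- vals[1, ]
    if (nS >= 2) expect_equal(oracleDrps(v), max(v) - min(v),
                              tolerance = 1e-12)
  }
})

test_that("DPPS invariances: global shift and monotonicity", {
  set.seed(41)
  ents <- sprintf("e%d", 1:8)
  vals <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(ents, NULL))
  model <- PathwayModel(list(p = list(name = "p",
                                      reactions = list(r1 = ents[1:3],
                                                       r2 = ents[4:5],
                                                       r3 = ents[6:8]))))
  d0 <- pathwayDpps(model, "p", vals)
  expect_equal(pathwayDpps(model, "p", vals + 7), d0, tolerance = 1e-12)
  # widening one entity's span never decreases the pathway score
  vals2 <- vals
  vals2[1, which.max(vals[1, ])] <- max(vals[1, ]) + 2
  expect_gte(pathwayDpps(model, "p", vals2), d0)
})

test_that("pathway ranking orders by score with alphabetical ties", {
  vals <- matrix(0, 2, 3, dimnames = list(c("a", "b"), NULL))
  model <- PathwayModel(list(
    zeta = list(name = "z", reactions = list(r = "a")),
    alpha = list(name = "a", reactions = list(r = "b"))))
  rk <- rankPathways(model, vals)
  expect_identical(rk$pathway, c("alpha", "zeta"))  # all zero: alphabetical
  expect_true(all(rk$dpps == 0))
  vals["b", ] <- c(0, 2, 0)
  rk2 <- rankPathways(model, vals)
  expect_identical(rk2$pathway[1], "alpha")
  expect_equal(rk2$rank, 1:2)
  expect_equal(nrow(rankPathways(model, vals, topN = 10)), 2)
})

test_that("leave-out re-ranking recomputes scores without the masked entities", {
  set.seed(42)
  ids <- sprintf("e%02d", 1:12)
  vals <- matrix(rnorm(12 * 6, 0, 0.3), 12, 6, dimnames = list(ids, NULL))
  vals["e01", ] <- c(-3, 3, 0, 0, 0, 0)   # driver
  model <- PathwayModel(list(
    driven = list(name = "driven", reactions = list(r1 = c("e01", "e02"))),
    other = list(name = "other", reactions = list(r1 = c("e03", "e04")))))
  rr <- leaveOutRerank(model, vals, "e01")
  drv <- rr[rr$pathway == "driven", ]
  expect_equal(drv$dppsBefore, 6, tolerance = 1e-12)
  expect_equal(drv$dppsAfter,
               max(vals["e02", ]) - min(vals["e02", ]), tolerance = 1e-12)
  # removing an entity in no pathway changes nothing
  rr2 <- leaveOutRerank(model, vals, "e12")
  expect_equal(rr2$dppsBefore, rr2$dppsAfter, tolerance = 1e-12)
  expect_true(all(rr2$rankShift == 0))
  # removing every measured entity zeroes the pathway
  rr3 <- leaveOutRerank(model, vals, c("e01", "e02"))
  expect_equal(rr3$dppsAfter[rr3$pathway == "driven"], 0)
  expect_error(leaveOutRerank(model, vals, "nope"), "nope")
})

test_that("pathway models round-trip through JSON and TSV", {
  model <- PathwayModel(list(
    pw1 = list(name = "glycolysis", reactions = list(r1 = c("HXK1", "HXK2"),
                                                     r2 = "PFK1")),
    pw2 = list(name = "tca", reactions = list(r1 = character(0)))))
  js <- tempfile(fileext = ".json")
  writePathwayModel(model, js)
  back <- readPathwayModel(js)
  expect_identical(pathwayIds(back), pathwayIds(model))
  expect_identical(pathwayReactions(back, "pw1"),
                   pathwayReactions(model, "pw1"))
  expect_identical(pathwayReactions(back, "pw2")$r1, character(0))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("pathway_id\treaction_id\tentity_id",
               "pw1\tr1\tHXK1", "pw1\tr1\tHXK2", "pw1\tr2\tPFK1",
               "pw2\tr1\t"), tsv)
  tmodel <- readPathwayModel(tsv, format = "tsv")
  expect_setequal(pathwayReactions(tmodel, "pw1")$r1, c("HXK1", "HXK2"))
  expect_length(pathwayReactions(tmodel, "pw2")$r1, 0)
})
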