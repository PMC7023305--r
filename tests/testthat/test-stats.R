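test_that("exact rank-sum p-values match full enumeration on small samples", {
  expect_equal(rankSumTest(c(1, 2), c(3, 4), method = "exact"), 1 / 3)
  expect_equal(rankSumTest(c(1, 2, 3), c(4, 5, 6), method = "exact"), 0.1)
  # independent oracle: enumerate every label assignment with combn
  bruteP <- function(a, b) {
    pooled <- c(a, b); n1 <- length(a)
    r <- rank(pooled)
    w <- sum(r[seq_len(n1)])
    ws <- combn(length(pooled), n1, function(idx) sum(r[idx]))
    min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
  }
  set.seed(2)
  for (i in 1:20) {
    a <- runif(sample(2:5, 1)); b <- runif(sample(2:5, 1))
    expect_equal(rankSumTest(a, b, method = "exact"), bruteP(a, b))
  }
})

test_that("identical constant samples carry no evidence", {
  expect_equal(rankSumTest(c(3, 3, 3), c(3, 3)), 1)
})

test_that("empty samples and ties under the exact method are rejected", {
  expect_error(rankSumTest(numeric(0), 1:3), "empty")
  expect_error(rankSumTest(c(1, 2, 2), c(2, 3), method = "exact"), "tie")
})

test_that("the rank-sum test is symmetric and rank-invariant", {
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(7)
    expect_equal(rankSumTest(a, b), rankSumTest(b, a))
    # strictly monotone transform of the pooled values leaves p unchanged
    expect_equal(rankSumTest(exp(a), exp(b)), rankSumTest(a, b))
  }
})

test_that("exact and normal-approximation routes agree on tie-free 10+10 samples", {
  set.seed(7)
  diffs <- replicate(200, {
    a <- rnorm(10); b <- rnorm(10)
    abs(rankSumTest(a, b, "exact") - rankSumTest(a, b, "normal_approx"))
  })
  expect_lt(max(diffs), 0.02)
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone: sorted p implies sorted q; bounded by 1
  set.seed(5)
  p <- sort(runif(50))
  q <- bhAdjust(p)
  expect_true(all(diff(q) >= 0))
  expect_true(all(q <= 1 & q >= p[1]))
})

test_that("fold changes are oriented controls/patients with divergence flagged", {
  expect_equal(foldChange(c(2, 4, 6), c(1, 2, 3), center = "median"), 2)
  expect_equal(foldChange(c(1, 2), c(1, 2)), 1)
  expect_true(is.na(foldChange(c(1, 2), c(0, 0))))
  expect_equal(foldChange(c(0, 0), c(0, 0)), 1)
  # reciprocal under cohort swap when both defined
  a <- c(1, 5, 2); b <- c(2, 3, 9)
  expect_equal(foldChange(a, b) * foldChange(b, a), 1)
})

test_that("whole-panel testing attaches p, q and both fold changes per metabolite", {
  p <- simulateCohort(syntheticConfig(seed = 2))
  res <- testAll(imputeDataset(p)$panel)
  expect_equal(nrow(res), 768)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$q_value >= 0 & res$q_value <= 1))
  expect_equal(res$q_value, bhAdjust(res$p_value))
  up <- res$direction == "up_in_patients" & !is.na(res$fc_mean)
  expect_true(all(res$fc_mean[up] < 1))
})

test_that("testing refuses unimputed panels and degenerate cohorts", {
  expect_error(testAll(mixedClassPanel()), "impute")
  p <- buildPanel(matrix(1:8, 2), cohort = c("control", rep("patient", 3)))
  expect_error(testAll(p), "at least two")
})

test_that("per-metabolite type-I error is at nominal level on null cohorts", {
  tpl <- data.frame(sub_pathway = sprintf("SP%02d", 1:50),
                    super_pathway = "Null", n_members = 10,
                    panel = "global", imputation_class = "biological_min")
  rates <- vapply(1:5, function(s) {
    cfg <- syntheticConfig(template = tpl, lodQuantile = 0,
                           xenobioticUsageProb = 1, effects = NULL,
                           seed = 200 + s)
    res <- testAll(simulateCohort(cfg))
    mean(res$p_value < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.02)
})

test_that("volcano selection applies symmetric fold and p thresholds", {
  res <- data.frame(metabolite_id = c("m1", "m2", "m3"),
                    p_value = c(0.05, 0.01, 0.2),
                    fc_mean = c(2.5, 1.1, 0.4),
                    fc_median = c(2.5, 1.1, 0.4))
  expect_equal(volcanoSelect(res)$metabolite_id, "m1")
  expect_equal(nrow(volcanoSelect(res, fcMin = Inf)), 0)
  # monotone in thresholds: relaxing never shrinks the selection
  strict <- volcanoSelect(res, fcMin = 2, pMax = 0.1)
  relaxed <- volcanoSelect(res, fcMin = 1.5, pMax = 0.3)
  expect_true(all(strict$metabolite_id %in% relaxed$metabolite_id))
})

test_that("dichotomized FDR adjusts independently within each super-pathway", {
  res <- data.frame(metabolite_id = c("a", "b", "c"),
                    super_pathway = c("X", "Y", "Y"),
                    p_value = c(0.01, 0.01, 0.5))
  adj <- dichotomizedAdjust(res)
  expect_equal(adj$q_value, c(0.01, 0.02, 0.5))
  expect_equal(unique(adj$q_scope), "super_pathway")
  # one group degenerates to the whole-panel adjustment
  res$super_pathway <- "X"
  expect_equal(dichotomizedAdjust(res)$q_value, bhAdjust(res$p_value))
})

test_that("normalization log-transforms and autoscales per metabolite", {
  m <- matrix(c(1, 10, 100), nrow = 1)
  expect_equal(unname(normalizeMatrix(m, autoscale = FALSE)[1, ]), c(0, 1, 2))
  set.seed(6)
  m2 <- matrix(exp(rnorm(50)), nrow = 5)
  z <- normalizeMatrix(m2)
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-12))
  m3 <- rbind(m2, 7)
  expect_warning(z3 <- normalizeMatrix(m3), "zero-variance")
  expect_true(all(z3[6, ] == 0))
})

test_that("feature filtering drops the least dispersed rows stably", {
  m <- rbind(c(100, 101, 99), c(10, 15, 5), c(1, 10, 0.1))
  expect_identical(filterFeatures(m, "rsd", 0), m)
  kept <- filterFeatures(m, "rsd", 1 / 3)
  expect_equal(nrow(kept), 2)
  expect_equal(unname(kept[1, ]), c(10, 15, 5))  # the near-constant row went
  # a constant row has zero MAD/median and ranks lowest
  m4 <- rbind(c(5, 5, 5), c(1, 9, 4))
  expect_equal(unname(filterFeatures(m4, "mad_over_median", 0.5)[1, ]),
               c(1, 9, 4))
})
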