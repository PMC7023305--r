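test_that("the one-sided KS uniformity p matches the reference implementation", {
  set.seed(9)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    p <- runif(n)^sample(c(1, 2, 0.5), 1)
    ref <- suppressWarnings(
      stats::ks.test(p, "punif", alternative = "greater", exact = TRUE)$p.value)
    expect_equal(ksUniformPValue(p), ref, tolerance = 1e-10)
  }
})

test_that("the KS statistic equals the brute-force empirical-CDF maximum", {
  # D+ is the largest gap ecdf(t) - t; on small sets, scan a fine grid
  set.seed(10)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    p <- sort(runif(n))
    grid <- sort(c(p, p - 1e-12, seq(0, 1, length.out = 2000)))
    grid <- grid[grid >= 0 & grid <= 1]
    dBrute <- max(ecdf(p)(grid) - grid)
    dMine <- max(seq_len(n) / n - p)
    expect_equal(dMine, dBrute, tolerance = 1e-6)
  }
})

test_that("an anti-enriched cluster has p near 1 and no altered members", {
  res <- data.frame(metabolite_id = sprintf("m%d", 1:6),
                    p_value = rep(0.999, 6), fc_mean = 1.2)
  cl <- list(C = res$metabolite_id)
  out <- enrichClusters(res, cl)
  expect_gt(out$p_value, 0.99)
  expect_equal(out$n_altered, 0)
})

test_that("null clusters show nominal set-level type-I error", {
  set.seed(11)
  pvals <- replicate(1000, ksUniformPValue(runif(10)))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.02)
})

test_that("cluster results are invariant to metabolite order", {
  set.seed(12)
  res <- data.frame(metabolite_id = sprintf("m%d", 1:30),
                    p_value = runif(30), fc_mean = exp(rnorm(30)))
  cl <- list(A = sprintf("m%d", 1:10), B = sprintf("m%d", 11:30))
  a <- enrichClusters(res, cl)
  b <- enrichClusters(res[sample(30), ], cl)
  expect_equal(a, b)
})

test_that("adding a p = 1 member never strengthens a cluster", {
  set.seed(13)
  for (i in 1:10) {
    p <- runif(sample(4:9, 1))
    expect_gte(ksUniformPValue(c(p, 1)), ksUniformPValue(p))
  }
})

test_that("altered members split exactly into increased and decreased", {
  p <- simulateCohort(syntheticConfig(seed = 14))
  imp <- imputeDataset(p)$panel
  res <- testAll(imp)
  cl <- suppressMessages(buildClusters(annotations(imp)))
  out <- enrichClusters(res, cl)
  expect_true(all(out$n_increased + out$n_decreased == out$n_altered))
  expect_true(all(out$n_altered <= out$size))
  inCluster <- res$metabolite_id %in% unlist(cl)
  expect_equal(sum(out$n_altered),
               sum(res$p_value[inCluster] < 0.05))
})

test_that("a single cluster keeps its raw p after BH", {
  res <- data.frame(metabolite_id = sprintf("m%d", 1:5),
                    p_value = c(0.01, 0.2, 0.4, 0.6, 0.9), fc_mean = 2)
  out <- enrichClusters(res, list(only = res$metabolite_id))
  expect_equal(out$q_value, out$p_value)
})

test_that("the key compound is the smallest-p member with lexicographic ties", {
  res <- data.frame(metabolite_id = c("mB", "mA", "mC"),
                    p_value = c(0.01, 0.01, 0.5), fc_mean = 2)
  out <- enrichClusters(res, list(k = res$metabolite_id))
  expect_equal(out$key_compound, "mA")
})

test_that("cluster building partitions by sub-pathway and drops small clusters", {
  ann <- data.frame(metabolite_id = sprintf("m%d", 1:7),
                    sub_pathway = c(rep("A", 4), rep("B", 2), "C"))
  expect_message(cl <- buildClusters(ann), "2 cluster\\(s\\)")
  expect_equal(names(cl), "A")
  # an external map identical to the labels gives the same partition
  map <- data.frame(metabolite_id = ann$metabolite_id,
                    cluster = ann$sub_pathway)
  cl2 <- suppressMessages(
    buildClusters(ann, scheme = "external_map", externalMap = map))
  expect_equal(cl2, cl)
  badMap <- data.frame(metabolite_id = "zz", cluster = "A")
  expect_error(buildClusters(ann, "external_map", badMap), "zz")
})

test_that("missing member results are a hard error", {
  res <- data.frame(metabolite_id = "m1", p_value = 0.5, fc_mean = 1)
  expect_error(enrichClusters(res, list(A = c("m1", "m2", "m3"))), "m2")
  expect_error(enrichClusters(res[0, ], list(A = "m1")), "empty")
})

test_that("drug clusters are computed but flagged for report filtering", {
  res <- data.frame(metabolite_id = sprintf("m%d", 1:6),
                    p_value = runif(6), fc_mean = 1)
  cl <- list("Drug - Antibiotics" = sprintf("m%d", 1:3),
             "Acyl Cholines" = sprintf("m%d", 4:6))
  out <- enrichClusters(res, cl)
  expect_equal(out$is_drug[out$cluster == "Drug - Antibiotics"], TRUE)
  expect_equal(out$is_drug[out$cluster == "Acyl Cholines"], FALSE)
})
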