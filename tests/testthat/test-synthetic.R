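test_that("global template matches the expected panel composition", {
  tpl <- defaultTemplate("global")
  expect_equal(sum(tpl$n_members), 768)
  expect_equal(nrow(tpl), 94)
  sup <- tapply(tpl$n_members, tpl$super_pathway, sum)
  expect_equal(as.vector(sup[c("Amino Acids", "Carbohydrates",
                            "Cofactors and Vitamins", "Energy", "Lipids",
                            "Nucleotides", "Partially Characterized Molecules",
                            "Peptides", "Xenobiotics")]),
               c(196, 25, 29, 10, 259, 33, 2, 33, 181))
  expect_equal(tpl$n_members[tpl$sub_pathway == "Acyl Cholines"], 7)
  expect_equal(tpl$n_members[tpl$sub_pathway == "Androgenic Steroids"], 18)
  drugs <- grepl("Drug", tpl$sub_pathway)
  expect_equal(sum(drugs), 8)
  expect_equal(sum(tpl$n_members[drugs]), 64)
  expect_equal(tpl$n_members[tpl$sub_pathway == "Tobacco Metabolites"], 6)
  expect_true(all(tpl$imputation_class[drugs] == "structural_zero"))
})

test_that("lipid template matches the expected panel composition", {
  tpl <- defaultTemplate("lipid")
  expect_equal(sum(tpl$n_members), 1007)
  expect_equal(nrow(tpl), 19)
  expect_equal(length(unique(tpl$super_pathway)), 11)
  expect_equal(sum(tpl$n_members[tpl$super_pathway == "Triacylglycerols"]), 518)
  expect_true(all(tpl$imputation_class == "biological_min"))
})

test_that("identical configurations generate byte-identical panels", {
  cfg <- syntheticConfig(seed = 5)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(abundances(a), abundances(b))
  f1 <- tempfile(); f2 <- tempfile()
  writePanel(a, f1); writePanel(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the null configuration yields no missingness and unit median ratios", {
  # low-noise configuration: at n = 26 + 26 the sampling error of a group
  # median is ~1.25 sigma/sqrt(n), so sigma = 0.3 keeps ~97% of null median
  # ratios inside [0.8, 1.25]
  cfg <- syntheticConfig(lodQuantile = 0, xenobioticUsageProb = 1,
                         baselineLogSd = 0.3, subjectScaleSd = 0,
                         effects = NULL, seed = 8)
  p <- simulateCohort(cfg)
  expect_equal(nMissing(p), 0)
  coh <- as.character(cohorts(p))
  mat <- abundances(p)
  ratios <- vapply(seq_len(nrow(mat)), function(i)
    medianRatio(mat[i, ], coh), numeric(1))
  expect_gte(mean(ratios >= 0.8 & ratios <= 1.25), 0.95)
})

test_that("a planted two-fold effect is recovered by the averaged median ratio", {
  # a sub-pathway's member ratios share subjects, so a single cohort draw is
  # noisy; recovery is asserted on the average over a handful of cohorts
  got <- vapply(21:25, function(s) {
    cfg <- syntheticConfig(lodQuantile = 0, xenobioticUsageProb = 1,
                           effects = data.frame(sub_pathway = "Acyl Cholines",
                                                multiplier = 2, fraction = 1),
                           seed = s)
    rt <- subpathwayRatios(simulateCohort(cfg))
    rt$mean_median_ratio[rt$sub_pathway == "Acyl Cholines"]
  }, numeric(1))
  expect_lt(abs(mean(got) - 2), 0.3)
  p <- simulateCohort(syntheticConfig(seed = 21))
  expect_identical(unname(metadata(p)$trueMultiplier[
    annotations(p)$sub_pathway == "Acyl Cholines"]), rep(2, 7))
})

test_that("below-detection censoring realizes the requested missing fraction", {
  fracs <- vapply(1:10, function(s) {
    p <- simulateCohort(syntheticConfig(lodQuantile = 0.15,
                                        xenobioticUsageProb = 1,
                                        effects = NULL, seed = s))
    bio <- imputationClass(p) == "biological_min"
    mean(isMissing(p)[bio, ])
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.15), 0.02)
})

test_that("censoring is missing-not-at-random: censored cells sit below observed", {
  p <- simulateCohort(syntheticConfig(lodQuantile = 0.2, seed = 3))
  latent <- metadata(p)$latent
  miss <- isMissing(p)
  bio <- imputationClass(p) == "biological_min"
  for (i in which(bio)[1:50]) {
    if (!any(miss[i, ])) next
    expect_lt(max(latent[i, miss[i, ]]), min(latent[i, !miss[i, ]]))
  }
})

test_that("stronger planted effects give larger recovered ratios in expectation", {
  recover <- function(mult) {
    mean(vapply(1:20, function(s) {
      cfg <- syntheticConfig(
        lodQuantile = 0, xenobioticUsageProb = 1,
        effects = data.frame(sub_pathway = "Acyl Cholines",
                             multiplier = mult, fraction = 1),
        seed = 100 + s)
      rt <- subpathwayRatios(simulateCohort(cfg))
      rt$mean_median_ratio[rt$sub_pathway == "Acyl Cholines"]
    }, numeric(1)))
  }
  r <- vapply(c(1, 1.5, 2), recover, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("an effect on an unknown sub-pathway is rejected", {
  expect_error(simulateCohort(syntheticConfig(
    effects = data.frame(sub_pathway = "No Such Pathway", multiplier = 2,
                         fraction = 1))), "No Such Pathway")
})
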