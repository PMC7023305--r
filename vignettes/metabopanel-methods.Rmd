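---
title: "Case-control metabolomics panels: models and methods"
author: "MetaboPanel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-control metabolomics panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetaboPanel)
```

# The analysis problem

Vendor metabolomics panels deliver a wide abundance matrix -- hundreds to
thousands of identified compounds quantified across a modest number of
subjects -- together with a two-level chemical annotation (super-pathway /
sub-pathway) per compound. In a case--control design the questions are:
which individual compounds differ between cohorts, and, since single-compound
signals rarely survive multiple-testing correction at such sample sizes,
which chemical classes are collectively shifted. MetaboPanel implements this
pipeline end to end: class-aware imputation, per-metabolite rank statistics
with two flavours of FDR control, set-level enrichment of sub-pathway
clusters, and an inclusive median-ratio summary per sub-pathway. A synthetic
cohort generator with the same data structure makes every stage testable
without access to any particular study's data.

All fold-type quantities are oriented **controls/patients**: a value above 1
means the compound is lower in patients. Cluster tables additionally count
altered members as increased/decreased **in patients versus controls**; the
two conventions coexist in the field's reports and every output table of
this package labels its own.

# Missingness model and imputation

A missing cell has one of two causes, and conflating them corrupts
downstream statistics:

* **Structural zeros.** Drug and tobacco xenobiotics are genuinely absent
  from the blood of subjects who do not consume them. Missing values in
  these sub-pathways are imputed as 0. By default a sub-pathway is in this
  class when its name contains "Drug" or equals "Tobacco Metabolites"; the
  set is overridable because annotation vocabularies differ.
* **Below-detection censoring.** Every other compound is expected in human
  plasma; a missing value means the abundance fell below the instrument's
  limit of detection. Each missing cell is replaced by the metabolite's
  minimum *observed* value across **all** subjects, both cohorts pooled: the
  project is one quantification batch, and pooling avoids manufacturing a
  cohort difference out of the imputation itself.

`imputeDataset()` never alters an observed value, is the identity on a
complete panel, and aborts (naming the metabolite) if a biological compound
is missing in every subject, since no minimum exists. The accompanying
`ImputationReport` stratifies the biological metabolites into
complete / missing in < 20% of subjects / missing in more. The 20%
boundary itself is assigned to the lower stratum; with typical cohort sizes
the boundary is not attainable exactly, so the choice is documented but
inert. A run can also skip imputation and drop missing cells pairwise
(compute on the observed values only) as a robustness check, by testing the
unimputed matrix per metabolite after removing `NA`s manually; the package
keeps imputation an explicit, separate stage for exactly this reason.

# Per-metabolite statistics

**Test.** The two-sided Wilcoxon rank-sum test compares cohorts per
metabolite. Two routes are implemented. The default large-sample route is
the conventional one -- midranks for ties, tie-corrected variance, 0.5
continuity correction (delegated to `stats::wilcox.test`). An exact route
enumerates the permutation null of the rank-sum statistic by dynamic
programming; it requires tie-free data and is the independent oracle the
test suite compares the approximation against (they agree within 0.02 on
tie-free 10+10 samples). Two identical constant samples return p = 1 by the
no-evidence convention. Rank tests are invariant under monotone transforms,
so no log transform is applied before testing.

**FDR.** Benjamini--Hochberg over the whole panel is the default
(`q_scope = "whole_panel"`). With hundreds of tests and two dozen subjects
per arm this is conservative; `dichotomizedAdjust()` therefore re-adjusts
within each super-pathway separately, trading a family-level guarantee for
power inside smaller, chemically coherent families. Both q-values are
reported with their scope; neither is silently substituted for the other.

**Fold changes.** Mean- and median-based controls/patients ratios are both
computed; the median is preferred for summaries because panel abundances
span orders of magnitude and single outlier subjects otherwise dominate.
A ratio with a zero patient center and positive control center is reported
as undefined (`NA`) rather than clamped -- clamping would fabricate a
magnitude. Two zero centers count as no change.

**Volcano selection.** `volcanoSelect()` keeps metabolites with
p < `pMax` (strict, default 0.1) and fold change >= `fcMin` or <=
1/`fcMin` (default 2); the fold threshold is symmetric in direction.
Strict inequalities are used throughout; at these data scales the boundary
cases are measure-zero, so the choice is documented rather than
consequential.

# Sub-pathway set enrichment

The set-level question -- are a cluster's member p-values collectively
smaller than chance -- is answered with a one-sided Kolmogorov--Smirnov
test against Uniform(0, 1). With member p-values $p_{(1)} \le \dots \le
p_{(n)}$ the statistic is the largest upward excursion of their empirical
CDF,

$$D^+ = \max_i \left( \tfrac{i}{n} - p_{(i)} \right),$$

and the reported p-value is the exact finite-sample one-sided tail
$P(D^+ \ge d)$ (Birnbaum--Tingey), evaluated in log space so that clusters
of several hundred members remain numerically stable. Cluster p-values are
BH-adjusted across clusters. The statistic consumes only p-values and fold
directions, which are scale-free, so a global (relative intensity) and a
lipid (concentration) panel can be concatenated without rescaling.

Choices worth stating:

* Clusters come from the sub-pathway annotation by default
  (`buildClusters()`), or from any external two-column map; the mapping is
  an input, not something inferred from chemical structure.
* Minimum cluster size 3 (configurable): a distributional test on fewer
  points is uninformative.
* A member is *altered* when its raw p < 0.05 (configurable, strict);
  altered members split into increased/decreased in patients by the
  mean-based fold change (ratio < 1 means increased in patients). A ratio
  exactly 1 is counted with the decreased side to keep the two counts an
  exact partition of the altered set; with continuous data this tie has
  probability zero.
* The *key compound* is the member with the smallest raw p, ties broken
  lexicographically by metabolite id, making reports deterministic.
* Drug/tobacco clusters are computed like any other but flagged `is_drug`,
  so reports can filter them: differences in medication use between cohorts
  are real signals of the wrong kind.

# The inclusive sub-pathway summary

Significance-gated analyses ignore every compound lacking the identifiers
they key on. The complementary, inclusive statistic is deliberately simple:
per metabolite the controls/patients ratio of cohort medians, averaged
arithmetically over all members of each sub-pathway
(`subpathwayRatios()`). Nothing is excluded by an identifier; undefined
(divergent) member ratios are excluded from the average and counted. The
arithmetic mean of ratios is asymmetric under cohort swap -- individual
ratios reciprocate, the average of reciprocals is not the reciprocal of the
average -- so a geometric alternative sits behind the `average` flag; the
arithmetic form stays the default because it is the statistic's defining
convention. All sub-pathways are computed; the drug sub-pathways and
tobacco metabolites are flagged non-displayable by default, their
zero-imputed values making ratios meaningless for display.

# The synthetic cohort generator

`simulateCohort()` emulates the structure the analysis assumes, not any
particular instrument:

* **Composition.** `defaultTemplate("global")` describes a 768-metabolite
  panel over 9 super-pathways and 94 sub-pathways, including a 7-member
  acyl choline and an 18-member androgenic steroid sub-pathway, 8 drug
  sub-pathways (64 compounds) and 6 tobacco metabolites;
  `defaultTemplate("lipid")` a 1007-compound panel over 11 super-pathways
  and 19 sub-pathways dominated by triacylglycerols (518). Sub-pathway
  names not fixed by these headline figures are representative placeholders
  from the vendor's public vocabulary.
* **Abundance model.** Log-normal: per-metabolite baselines with log-sd 2
  (abundances span orders of magnitude), a per-subject multiplicative
  offset with log-sd 0.2 (subject scale, which is what makes median-based
  statistics non-trivially robust), and within-group noise with log-sd 1.
  The noise default is calibrated so that a planted two-fold group
  difference lands at rank-sum p-values of a few percent at n = 26 + 26 --
  the marginal-significance regime such effects occupy in real panels of
  this size, where whole-panel q-values stay unremarkable while set-level
  statistics light up.
* **Planted effects.** Multiplicative on the natural scale; patients'
  values are divided by the multiplier, so the multiplier *is* the expected
  controls/patients ratio. Defaults: acyl cholines x2.0, androgenic
  steroids x1.7, every member affected. Unaffected metabolites have
  multiplier exactly 1 (noise only) -- a modelling choice; the generator
  does not scatter small nuisance effects.
* **Missingness.** Below-detection censoring removes, per biological
  metabolite, the `round(lodQuantile * n)` smallest pooled values
  (rank-based left-censoring, so censored cells always sit below observed
  ones -- the missing-not-at-random structure minimum imputation assumes).
  Structural-zero compounds are present per cell with probability
  `xenobioticUsageProb`. The defaults (0.08 and 0.14) reproduce the
  missingness regime of vendor panels of this shape: roughly 15% of cells
  missing overall, with drug/tobacco compounds contributing about half.
* **Determinism.** One seed governs all draws through a private RNG stream;
  identical configurations produce byte-identical written panels. Ground
  truth (true multipliers, the uncensored latent matrix, the config) rides
  along in the object metadata.

What the generator does **not** emulate: batch/run-order drift,
compound-identification errors, correlated metabolite blocks beyond the
shared subject offset, heavy-tailed or skewed noise, and cohort covariate
imbalance (age, BMI). Passing tests therefore demonstrate the statistical
machinery under the stated model, not robustness to instrument artefacts.

# Numerical choices and degenerate inputs

* Exact rank-sum route: subset-sum dynamic programming over ranks; ties are
  a hard error there (the approximation handles them), and `auto` switches
  to the exact route only for pooled n <= 20 tie-free samples.
* KS tail evaluated in log space; p clamped to [0, 1]; `D+ <= 0` returns 1.
* `normalizeMatrix()` (the optional filtering/normalization path) offsets
  zeros by half the smallest positive value before the log, and sets
  zero-variance rows to all zeros with a warning rather than dividing by 0.
* `filterFeatures()` ranks with R's stable ordering, so ties keep input
  order; the drop count uses `floor` with a small epsilon against binary
  representation of fractions like 1/3.
* Percentages in report objects round half-up to one decimal, matching how
  such tables are conventionally printed.
* Written panels render cells with 17 significant digits so that
  write-then-read reproduces doubles exactly, missing cells as empty
  fields.

# Problem sizes used by the test suite

Calibration tests use 1000 null metabolites (100 sub-pathways x 10) per
cohort draw over 5--10 seeds and 1000 null clusters of size 10;
planted-effect recovery runs 10 cohorts of 26 + 26 at the full 768-compound
template; oracle agreement uses 1000 tie-free 10+10 draws. These sizes give
the binomial standard errors needed for the +/-0.02 calibration bands while
keeping the whole suite under a minute.

# Limitations

* No covariate adjustment (age, BMI): the rank test compares cohorts
  marginally, as the analysis it implements does.
* No model-based imputation (k-NN, left-censored likelihood); minimum
  substitution is simple and auditable but biases within-metabolite
  variance downward, one reason inference leans on ranks and medians.
* Enrichment assumes the cluster map partitions metabolites; overlapping
  ontologies need to be flattened first.
* Arithmetic averaging of median ratios is direction-asymmetric (see the
  geometric flag).

# A worked run

```{r example, eval = FALSE}
cfg <- pipelineConfig(outDir = "run", seed = 1)
bundle <- runPipeline(cfg)
subset(bundle$enrichment, q_value < 0.15)
```
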