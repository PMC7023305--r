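# MetaboPanel

Case–control differential-abundance analysis for annotated metabolomics
panels — the wide metabolite × subject matrices that vendor platforms
deliver with a two-level chemical annotation (super-pathway / sub-pathway)
per compound. The package is aimed at analysts working with such panels in
small case–control cohorts (tens of subjects, hundreds to thousands of
compounds), where single-compound signals rarely survive whole-panel FDR
control and the informative statistics are set-level.

## What it computes

For a panel with cohorts *C* (controls) and *P* (patients):

- **Class-aware imputation.** Missing values in drug/tobacco sub-pathways
  are structural zeros (the compound is genuinely absent) and become 0;
  every other compound is biologically expected, so a missing value is
  below-detection and becomes that metabolite's minimum observed value
  across all subjects. An `ImputationReport` audits the counts and the
  missingness strata (complete / <20% / >20% of subjects).
- **Per-metabolite statistics.** Two-sided Wilcoxon rank-sum p-values
  (conventional normal approximation with midranks, tie correction and
  continuity correction; an exact enumeration route doubles as the test
  oracle), Benjamini–Hochberg q-values over the whole panel or
  dichotomized within each super-pathway, mean- and median-based fold
  changes oriented controls/patients, and volcano selection
  (|fold| ≥ 2, p < 0.1 by default).
- **Sub-pathway set enrichment.** For each sub-pathway cluster, a
  one-sided Kolmogorov–Smirnov test of the members' raw p-values against
  Uniform(0,1): with ordered member p-values *p₍ᵢ₎*, the statistic is
  *D⁺ = maxᵢ (i/n − p₍ᵢ₎)* and the p-value is the exact Birnbaum–Tingey
  one-sided tail. Clusters are BH-adjusted, altered members (raw p < 0.05)
  are counted increased/decreased in patients, and drug clusters are
  flagged.
- **Inclusive sub-pathway summary.** Per metabolite the controls/patients
  ratio of cohort medians, averaged arithmetically within each
  sub-pathway — a summary that excludes no compound for lacking an
  identifier.
- **Synthetic cohorts.** `simulateCohort()` generates case–control panels
  with the same structure — log-normal abundances spanning orders of
  magnitude, subject-scale offsets, rank-based below-detection censoring
  (missing-not-at-random), structural-zero xenobiotics, and planted
  per-sub-pathway effects with ground truth attached — so every stage is
  testable end to end.

## Worked example

Simulate a 26 + 26 cohort on the default 768-metabolite global template
(acyl cholines planted at ×2.0, androgenic steroids at ×1.7), impute, test,
and enrich:

```r
library(MetaboPanel)

p <- simulateCohort(syntheticConfig(seed = 1))
p
#> MetaboPanel: 768 metabolites x 52 subjects
#>   cohorts: control = 26, patient = 26
#>   panels: global
#>   missing: 5890 of 39936 cells (14.7%)

imp <- imputeDataset(p)
imp$report
#> ImputationReport: 5890 of 39936 cells missing (14.7%)
#>   zero-imputed (structural): 3098  min-imputed (below detection): 2792
#>   ...

res <- testAll(imp$panel)
sum(res$p_value < 0.05)
#> [1] 51

en <- enrichClusters(res, buildClusters(annotations(imp$panel)))
subset(en, q_value < 0.15)[, 1:7]
#>              cluster size      p_value      q_value n_altered n_increased n_decreased
#>        Acyl Cholines    7 5.130366e-07 4.463419e-05         6           0           6
#>  Androgenic Steroids   18 2.239489e-05 9.741777e-04        10           0          10

rt <- subpathwayRatios(imp$panel)
subset(rt, sub_pathway %in% c("Acyl Cholines", "Androgenic Steroids"))
#>          sub_pathway super_pathway n_members n_undefined mean_median_ratio displayable
#>        Acyl Cholines        Lipids         7           0          2.690472        TRUE
#>  Androgenic Steroids        Lipids        18           0          1.812787        TRUE
```

Reading the output: about 7% of metabolites reach raw p < 0.05 — barely
above the null rate, which is why per-compound q-values are unremarkable at
this sample size — while both planted sub-pathways are recovered decisively
at the cluster level (every altered member decreased in patients) and their
averaged median ratios land near the planted 2.0 and 1.7. `runPipeline()`
wraps these stages and writes the report bundle (imputation report,
per-metabolite results, volcano selection, cluster enrichment, sub-pathway
ratios) as TSV.

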