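Package: MetaboPanel
Title: Case-Control Analysis of Annotated Metabolomics Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for case-control differential-abundance analysis of
    annotated metabolomics panels (vendor-style global and complex-lipid
    panels). Provides a SummarizedExperiment-derived container for
    metabolite-by-subject abundance matrices with super-pathway /
    sub-pathway annotations, class-aware imputation of missing values
    (structural zeros for xenobiotic drug and tobacco compounds, minimum
    substitution for below-detection biological compounds), per-metabolite
    Wilcoxon rank-sum statistics with whole-panel and super-pathway
    dichotomized false discovery rate control, fold-change and volcano
    selection, chemical-set enrichment of sub-pathway clusters via a
    one-sided Kolmogorov-Smirnov test of member p-values against the
    uniform null, averaged median-fold-change sub-pathway summaries, and a
    synthetic case-control cohort generator with missing-not-at-random
    censoring for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors
Suggests: testthat (>= 3.0.0), jsonlite, ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
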