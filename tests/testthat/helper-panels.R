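# In-code fixtures: small panels built programmatically.

# A panel from an explicit value matrix; metabolite/subject metadata filled
# with sensible defaults unless overridden.
buildPanel <- function(values, subPathway = NULL, superPathway = NULL,
                       cohort = NULL, panelKind = "global") {
  values <- as.matrix(values)
  nMet <- nrow(values); nSub <- ncol(values)
  if (is.null(subPathway)) subPathway <- rep("Glutamate Metabolism", nMet)
  if (is.null(superPathway)) superPathway <- rep("Amino Acids", nMet)
  if (is.null(cohort))
    cohort <- rep(c("control", "patient"), length.out = nSub)
  ann <- data.frame(
    metabolite_id = sprintf("m%02d", seq_len(nMet)),
    name = sprintf("compound %d", seq_len(nMet)),
    super_pathway = superPathway, sub_pathway = subPathway,
    stringsAsFactors = FALSE)
  subj <- data.frame(
    subject_id = sprintf("s%02d", seq_len(nSub)),
    cohort = cohort, stringsAsFactors = FALSE)
  MetaboPanel(values, ann, subj, panelKind = panelKind)
}

# A small mixed-class panel: two biological metabolites and one drug.
mixedClassPanel <- function() {
  vals <- rbind(c(5, NA, 2, NA),
                c(1, 2, 3, 4),
                c(NA, 7, NA, NA))
  buildPanel(vals,
             subPathway = c("Acyl Cholines", "Glutamate Metabolism",
                            "Drug - Antibiotics"),
             superPathway = c("Lipids", "Amino Acids", "Xenobiotics"))
}

# Balanced two-cohort panel with log-normal values and no missingness.
completeNullPanel <- function(nMet = 20, nPerCohort = 5, seed = 42) {
  set.seed(seed)
  vals <- matrix(exp(rnorm(nMet * 2 * nPerCohort)), nrow = nMet)
  buildPanel(vals, cohort = rep(c("control", "patient"), each = nPerCohort))
}
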