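#' Panel summary
#'
#' Bookkeeping of a panel's dimensions, chemical-class partition and
#' missingness, as produced by [summarizePanel()]. Percentages shown by the
#' `show` method are rounded half-up to one decimal.
#'
#' @slot nMetabolites,nSubjects,nCells,nMissing integer counts.
#' @slot perSuperPathway,perSubPathway named integer vectors partitioning the
#'   metabolites; each sums to `nMetabolites`.
#' @slot missingByClass named integer vector (by imputation class) summing to
#'   `nMissing`.
#' @export
setClass("PanelSummary", representation(
  nMetabolites = "integer", nSubjects = "integer", nCells = "integer",
  perSuperPathway = "integer", perSubPathway = "integer",
  nMissing = "integer", missingByClass = "integer"))

setValidity("PanelSummary", function(object) {
  msg <- character()
  if (object@nCells != object@nMetabolites * object@nSubjects)
    msg <- c(msg, "nCells must equal nMetabolites * nSubjects")
  if (object@nMetabolites > 0L) {
    if (sum(object@perSuperPathway) != object@nMetabolites)
      msg <- c(msg, "perSuperPathway must sum to nMetabolites")
    if (sum(object@perSubPathway) != object@nMetabolites)
      msg <- c(msg, "perSubPathway must sum to nMetabolites")
  }
  if (sum(object@missingByClass) != object@nMissing)
    msg <- c(msg, "missingByClass must sum to nMissing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PanelSummary", function(object) {
  cat("PanelSummary:", object@nMetabolites, "metabolites x",
      object@nSubjects, "subjects =", object@nCells, "cells\n")
  pct <- if (object@nCells > 0)
    roundHalfUp(100 * object@nMissing / object@nCells, 1) else 0
  cat(sprintf("  missing: %d (%s%%)", object@nMissing, format(pct)))
  if (object@nMissing > 0)
    cat("  [", paste(names(object@missingByClass), object@missingByClass,
                     sep = " = ", collapse = ", "), "]")
  cat("\n  super-pathways:", length(object@perSuperPathway),
      " sub-pathways:", length(object@perSubPathway), "\n")
  for (sp in names(object@perSuperPathway))
    cat(sprintf("    %s (%d)\n", sp, object@perSuperPathway[[sp]]))
  invisible(NULL)
})

#' Imputation report
#'
#' Audit of the dual imputation pass performed by [imputeDataset()]: how many
#' cells were missing, how the imputations split between structural zeros and
#' per-metabolite minimum substitution, the missingness strata of the
#' biological metabolites, and the per-cohort share of missing cells.
#'
#' @slot nCells,nMissing,nZeroImputed,nMinImputed integer counts;
#'   `nZeroImputed + nMinImputed == nMissing`.
#' @slot strata named integer vector over biological-minimum metabolites:
#'   `complete` (observed in every subject), `lt20` (missing in < 20% of
#'   subjects; exactly 20% also counts here), `ge20` (the rest).
#' @slot minImputedByStratum named integer vector: minimum-substituted cells
#'   attributed to the `lt20` / `ge20` strata.
#' @slot perCohortMissing named integer vector of missing cells by cohort.
#' @export
setClass("ImputationReport", representation(
  nCells = "integer", nMissing = "integer",
  nZeroImputed = "integer", nMinImputed = "integer",
  strata = "integer", minImputedByStratum = "integer",
  perCohortMissing = "integer"))

setValidity("ImputationReport", function(object) {
  msg <- character()
  if (object@nZeroImputed + object@nMinImputed != object@nMissing)
    msg <- c(msg, "nZeroImputed + nMinImputed must equal nMissing")
  if (!identical(names(object@strata), c("complete", "lt20", "ge20")))
    msg <- c(msg, "strata must be named complete/lt20/ge20")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ImputationReport", function(object) {
  pct <- if (object@nCells > 0)
    roundHalfUp(100 * object@nMissing / object@nCells, 1) else 0
  cat("ImputationReport:", object@nMissing, "of", object@nCells,
      sprintf("cells missing (%s%%)\n", format(pct)))
  cat("  zero-imputed (structural):", object@nZeroImputed,
      " min-imputed (below detection):", object@nMinImputed, "\n")
  cat("  biological metabolites by missingness: complete =",
      object@strata[["complete"]], ", <20% =", object@strata[["lt20"]],
      ", >=20% =", object@strata[["ge20"]], "\n")
  cat("  missing by cohort:",
      paste(names(object@perCohortMissing), object@perCohortMissing,
            sep = " = ", collapse = ", "), "\n")
  invisible(NULL)
})

#' Convert an ImputationReport to a one-row data.frame
#'
#' Used when writing the report bundle to TSV.
#' @param report an `ImputationReport`.
#' @return a one-row data.frame of the report counts.
#' @export
imputationReportFrame <- function(report) {
  stopifnot(is(report, "ImputationReport"))
  data.frame(
    n_cells = report@nCells, n_missing = report@nMissing,
    n_zero_imputed = report@nZeroImputed, n_min_imputed = report@nMinImputed,
    strata_complete = report@strata[["complete"]],
    strata_lt20 = report@strata[["lt20"]],
    strata_ge20 = report@strata[["ge20"]],
    min_imputed_lt20 = report@minImputedByStratum[["lt20"]],
    min_imputed_ge20 = report@minImputedByStratum[["ge20"]],
    missing_controls = report@perCohortMissing[["control"]],
    missing_patients = report@perCohortMissing[["patient"]],
    row.names = NULL)
}
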