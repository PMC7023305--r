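#' Classify a metabolite's imputation strategy from its sub-pathway
#'
#' Missingness in a vendor panel has two distinct causes that demand distinct
#' imputations. Drug and tobacco xenobiotics are genuinely absent from the
#' blood of subjects who do not take them: their missing values are
#' structural zeros. Every other compound is expected in human plasma, so a
#' missing value reflects abundance below the instrument's limit of
#' detection and is later replaced by the metabolite's observed minimum.
#'
#' By default a sub-pathway is structural-zero when its name contains
#' `"Drug"` (case-insensitive) or equals `"Tobacco Metabolites"`; pass
#' `structuralZeroSubPathways` to replace that rule with an explicit set,
#' since annotation vocabularies differ between datasets.
#'
#' @param subPathway character vector of sub-pathway labels.
#' @param structuralZeroSubPathways optional character vector; when supplied,
#'   exactly these sub-pathways are classed `structural_zero`.
#' @return character vector, `"structural_zero"` or `"biological_min"`.
#' @examples
#' classifyImputation(c("Tobacco Metabolites", "Acyl Cholines",
#'                      "Drug - Analgesics, Anesthetics"))
#' @export
classifyImputation <- function(subPathway, structuralZeroSubPathways = NULL) {
  subPathway <- as.character(subPathway)
  if (is.null(structuralZeroSubPathways)) {
    sz <- grepl("drug", subPathway, ignore.case = TRUE) |
      subPathway == "Tobacco Metabolites"
  } else {
    sz <- subPathway %in% structuralZeroSubPathways
  }
  ifelse(sz, "structural_zero", "biological_min")
}

#' Stratify biological metabolites by missingness
#'
#' Biological-minimum metabolites fall into three strata: observed in every
#' subject (`complete`), missing in less than 20% of subjects (`lt20`;
#' exactly 20% also lands here, the printed phrasings being strict on both
#' sides), and missing in more than 20% (`ge20`).
#'
#' @param panel a [MetaboPanel].
#' @return named integer vector `c(complete, lt20, ge20)` over the
#'   biological-minimum metabolites.
#' @export
missingnessStrata <- function(panel) {
  stopifnot(is(panel, "MetaboPanel"))
  bio <- imputationClass(panel) == "biological_min"
  frac <- rowMeans(isMissing(panel)[bio, , drop = FALSE])
  c(complete = sum(frac == 0),
    lt20 = sum(frac > 0 & frac <= 0.2),
    ge20 = sum(frac > 0.2))
}

#' Impute missing values with the dual class-aware strategy
#'
#' Structural-zero metabolites (drugs, tobacco) have their missing cells set
#' to 0. Biological-minimum metabolites have each missing cell replaced by
#' that metabolite's minimum observed value across all subjects, both cohorts
#' pooled -- the whole project is one quantification batch, so the observed
#' minimum is the best available stand-in for a below-detection value.
#' Observed values are never altered, and imputing an already-complete panel
#' is the identity.
#'
#' @param panel a [MetaboPanel], possibly with missing cells.
#' @return list with elements `panel` (complete `MetaboPanel`) and `report`
#'   (an [ImputationReport-class]).
#' @section Errors: a biological-minimum metabolite missing in every subject
#'   has no observed minimum and aborts with the metabolite named.
#' @export
imputeDataset <- function(panel) {
  stopifnot(is(panel, "MetaboPanel"))
  mat <- abundances(panel)
  cls <- imputationClass(panel)
  miss <- is.na(mat)
  nZero <- 0L; nMin <- 0L
  minByStratum <- c(lt20 = 0L, ge20 = 0L)
  nSubj <- ncol(mat)
  for (i in seq_len(nrow(mat))) {
    mi <- miss[i, ]
    if (!any(mi)) next
    if (cls[i] == "structural_zero") {
      mat[i, mi] <- 0
      nZero <- nZero + sum(mi)
    } else {
      obs <- mat[i, !mi]
      if (length(obs) == 0L)
        stop("metabolite '", rownames(mat)[i],
             "' is missing in all subjects; no minimum to impute")
      mat[i, mi] <- min(obs)
      k <- sum(mi)
      nMin <- nMin + k
      stratum <- if (k / nSubj <= 0.2) "lt20" else "ge20"
      minByStratum[stratum] <- minByStratum[stratum] + k
    }
  }
  coh <- cohorts(panel)
  perCohort <- vapply(c("control", "patient"), function(g)
    sum(miss[, coh == g, drop = FALSE]), integer(1))
  report <- new("ImputationReport",
                nCells = length(mat), nMissing = sum(miss),
                nZeroImputed = nZero, nMinImputed = nMin,
                strata = missingnessStrata(panel),
                minImputedByStratum = minByStratum,
                perCohortMissing = perCohort)
  out <- panel
  assay(out, "abundance") <- mat
  validObject(out)
  list(panel = out, report = report)
}
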