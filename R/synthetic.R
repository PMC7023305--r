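#' Default planted group effects
#'
#' The effects the simulator plants by default: acyl cholines twice as
#' abundant in controls as in patients and androgenic steroids 1.7-fold
#' higher in controls, each applied to every member of the sub-pathway.
#' Multipliers are expressed as control/patient expected-abundance ratios on
#' the natural scale.
#'
#' @return data.frame with columns `sub_pathway`, `multiplier`, `fraction`.
#' @export
defaultEffects <- function() {
  data.frame(sub_pathway = c("Acyl Cholines", "Androgenic Steroids"),
             multiplier = c(2.0, 1.7),
             fraction = c(1, 1),
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a 26 control + 26 patient plasma study quantified on a
#' vendor global panel. Abundances are log-normal with per-metabolite
#' baselines spanning several orders of magnitude (`metaboliteLogSd`),
#' per-subject multiplicative scale offsets (`subjectScaleSd`), and
#' within-group biological noise `baselineLogSd = 1` -- a level at which a
#' planted two-fold group difference reaches rank-sum p-values of a few
#' percent at n = 26 + 26, as such effects do in real panels of this size.
#' Missingness has the two real mechanisms: below-detection censoring of the
#' lowest `lodQuantile` share of each biological metabolite's values
#' (missing-not-at-random), and structural absence of drug/tobacco compounds,
#' each cell present only with probability `xenobioticUsageProb`. The
#' censoring and usage defaults (0.08, 0.14) reproduce the missingness
#' shares typical of such panels, where drug and tobacco compounds account
#' for about half of all missing cells.
#'
#' @param nControls,nPatients cohort sizes (>= 1).
#' @param template pathway template, see [defaultTemplate()].
#' @param baselineLogMean grand mean of log-abundance (natural log).
#' @param baselineLogSd within-group biological/technical log-sd (> 0).
#' @param metaboliteLogSd log-sd of per-metabolite baselines.
#' @param subjectScaleSd log-sd of the per-subject multiplicative offset.
#' @param lodQuantile fraction in `[0, 1)`: per metabolite, this share of the
#'   pooled values (the lowest ones) is censored to missing.
#' @param xenobioticUsageProb probability in `[0, 1]` that a structural-zero
#'   compound is present at all in a given subject cell.
#' @param effects data.frame of planted effects (`sub_pathway`, `multiplier`,
#'   optional `fraction` of members affected); see [defaultEffects()].
#' @param seed integer seed; identical configurations generate identical
#'   datasets.
#' @return a list of class `"syntheticConfig"`.
#' @export
syntheticConfig <- function(nControls = 26, nPatients = 26,
                            template = defaultTemplate("global"),
                            baselineLogMean = 10, baselineLogSd = 1,
                            metaboliteLogSd = 2, subjectScaleSd = 0.2,
                            lodQuantile = 0.08, xenobioticUsageProb = 0.14,
                            effects = defaultEffects(), seed = 1L) {
  stopifnot(nControls >= 1, nPatients >= 1,
            baselineLogSd > 0, metaboliteLogSd >= 0, subjectScaleSd >= 0,
            lodQuantile >= 0, lodQuantile < 1,
            xenobioticUsageProb >= 0, xenobioticUsageProb <= 1)
  if (!is.null(effects) && nrow(effects)) {
    if (!all(c("sub_pathway", "multiplier") %in% colnames(effects)))
      stop("effects need columns 'sub_pathway' and 'multiplier'")
    if (!"fraction" %in% colnames(effects)) effects$fraction <- 1
    stopifnot(all(effects$multiplier > 0),
              all(effects$fraction > 0), all(effects$fraction <= 1))
  }
  structure(list(
    nControls = as.integer(nControls), nPatients = as.integer(nPatients),
    template = template, baselineLogMean = baselineLogMean,
    baselineLogSd = baselineLogSd, metaboliteLogSd = metaboliteLogSd,
    subjectScaleSd = subjectScaleSd, lodQuantile = lodQuantile,
    xenobioticUsageProb = xenobioticUsageProb,
    effects = effects, seed = as.integer(seed)),
    class = "syntheticConfig")
}

#' Simulate a case--control panel dataset
#'
#' Draws a complete latent log-normal abundance matrix, divides patient
#' values of affected metabolites by their planted multiplier, then applies
#' the two missingness mechanisms: for each biological-minimum metabolite the
#' lowest `lodQuantile` share of its pooled values is censored to missing
#' (so missing cells always sit below observed ones -- the
#' missing-not-at-random structure minimum imputation assumes), and each
#' structural-zero cell is kept only with probability
#' `xenobioticUsageProb`. Ground truth is attached to the result's metadata:
#' `trueMultiplier` (named per-metabolite control/patient ratio), `latent`
#' (the uncensored matrix) and the generating `config`.
#'
#' @param config a [syntheticConfig()].
#' @return a [MetaboPanel] with ground-truth metadata.
#' @examples
#' panel <- simulateCohort(syntheticConfig(seed = 7))
#' panel
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  tpl <- config$template
  eff <- config$effects
  if (!is.null(eff) && nrow(eff)) {
    unknown <- setdiff(eff$sub_pathway, tpl$sub_pathway)
    if (length(unknown))
      stop("effect sub-pathway(s) not in template: ",
           paste(unknown, collapse = ", "))
  }
  ann <- templateAnnotations(tpl)
  nMet <- nrow(ann)
  nSub <- config$nControls + config$nPatients
  cohort <- rep(c("control", "patient"), c(config$nControls, config$nPatients))
  subj <- data.frame(
    subject_id = sprintf("S%02d", seq_len(nSub)),
    cohort = cohort, stringsAsFactors = FALSE)

  withSeed(config$seed, {
    metBase <- config$baselineLogMean + rnorm(nMet, 0, config$metaboliteLogSd)
    subjOffset <- rnorm(nSub, 0, config$subjectScaleSd)
    noise <- matrix(rnorm(nMet * nSub, 0, config$baselineLogSd), nMet, nSub)

    mult <- rep(1, nMet)
    names(mult) <- ann$metabolite_id
    if (!is.null(eff) && nrow(eff)) {
      for (k in seq_len(nrow(eff))) {
        members <- which(ann$sub_pathway == eff$sub_pathway[k])
        if (eff$fraction[k] < 1) {
          nPick <- max(1L, ceiling(eff$fraction[k] * length(members)))
          members <- sort(sample(members, nPick))
        }
        mult[members] <- eff$multiplier[k]
      }
    }

    latent <- exp(outer(metBase, subjOffset, "+") + noise)
    isPatient <- cohort == "patient"
    latent[, isPatient] <- latent[, isPatient] / mult

    mat <- latent
    bio <- ann$imputation_class == "biological_min"
    if (config$lodQuantile > 0) {
      # rank-based left-censoring: drop the k lowest pooled values per metabolite
      k <- as.integer(round(config$lodQuantile * nSub))
      if (k > 0) {
        for (i in which(bio)) {
          censored <- order(mat[i, ])[seq_len(k)]
          mat[i, censored] <- NA_real_
        }
      }
    }
    sz <- which(!bio)
    if (length(sz)) {
      present <- matrix(
        runif(length(sz) * nSub) < config$xenobioticUsageProb,
        length(sz), nSub)
      mat[sz, ][!present] <- NA_real_
    }

    panel <- MetaboPanel(mat, ann, subj, panelKind = tpl$panel[1])
    metadata(panel)$trueMultiplier <- mult
    metadata(panel)$latent <- latent
    metadata(panel)$config <- config
    panel
  })
}
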