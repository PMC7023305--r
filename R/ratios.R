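#' Controls/patients median ratio for one metabolite
#'
#' The median is used rather than the mean because panel abundances span
#' orders of magnitude and a single extreme subject can dominate a mean.
#' When the patient median is 0 (a zero-imputed xenobiotic taken by few
#' patients) and the control median positive, the ratio diverges and is
#' returned as `NA` (undefined) rather than clamped to a fabricated
#' magnitude; two zero medians count as no change (ratio 1).
#'
#' @param values numeric vector of one metabolite's abundances (complete).
#' @param cohort parallel vector of `"control"` / `"patient"` labels; both
#'   cohorts must be present.
#' @return median(controls) / median(patients), 1, or `NA`.
#' @export
medianRatio <- function(values, cohort) {
  cohort <- as.character(cohort)
  if (!any(cohort == "control") || !any(cohort == "patient"))
    stop("both cohorts must be present")
  .assertNumericSample(values, "values")
  mc <- stats::median(values[cohort == "control"])
  mp <- stats::median(values[cohort == "patient"])
  if (mp == 0 && mc == 0) return(1)
  if (mp == 0) return(NA_real_)
  mc / mp
}

#' Averaged median-ratio summary per sub-pathway
#'
#' The inclusive sub-pathway statistic: every metabolite's
#' controls/patients median ratio, averaged arithmetically over the members
#' of each sub-pathway. Unlike a significance-gated enrichment, no
#' metabolite is excluded by an identifier or a threshold, so the summary
#' covers the entire panel; undefined (divergent) member ratios are excluded
#' from the average and counted. All sub-pathways are computed; the
#' `displayable` flag marks those outside `exclusions` (by default the
#' drug sub-pathways and tobacco metabolites, whose zero-imputed values make
#' ratios meaningless for display).
#'
#' @param panel a complete (imputed) [MetaboPanel].
#' @param exclusions character vector of sub-pathways to flag as
#'   non-displayable; `NULL` uses the structural-zero rule of
#'   [classifyImputation()].
#' @param average `"arithmetic"` (default, matching the statistic's
#'   definition) or `"geometric"`.
#' @return data.frame with one row per sub-pathway: `sub_pathway`,
#'   `super_pathway`, `n_members`, `n_undefined`, `mean_median_ratio`,
#'   `displayable`.
#' @export
subpathwayRatios <- function(panel, exclusions = NULL,
                             average = c("arithmetic", "geometric")) {
  stopifnot(is(panel, "MetaboPanel"))
  average <- match.arg(average)
  if (anyNA(abundances(panel)))
    stop("panel contains missing values; impute first (see imputeDataset)")
  coh <- as.character(cohorts(panel))
  mat <- abundances(panel)
  ann <- annotations(panel)
  ratios <- vapply(seq_len(nrow(mat)), function(i)
    medianRatio(mat[i, ], coh), numeric(1))
  subs <- unique(ann$sub_pathway)
  if (is.null(exclusions))
    exclusions <- subs[classifyImputation(subs) == "structural_zero"]
  rows <- lapply(subs, function(sp) {
    r <- ratios[ann$sub_pathway == sp]
    defined <- r[!is.na(r)]
    avg <- if (length(defined) == 0L) NA_real_
           else if (average == "arithmetic") mean(defined)
           else exp(mean(log(defined)))
    data.frame(sub_pathway = sp,
               super_pathway = ann$super_pathway[match(sp, ann$sub_pathway)],
               n_members = length(r), n_undefined = sum(is.na(r)),
               mean_median_ratio = avg,
               displayable = !(sp %in% exclusions),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bar plot of sub-pathway median-ratio summaries
#'
#' Displays the displayable sub-pathways grouped by super-pathway, with the
#' averaged controls/patients median ratio on the y axis and a reference
#' line at 1 (no change). Requires ggplot2.
#'
#' @param ratios output of [subpathwayRatios()].
#' @return a ggplot object.
#' @export
plotSubpathwayRatios <- function(ratios) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- ratios[ratios$displayable & !is.na(ratios$mean_median_ratio), ]
  df <- df[order(df$super_pathway, df$sub_pathway), ]
  df$sub_pathway <- factor(df$sub_pathway, levels = df$sub_pathway)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sub_pathway,
                                   y = .data$mean_median_ratio,
                                   fill = .data$super_pathway)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "controls / patients (averaged median ratio)",
                  fill = "super-pathway") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
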