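#' Summarize a panel
#'
#' Counts metabolites per super- and sub-pathway (a partition: every
#' metabolite counted exactly once) and missing cells per imputation class.
#'
#' @param panel a [MetaboPanel]; an empty panel yields an all-zero summary.
#' @return a [PanelSummary-class] object.
#' @export
summarizePanel <- function(panel) {
  stopifnot(is(panel, "MetaboPanel"))
  ann <- annotations(panel)
  miss <- isMissing(panel)
  byClass <- vapply(c("structural_zero", "biological_min"), function(cl)
    sum(miss[ann$imputation_class == cl, , drop = FALSE]), integer(1))
  asCounts <- function(f) {
    tab <- table(f)
    out <- as.integer(tab)
    names(out) <- names(tab)
    out
  }
  new("PanelSummary",
      nMetabolites = nrow(panel), nSubjects = ncol(panel),
      nCells = nrow(panel) * ncol(panel),
      perSuperPathway = asCounts(ann$super_pathway),
      perSubPathway = asCounts(ann$sub_pathway),
      nMissing = sum(miss), missingByClass = byClass)
}

#' Merge two panels over the same subjects
#'
#' Row-concatenates two panels (typically a global and a complex-lipid panel
#' of the same cohort) for combined set-enrichment analyses. The subject sets
#' must coincide; columns follow the order of `a`. Colliding metabolite ids
#' are disambiguated by prefixing with the panel of origin. Per-metabolite
#' value semantics are preserved, so relative intensities and concentrations
#' coexist without rescaling.
#'
#' @param a,b [MetaboPanel] objects sharing subject ids (order may differ).
#' @return a merged `MetaboPanel` with `nrow(a) + nrow(b)` metabolites.
#' @export
mergePanels <- function(a, b) {
  stopifnot(is(a, "MetaboPanel"), is(b, "MetaboPanel"))
  if (nrow(b) == 0L) return(a)
  if (nrow(a) == 0L) return(b)
  sa <- colnames(a); sb <- colnames(b)
  if (!setequal(sa, sb)) {
    diff <- c(setdiff(sa, sb), setdiff(sb, sa))
    stop("subject sets differ; symmetric difference: ",
         paste(diff, collapse = ", "))
  }
  annA <- annotations(a)
  annB <- annotations(b)
  clash <- intersect(annA$metabolite_id, annB$metabolite_id)
  if (length(clash)) {
    annA$metabolite_id[annA$metabolite_id %in% clash] <-
      paste(annA$panel[annA$metabolite_id %in% clash],
            annA$metabolite_id[annA$metabolite_id %in% clash], sep = ":")
    annB$metabolite_id[annB$metabolite_id %in% clash] <-
      paste(annB$panel[annB$metabolite_id %in% clash],
            annB$metabolite_id[annB$metabolite_id %in% clash], sep = ":")
    if (length(intersect(annA$metabolite_id, annB$metabolite_id)))
      stop("metabolite id collision persists after panel-prefixing")
  }
  matB <- abundances(b)[, sa, drop = FALSE]
  mat <- rbind(abundances(a), matB)
  ann <- rbind(annA, annB)
  rownames(mat) <- ann$metabolite_id
  se <- SummarizedExperiment(
    assays = list(abundance = mat),
    rowData = DataFrame(ann, row.names = ann$metabolite_id),
    colData = colData(a))
  new("MetaboPanel", se)
}
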