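#' MetaboPanel: an annotated metabolite-by-subject abundance container
#'
#' `MetaboPanel` extends [SummarizedExperiment::SummarizedExperiment] for
#' case--control metabolomics panels. The single assay `"abundance"` holds
#' non-negative abundances (relative intensities for a global panel,
#' concentrations for a complex-lipid panel); a missing measurement is stored
#' as `NA`, which is a distinct state from any numeric value, including an
#' imputed zero. Row metadata carries the vendor-style two-level chemical
#' annotation (super-pathway / sub-pathway), an optional HMDB accession, the
#' panel of origin, the per-metabolite value semantics, and the imputation
#' class (`"structural_zero"` for compounds whose absence is biologically
#' genuine -- drug and tobacco xenobiotics -- versus `"biological_min"` for
#' compounds expected in every subject, whose missingness reflects
#' below-detection censoring). Column metadata carries the subject cohort
#' (`"control"` or `"patient"`) and optional age / BMI covariates.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @name MetaboPanel-class
#' @aliases MetaboPanel-class
#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @exportClass MetaboPanel
setClass("MetaboPanel", contains = "SummarizedExperiment")

.REQUIRED_ROWDATA <- c("metabolite_id", "name", "super_pathway", "sub_pathway",
                       "hmdb_id", "panel", "value_semantics", "imputation_class")

setValidity("MetaboPanel", function(object) {
  msg <- character()
  if (!"abundance" %in% assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  rd <- rowData(object)
  missingCols <- setdiff(.REQUIRED_ROWDATA, colnames(rd))
  if (length(missingCols))
    msg <- c(msg, paste0("rowData lacks column(s): ",
                         paste(missingCols, collapse = ", ")))
  if (!"cohort" %in% colnames(colData(object)))
    msg <- c(msg, "colData lacks column 'cohort'")
  else if (!all(as.character(colData(object)$cohort) %in% c("control", "patient")))
    msg <- c(msg, "cohort must be 'control' or 'patient'")
  if (length(msg) == 0L) {
    if (anyDuplicated(rd$metabolite_id))
      msg <- c(msg, "duplicate metabolite_id")
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, "duplicate subject id")
    a <- assay(object, "abundance")
    if (any(a < 0, na.rm = TRUE))
      msg <- c(msg, "negative abundance values are not allowed")
    if (!all(rd$imputation_class %in% c("structural_zero", "biological_min")))
      msg <- c(msg, "imputation_class must be structural_zero or biological_min")
    if (!all(rd$value_semantics %in% c("relative_intensity", "concentration")))
      msg <- c(msg, "value_semantics must be relative_intensity or concentration")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MetaboPanel
#'
#' @param abundance numeric matrix, metabolites in rows and subjects in
#'   columns; `NA` marks a missing measurement. Row/column names are taken
#'   from `annotations$metabolite_id` and `subjects$subject_id`.
#' @param annotations data.frame with columns `metabolite_id`, `name`,
#'   `super_pathway`, `sub_pathway`, and optionally `hmdb_id` (NA when the
#'   compound has no accession) and `imputation_class`. When
#'   `imputation_class` is absent it is derived from the sub-pathway via
#'   [classifyImputation()].
#' @param subjects data.frame with columns `subject_id`, `cohort`
#'   (`"control"`/`"patient"`), and optionally `age`, `bmi`.
#' @param panelKind `"global"` (relative intensities) or `"lipid"`
#'   (concentrations); recorded per metabolite together with the matching
#'   value semantics.
#' @param structuralZeroSubPathways passed to [classifyImputation()] when the
#'   imputation class must be derived.
#' @return a validated `MetaboPanel`.
#' @examples
#' ann <- data.frame(metabolite_id = c("m1", "m2"), name = c("A", "B"),
#'                   super_pathway = "Lipids", sub_pathway = "Acyl Cholines")
#' sub <- data.frame(subject_id = c("s1", "s2"),
#'                   cohort = c("control", "patient"))
#' m <- matrix(c(1, 2, 3, NA), nrow = 2,
#'             dimnames = list(ann$metabolite_id, sub$subject_id))
#' MetaboPanel(m, ann, sub)
#' @export
MetaboPanel <- function(abundance, annotations, subjects,
                        panelKind = c("global", "lipid"),
                        structuralZeroSubPathways = NULL) {
  panelKind <- match.arg(panelKind)
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  for (col in c("metabolite_id", "name", "super_pathway", "sub_pathway"))
    if (!col %in% colnames(annotations))
      stop("annotations lack required column '", col, "'")
  if (!all(c("subject_id", "cohort") %in% colnames(subjects)))
    stop("subjects need columns 'subject_id' and 'cohort'")
  if (anyDuplicated(annotations$metabolite_id))
    stop("duplicate metabolite_id in annotations")
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject_id in subjects")
  if (nrow(abundance) != nrow(annotations) ||
      ncol(abundance) != nrow(subjects))
    stop("abundance matrix dimensions do not match annotations/subjects")
  nAnn <- nrow(annotations)
  if (!"hmdb_id" %in% colnames(annotations))
    annotations$hmdb_id <- rep(NA_character_, nAnn)
  if (!"panel" %in% colnames(annotations))
    annotations$panel <- rep(panelKind, nAnn)
  if (!"value_semantics" %in% colnames(annotations))
    annotations$value_semantics <-
      ifelse(annotations$panel == "lipid", "concentration", "relative_intensity")
  if (!"imputation_class" %in% colnames(annotations))
    annotations$imputation_class <- classifyImputation(
      annotations$sub_pathway, structuralZeroSubPathways)
  if (!"age" %in% colnames(subjects)) subjects$age <- rep(NA_real_, nrow(subjects))
  if (!"bmi" %in% colnames(subjects)) subjects$bmi <- rep(NA_real_, nrow(subjects))
  dimnames(abundance) <- list(annotations$metabolite_id, subjects$subject_id)
  se <- SummarizedExperiment(
    assays = list(abundance = abundance),
    rowData = DataFrame(annotations[.REQUIRED_ROWDATA], row.names = annotations$metabolite_id),
    colData = DataFrame(subjects, row.names = subjects$subject_id))
  new("MetaboPanel", se)
}

#' Accessors for MetaboPanel
#'
#' @param x a `MetaboPanel`.
#' @name MetaboPanel-accessors
#' @return `cohorts`: factor of cohort labels (levels `control`, `patient`);
#'   `annotations`: data.frame of row metadata; `subjects`: data.frame of
#'   column metadata; `abundances`: the abundance matrix (`NA` = missing);
#'   `isMissing`: logical matrix; `nMissing`: count of missing cells;
#'   `imputationClass`: named character vector of imputation classes.
NULL

#' @rdname MetaboPanel-accessors
#' @export
setGeneric("cohorts", function(x) standardGeneric("cohorts"))

#' @rdname MetaboPanel-accessors
#' @export
setMethod("cohorts", "MetaboPanel", function(x)
  factor(as.character(colData(x)$cohort), levels = c("control", "patient")))

#' @rdname MetaboPanel-accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname MetaboPanel-accessors
#' @export
setMethod("annotations", "MetaboPanel", function(x)
  as.data.frame(rowData(x)))

#' @rdname MetaboPanel-accessors
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname MetaboPanel-accessors
#' @export
setMethod("subjects", "MetaboPanel", function(x)
  as.data.frame(colData(x)))

#' @rdname MetaboPanel-accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname MetaboPanel-accessors
#' @export
setMethod("abundances", "MetaboPanel", function(x) assay(x, "abundance"))

#' @rdname MetaboPanel-accessors
#' @export
setGeneric("isMissing", function(x) standardGeneric("isMissing"))

#' @rdname MetaboPanel-accessors
#' @export
setMethod("isMissing", "MetaboPanel", function(x) is.na(assay(x, "abundance")))

#' @rdname MetaboPanel-accessors
#' @export
setGeneric("nMissing", function(x) standardGeneric("nMissing"))

#' @rdname MetaboPanel-accessors
#' @export
setMethod("nMissing", "MetaboPanel", function(x)
  sum(is.na(assay(x, "abundance"))))

#' @rdname MetaboPanel-accessors
#' @export
setGeneric("imputationClass", function(x) standardGeneric("imputationClass"))

#' @rdname MetaboPanel-accessors
#' @export
setMethod("imputationClass", "MetaboPanel", function(x) {
  cls <- rowData(x)$imputation_class
  names(cls) <- rownames(x)
  cls
})

setMethod("show", "MetaboPanel", function(object) {
  n <- nrow(object) * ncol(object)
  miss <- nMissing(object)
  cat("MetaboPanel:", nrow(object), "metabolites x", ncol(object), "subjects\n")
  tab <- table(cohorts(object))
  cat("  cohorts:", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  cat("  panels:", paste(unique(rowData(object)$panel), collapse = ", "), "\n")
  cat(sprintf("  missing: %d of %d cells (%s%%)\n", miss, n,
              format(roundHalfUp(100 * miss / max(n, 1), 1))))
  invisible(NULL)
})
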