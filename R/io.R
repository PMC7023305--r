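#' Read an annotated panel from delimited text
#'
#' Panels are exchanged as delimiter-separated text (TSV by default, CSV
#' accepted). The first five columns are `metabolite_id`, `name`,
#' `super_pathway`, `sub_pathway`, `hmdb_id`; every remaining column is one
#' subject's abundances. An empty cell (or `NA`) marks a missing measurement
#' and becomes the explicit missing state. Subject metadata arrives in a
#' separate table with columns `subject_id`, `cohort`, and optionally `age`,
#' `bmi`.
#'
#' @param path panel file.
#' @param subjectsPath subject-metadata file.
#' @param panelKind `"global"` or `"lipid"`; sets the value semantics.
#' @param sep field separator, `"\t"` (default) or `","`.
#' @param structuralZeroSubPathways optional override of the sub-pathway set
#'   classed as structural zero (see [classifyImputation()]).
#' @return a validated [MetaboPanel].
#' @seealso [writePanel()] for the inverse; the two round-trip losslessly,
#'   including missing states.
#' @export
readPanel <- function(path, subjectsPath, panelKind = c("global", "lipid"),
                      sep = "\t", structuralZeroSubPathways = NULL) {
  panelKind <- match.arg(panelKind)
  if (!file.exists(path)) stop("panel file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", stringsAsFactors = FALSE)
  annCols <- c("metabolite_id", "name", "super_pathway", "sub_pathway", "hmdb_id")
  if (!all(annCols %in% colnames(raw)[seq_len(5)]))
    stop("panel header must start with: ", paste(annCols, collapse = ", "))
  subjectIds <- setdiff(colnames(raw), annCols)
  if (length(subjectIds) == 0L) stop("panel has no subject columns")
  if (anyDuplicated(raw$metabolite_id))
    stop("duplicate metabolite_id in ", path, ": ",
         paste(unique(raw$metabolite_id[duplicated(raw$metabolite_id)]),
               collapse = ", "))
  if (anyDuplicated(subjectIds))
    stop("duplicate subject id in panel header")
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = length(subjectIds),
                dimnames = list(raw$metabolite_id, subjectIds))
  for (j in seq_along(subjectIds)) {
    cell <- raw[[subjectIds[j]]]
    blank <- is.na(cell) | cell == ""
    val <- suppressWarnings(as.numeric(cell))
    bad <- !blank & is.na(val)
    if (any(bad)) {
      i <- which(bad)[1]
      stop("non-numeric abundance '", cell[i], "' at metabolite '",
           raw$metabolite_id[i], "', subject '", subjectIds[j], "'")
    }
    mat[, j] <- ifelse(blank, NA_real_, val)
  }
  ann <- raw[annCols]
  ann$hmdb_id[ann$hmdb_id == ""] <- NA_character_
  if (any(ann$sub_pathway == "" | is.na(ann$sub_pathway)))
    warning("metabolites without a sub-pathway are classed biological_min")
  subj <- readSubjects(subjectsPath, sep = sep)
  subj <- subj[match(subjectIds, subj$subject_id), , drop = FALSE]
  if (anyNA(subj$subject_id))
    stop("subjects absent from metadata: ",
         paste(setdiff(subjectIds, subj$subject_id), collapse = ", "))
  MetaboPanel(mat, ann, subj, panelKind = panelKind,
              structuralZeroSubPathways = structuralZeroSubPathways)
}

#' Read a subject-metadata table
#'
#' @param path file with columns `subject_id`, `cohort` and optionally
#'   `age`, `bmi`.
#' @param sep field separator.
#' @return data.frame of subject records.
#' @export
readSubjects <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("subject file not found: ", path)
  subj <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "cohort") %in% colnames(subj)))
    stop("subject metadata needs columns 'subject_id' and 'cohort'")
  if (anyDuplicated(subj$subject_id)) stop("duplicate subject_id")
  if (!all(subj$cohort %in% c("control", "patient")))
    stop("cohort must be 'control' or 'patient'")
  subj$subject_id <- as.character(subj$subject_id)
  subj
}

# Full-precision decimal rendering so that write -> read is lossless.
.formatCell <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a panel (and its subject metadata) as delimited text
#'
#' Inverse of [readPanel()]: cells are written at full precision and missing
#' states as empty fields, so a written panel reads back cell-for-cell
#' identical, annotations and imputation classes included.
#'
#' @param panel a [MetaboPanel].
#' @param path destination panel file.
#' @param subjectsPath optional destination for the subject-metadata table.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writePanel <- function(panel, path, subjectsPath = NULL, sep = "\t") {
  stopifnot(is(panel, "MetaboPanel"))
  ann <- annotations(panel)
  mat <- abundances(panel)
  out <- data.frame(
    metabolite_id = ann$metabolite_id, name = ann$name,
    super_pathway = ann$super_pathway, sub_pathway = ann$sub_pathway,
    hmdb_id = ifelse(is.na(ann$hmdb_id), "", ann$hmdb_id),
    check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(mat))) out[[colnames(mat)[j]]] <- .formatCell(mat[, j])
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write panel to '", path, "': ",
                        conditionMessage(ok))
  if (!is.null(subjectsPath)) {
    subj <- subjects(panel)
    utils::write.table(subj[c("subject_id", "cohort", "age", "bmi")],
                       subjectsPath, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}
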