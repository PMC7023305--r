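#' Two-sided Wilcoxon rank-sum p-value
#'
#' The workhorse per-metabolite test. Two routes are available: `"exact"`
#' enumerates the permutation null of the rank-sum statistic by dynamic
#' programming (counting, for every achievable rank-sum, the number of ways
#' to choose the first sample's ranks), which is feasible for small samples
#' and requires tie-free data; `"normal_approx"` is the conventional
#' large-sample test with midranks, tie-corrected variance and a 0.5
#' continuity correction, delegated to [stats::wilcox.test()]. `"auto"`
#' picks the exact route when the pooled size is at most 20 and there are no
#' ties. Two identical constant samples carry no evidence and return p = 1.
#'
#' @param a,b non-empty numeric samples.
#' @param method `"auto"`, `"exact"` or `"normal_approx"`.
#' @return two-sided p-value in `[0, 1]`.
#' @examples
#' rankSumTest(c(1, 2), c(3, 4), method = "exact")      # 1/3
#' rankSumTest(c(1, 2, 3), c(4, 5, 6), method = "exact") # 0.1
#' @export
rankSumTest <- function(a, b, method = c("auto", "exact", "normal_approx")) {
  method <- match.arg(method)
  .assertNumericSample(a, "a")
  .assertNumericSample(b, "b")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) return(1)
  ties <- anyDuplicated(pooled) > 0L
  if (method == "auto")
    method <- if (length(pooled) <= 20 && !ties) "exact" else "normal_approx"
  if (method == "exact") {
    if (ties) stop("exact method requires tie-free data")
    return(.exactRankSumP(a, b))
  }
  suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
}

# Exact permutation null of the rank-sum W of sample 'a' within the pooled
# ranks 1..N: count[w] = number of n1-subsets of 1..N with sum w, built by
# the standard subset-sum recurrence. Two-sided p doubles the smaller tail.
.exactRankSumP <- function(a, b) {
  n1 <- length(a); N <- length(a) + length(b)
  w <- sum(rank(c(a, b))[seq_len(n1)])
  counts <- .rankSumNullCounts(n1, N)
  wMin <- n1 * (n1 + 1) / 2
  total <- choose(N, n1)
  idx <- w - wMin + 1
  lower <- sum(counts[seq_len(idx)]) / total
  upper <- sum(counts[idx:length(counts)]) / total
  min(1, 2 * min(lower, upper))
}

.rankSumNullCounts <- function(n1, N) {
  wMin <- n1 * (n1 + 1) / 2
  wMax <- n1 * (2 * N - n1 + 1) / 2
  # dp over items 1..N choosing exactly n1, tracked per chosen-count
  dp <- vector("list", n1 + 1)
  dp[[1]] <- c(1, numeric(wMax))            # sum 0 with 0 chosen
  for (k in seq_len(n1)) dp[[k + 1]] <- numeric(wMax + 1)
  for (item in seq_len(N)) {
    for (k in rev(seq_len(min(item, n1)))) {
      src <- dp[[k]]
      shifted <- c(numeric(item), src[seq_len(wMax + 1 - item)])
      dp[[k + 1]] <- dp[[k + 1]] + shifted
    }
  }
  dp[[n1 + 1]][(wMin + 1):(wMax + 1)]
}

#' Benjamini--Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving with the input and clipped to 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fold change between cohorts
#'
#' Ratio of sample centers, oriented controls/patients: values above 1 mean
#' the compound is lower in patients. When the patient center is 0 and the
#' control center positive the ratio diverges and `NA` is returned (flagged
#' undefined rather than clamped); two zero centers count as no change
#' (ratio 1).
#'
#' @param a controls sample; @param b patients sample (both complete).
#' @param center `"mean"` or `"median"`.
#' @return positive ratio, 1, or `NA` (undefined-divergent).
#' @export
foldChange <- function(a, b, center = c("mean", "median")) {
  center <- match.arg(center)
  .assertNumericSample(a, "a")
  .assertNumericSample(b, "b")
  f <- if (center == "mean") mean else stats::median
  ca <- f(a); cb <- f(b)
  if (cb == 0 && ca == 0) return(1)
  if (cb == 0) return(NA_real_)
  ca / cb
}

#' Per-metabolite differential-abundance tests over a complete panel
#'
#' Runs the rank-sum test on every metabolite (controls vs patients),
#' adjusts over the whole panel by Benjamini--Hochberg, and computes both
#' mean- and median-based controls/patients fold changes. The reported
#' direction follows the fold-change statistic named by `center`:
#' a ratio above 1 is `down_in_patients`, below 1 `up_in_patients`.
#'
#' @param panel a complete (imputed) [MetaboPanel] with both cohorts having
#'   at least two subjects.
#' @param method passed to [rankSumTest()].
#' @param center fold-change statistic driving the `direction` column.
#' @return data.frame with one row per metabolite: annotation columns,
#'   `p_value`, `q_value`, `q_scope = "whole_panel"`, `fc_mean`,
#'   `fc_median`, `direction`.
#' @export
testAll <- function(panel, method = "auto", center = c("mean", "median")) {
  stopifnot(is(panel, "MetaboPanel"))
  center <- match.arg(center)
  if (anyNA(abundances(panel)))
    stop("panel contains missing values; impute first (see imputeDataset)")
  coh <- cohorts(panel)
  if (sum(coh == "control") < 2 || sum(coh == "patient") < 2)
    stop("both cohorts need at least two subjects")
  mat <- abundances(panel)
  ctrl <- coh == "control"; pat <- coh == "patient"
  p <- vapply(seq_len(nrow(mat)), function(i)
    rankSumTest(mat[i, ctrl], mat[i, pat], method = method), numeric(1))
  fcMean <- vapply(seq_len(nrow(mat)), function(i)
    foldChange(mat[i, ctrl], mat[i, pat], "mean"), numeric(1))
  fcMedian <- vapply(seq_len(nrow(mat)), function(i)
    foldChange(mat[i, ctrl], mat[i, pat], "median"), numeric(1))
  fc <- if (center == "mean") fcMean else fcMedian
  direction <- ifelse(is.na(fc), "down_in_patients",
               ifelse(fc > 1, "down_in_patients",
               ifelse(fc < 1, "up_in_patients", "flat")))
  ann <- annotations(panel)
  data.frame(metabolite_id = ann$metabolite_id, name = ann$name,
             super_pathway = ann$super_pathway,
             sub_pathway = ann$sub_pathway, hmdb_id = ann$hmdb_id,
             p_value = p, q_value = bhAdjust(p), q_scope = "whole_panel",
             fc_mean = fcMean, fc_median = fcMedian, direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Volcano selection
#'
#' Joint thresholding on fold-change magnitude and p-value. "Absolute"
#' fold change is symmetric in direction: a metabolite passes when its
#' controls/patients ratio is at least `fcMin` or at most `1/fcMin`, and its
#' raw p-value is strictly below `pMax`. Metabolites with an undefined
#' (divergent) ratio are not selected.
#'
#' @param results output of [testAll()].
#' @param fcMin fold-change threshold (default 2).
#' @param pMax p-value threshold (default 0.1), strict.
#' @param center which fold-change column to threshold.
#' @return the selected subset of `results`.
#' @export
volcanoSelect <- function(results, fcMin = 2, pMax = 0.1,
                          center = c("mean", "median")) {
  center <- match.arg(center)
  fc <- if (center == "mean") results$fc_mean else results$fc_median
  keep <- !is.na(fc) & (fc >= fcMin | fc <= 1 / fcMin) & results$p_value < pMax
  results[keep, , drop = FALSE]
}

#' Super-pathway dichotomized FDR adjustment
#'
#' Re-adjusts p-values independently within each annotation group (by
#' default the super-pathway), regaining power in a large panel measured on
#' a small cohort: each group's multiple-testing burden is its own size
#' rather than the whole panel's. Row order is preserved.
#'
#' @param results output of [testAll()].
#' @param grouping column of `results` to split on.
#' @return `results` with `q_value` recomputed per group and
#'   `q_scope = "super_pathway"` (or the grouping column's name).
#' @export
dichotomizedAdjust <- function(results, grouping = "super_pathway") {
  if (!grouping %in% colnames(results))
    stop("no column '", grouping, "' in results")
  g <- results[[grouping]]
  if (anyNA(g)) stop("every metabolite needs a '", grouping, "' value")
  q <- numeric(nrow(results))
  for (grp in unique(g)) {
    idx <- g == grp
    q[idx] <- bhAdjust(results$p_value[idx])
  }
  results$q_value <- q
  results$q_scope <- grouping
  results
}

#' Log-transform and autoscale an abundance matrix
#'
#' The normalization pair used by metabolomics statistics front-ends: an
#' elementwise log (base 10 by default) followed by per-metabolite
#' autoscaling (mean-centering and division by the standard deviation of
#' each row). Zeros introduced by structural-zero imputation are offset by
#' half the smallest positive value of the matrix before the log. A
#' zero-variance row cannot be autoscaled and is set to all zeros with a
#' warning.
#'
#' @param mat numeric matrix, metabolites in rows.
#' @param logTransform,autoscale logical switches.
#' @param logBase base of the logarithm.
#' @return transformed matrix.
#' @export
normalizeMatrix <- function(mat, logTransform = TRUE, autoscale = TRUE,
                            logBase = 10) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("matrix contains missing values; impute first")
  if (logTransform) {
    if (any(mat < 0)) stop("log transform requires non-negative values")
    if (any(mat == 0)) {
      pos <- mat[mat > 0]
      if (length(pos) == 0L) stop("all-zero matrix cannot be log transformed")
      mat[mat == 0] <- min(pos) / 2
    }
    mat <- log(mat, base = logBase)
  }
  if (autoscale) {
    centered <- mat - rowMeans(mat)
    sds <- apply(mat, 1, stats::sd)
    flat <- sds == 0
    if (any(flat)) {
      warning(sum(flat), " zero-variance row(s) set to 0 during autoscaling")
      sds[flat] <- 1
    }
    mat <- centered / sds
  }
  mat
}

#' Filter metabolites by a dispersion statistic
#'
#' Ranks rows by interquartile range, relative standard deviation (sd/mean)
#' or its non-parametric analogue (MAD/median) and removes the least
#' dispersed `dropFraction` of them -- the near-constant features that
#' contribute noise but no signal. Ties keep input order (stable ranking).
#'
#' @param mat numeric matrix, metabolites in rows.
#' @param method `"iqr"`, `"rsd"` or `"mad_over_median"`.
#' @param dropFraction fraction in `[0, 1)` of rows to drop.
#' @return the filtered matrix.
#' @export
filterFeatures <- function(mat, method = c("iqr", "rsd", "mad_over_median"),
                           dropFraction = 0) {
  method <- match.arg(method)
  stopifnot(dropFraction >= 0, dropFraction < 1)
  mat <- as.matrix(mat)
  if (dropFraction == 0 || nrow(mat) == 0L) return(mat)
  stat <- switch(method,
    iqr = apply(mat, 1, stats::IQR),
    rsd = apply(mat, 1, function(x) stats::sd(x) / mean(x)),
    mad_over_median = apply(mat, 1, function(x)
      stats::mad(x) / stats::median(x)))
  k <- floor(dropFraction * nrow(mat) + 1e-9)
  if (k == 0L) return(mat)
  drop <- utils::head(order(stat), k)   # order() is stable: ties keep input order
  mat[-drop, , drop = FALSE]
}
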