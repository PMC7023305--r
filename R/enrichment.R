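#' One-sided Kolmogorov--Smirnov uniformity p-value for a p-value set
#'
#' The set-level statistic behind chemical-class enrichment: if a cluster's
#' member p-values are draws from Uniform(0, 1) (no signal), their empirical
#' CDF should not run above the diagonal. The statistic is
#' `D+ = max_i (i/n - p_(i))`, the largest upward excursion of the empirical
#' CDF, and the returned p-value is the exact one-sided tail
#' `P(D+ >= d)` under the continuous uniform null, computed by the
#' Birnbaum--Tingey finite-sample formula (evaluated in log space for
#' numerical stability at large n):
#' `P(D+ > d) = d * sum_j C(n, j) (j/n + d)^(j-1) (1 - d - j/n)^(n-j)`
#' over `j = 0 .. floor(n (1 - d))`.
#'
#' @param p numeric vector of member p-values in `[0, 1]`.
#' @return one-sided p-value: small when the members are collectively
#'   shifted toward 0.
#' @examples
#' ksUniformPValue(c(0.001, 0.02, 0.03, 0.2))
#' @export
ksUniformPValue <- function(p) {
  if (length(p) == 0L) stop("empty p-value set")
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  d <- max(seq_len(n) / n - sort(p))
  if (d <= 0) return(1)
  if (d >= 1) return(0)
  jmax <- floor(n * (1 - d))
  j <- 0:jmax
  # log-space evaluation; the j = 0 term reduces to (1 - d)^n
  logTerms <- lchoose(n, j) +
    ifelse(j == 0, -log(d), (j - 1) * log(j / n + d)) +
    (n - j) * log1p(-(d + j / n))
  logTerms[is.nan(logTerms) | is.infinite(logTerms)] <- -Inf
  pv <- d * sum(exp(logTerms))
  min(1, max(0, pv))
}

#' Build metabolite clusters from annotations
#'
#' Partitions metabolites into clusters, either by their sub-pathway
#' annotation or by an externally supplied two-column map. Clusters smaller
#' than `minSize` are uninformative for a distributional set test and are
#' dropped (with a message reporting how many).
#'
#' @param annotations annotation data.frame (see
#'   [MetaboPanel-accessors]) with `metabolite_id` and `sub_pathway`.
#' @param scheme `"sub_pathway"` or `"external_map"`.
#' @param externalMap for `scheme = "external_map"`: data.frame with columns
#'   `metabolite_id`, `cluster`. Ids absent from `annotations` are an error.
#' @param minSize minimum cluster size retained (default 3).
#' @return named list of metabolite-id character vectors.
#' @export
buildClusters <- function(annotations, scheme = c("sub_pathway", "external_map"),
                          externalMap = NULL, minSize = 3) {
  scheme <- match.arg(scheme)
  if (scheme == "sub_pathway") {
    map <- split(annotations$metabolite_id, annotations$sub_pathway)
  } else {
    if (is.null(externalMap) ||
        !all(c("metabolite_id", "cluster") %in% colnames(externalMap)))
      stop("external_map scheme needs a map with columns metabolite_id, cluster")
    unknown <- setdiff(externalMap$metabolite_id, annotations$metabolite_id)
    if (length(unknown))
      stop("external map references unknown metabolite id(s): ",
           paste(unknown, collapse = ", "))
    map <- split(externalMap$metabolite_id, externalMap$cluster)
  }
  small <- vapply(map, length, integer(1)) < minSize
  if (any(small))
    message(sum(small), " cluster(s) below minimum size ", minSize, " dropped")
  map[!small]
}

#' Chemical-set enrichment of metabolite clusters
#'
#' For each cluster, tests whether its members' raw p-values are
#' collectively smaller than uniform ([ksUniformPValue()]), adjusts across
#' clusters by Benjamini--Hochberg, and tabulates the altered members (raw
#' `p < alphaAltered`) split by fold direction. Direction is read off the
#' mean-based controls/patients ratio and reported patients-vs-controls:
#' a ratio below 1 counts as increased in patients. The cluster's key
#' compound is its smallest-p member (ties broken lexicographically by
#' metabolite id). Drug/tobacco clusters are computed like any other but
#' flagged, so reports can filter them.
#'
#' @param results per-metabolite results from [testAll()] (global, lipid, or
#'   both concatenated -- the statistic only consumes p-values and
#'   directions, which are scale-free).
#' @param clusters named list from [buildClusters()]; every member must have
#'   a row in `results`.
#' @param alphaAltered threshold on raw member p-values (default 0.05,
#'   strict).
#' @return data.frame with one row per cluster: `cluster`, `size`,
#'   `p_value`, `q_value`, `n_altered`, `n_increased`, `n_decreased`,
#'   `key_compound`, `is_drug`.
#' @export
enrichClusters <- function(results, clusters, alphaAltered = 0.05) {
  if (nrow(results) == 0L) stop("empty results")
  if (length(clusters) == 0L) stop("no clusters to test")
  idx <- match(unlist(clusters, use.names = FALSE), results$metabolite_id)
  if (anyNA(idx)) {
    missingIds <- unlist(clusters, use.names = FALSE)[is.na(idx)]
    stop("cluster member(s) without a test result: ",
         paste(unique(missingIds), collapse = ", "))
  }
  rows <- lapply(names(clusters), function(cl) {
    members <- results[match(clusters[[cl]], results$metabolite_id), ,
                       drop = FALSE]
    altered <- members$p_value < alphaAltered
    inc <- altered & !is.na(members$fc_mean) & members$fc_mean < 1
    dec <- altered & !inc
    best <- members$metabolite_id[order(members$p_value,
                                        members$metabolite_id)][1]
    data.frame(cluster = cl, size = nrow(members),
               p_value = ksUniformPValue(members$p_value),
               n_altered = sum(altered), n_increased = sum(inc),
               n_decreased = sum(dec), key_compound = best,
               is_drug = classifyImputation(cl) == "structural_zero",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bhAdjust(out$p_value)
  out[c("cluster", "size", "p_value", "q_value", "n_altered",
        "n_increased", "n_decreased", "key_compound", "is_drug")]
}
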