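#' Pipeline configuration
#'
#' Collects every threshold of the analysis as an explicit, logged
#' parameter: the altered-member alpha (0.05), volcano fold-change and
#' p-value thresholds (2 and 0.1), the set-level q cutoff (0.15), the
#' fold-change center used for reporting, the cluster scheme and the
#' minimum cluster size. Panels are either read from files (`globalPath` /
#' `lipidPath` + `subjectsPath`) or simulated from `simulateGlobal` /
#' `simulateLipid` configurations.
#'
#' @param outDir directory for the report bundle (created if needed).
#' @param globalPath,lipidPath,subjectsPath optional input files (TSV).
#' @param simulateGlobal,simulateLipid optional [syntheticConfig()] objects;
#'   used when the matching path is `NULL`.
#' @param alphaAltered,volcanoFcMin,volcanoPMax,qCutoff thresholds.
#' @param fcCenter `"mean"` or `"median"` for reporting direction.
#' @param minClusterSize minimum enrichment cluster size.
#' @param seed integer seed governing any simulation.
#' @return a list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(outDir,
                           globalPath = NULL, lipidPath = NULL,
                           subjectsPath = NULL,
                           simulateGlobal = NULL, simulateLipid = NULL,
                           alphaAltered = 0.05, volcanoFcMin = 2,
                           volcanoPMax = 0.1, qCutoff = 0.15,
                           fcCenter = c("mean", "median"),
                           minClusterSize = 3, seed = 1L) {
  fcCenter <- match.arg(fcCenter)
  stopifnot(alphaAltered > 0, alphaAltered < 1,
            volcanoFcMin >= 1, volcanoPMax > 0, volcanoPMax <= 1,
            qCutoff > 0, qCutoff <= 1, minClusterSize >= 1)
  if (is.null(globalPath) && is.null(simulateGlobal))
    simulateGlobal <- syntheticConfig(seed = seed)
  structure(list(outDir = outDir, globalPath = globalPath,
                 lipidPath = lipidPath, subjectsPath = subjectsPath,
                 simulateGlobal = simulateGlobal,
                 simulateLipid = simulateLipid,
                 alphaAltered = alphaAltered, volcanoFcMin = volcanoFcMin,
                 volcanoPMax = volcanoPMax, qCutoff = qCutoff,
                 fcCenter = fcCenter, minClusterSize = minClusterSize,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

.loadStagePanel <- function(path, subjectsPath, simConfig, kind) {
  if (!is.null(path)) {
    if (is.null(subjectsPath))
      stop("stage '", kind, "': a panel path needs a subjectsPath")
    readPanel(path, subjectsPath, panelKind = kind)
  } else if (!is.null(simConfig)) {
    simulateCohort(simConfig)
  } else NULL
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load -> impute -> per-metabolite tests -> combined
#' cluster enrichment -> sub-pathway median-ratio summary, and writes the
#' report bundle as TSV into `config$outDir`: `imputation_report.tsv`,
#' `metabolite_results.tsv` (per-metabolite statistics; fold changes
#' oriented controls/patients), `volcano_selection.tsv`,
#' `cluster_enrichment.tsv` (increased/decreased counted patients vs
#' controls), `subpathway_ratios.tsv`, and `run_log.txt` recording the
#' package version, seed and thresholds. Identical configuration and seed
#' produce a byte-identical bundle.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, a list with the in-memory stage outputs: `panels`
#'   (imputed), `reports`, `results`, `volcano`, `enrichment`, `ratios`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  panels <- list()
  panels$global <- stage("load global panel", .loadStagePanel(
    config$globalPath, config$subjectsPath, config$simulateGlobal, "global"))
  panels$lipid <- stage("load lipid panel", .loadStagePanel(
    config$lipidPath, config$subjectsPath, config$simulateLipid, "lipid"))
  panels <- panels[!vapply(panels, is.null, logical(1))]
  if (length(panels) == 0L) stop("no panel to analyse")

  imputed <- list(); reports <- list(); results <- list()
  for (nm in names(panels)) {
    imp <- stage(paste("impute", nm), imputeDataset(panels[[nm]]))
    imputed[[nm]] <- imp$panel
    reports[[nm]] <- imp$report
    results[[nm]] <- stage(paste("test", nm),
                           testAll(imp$panel, center = config$fcCenter))
  }
  allResults <- do.call(rbind, unname(results))
  volcano <- stage("volcano", volcanoSelect(
    allResults, fcMin = config$volcanoFcMin, pMax = config$volcanoPMax,
    center = config$fcCenter))
  combinedAnn <- do.call(rbind, lapply(unname(imputed), annotations))
  clusters <- stage("clusters", buildClusters(
    combinedAnn, scheme = "sub_pathway", minSize = config$minClusterSize))
  enrichment <- stage("enrichment", enrichClusters(
    allResults, clusters, alphaAltered = config$alphaAltered))
  ratioTabs <- lapply(names(imputed), function(nm)
    stage(paste("ratios", nm), subpathwayRatios(imputed[[nm]])))
  names(ratioTabs) <- names(imputed)

  writeTsv <- function(df, file, comment = NULL) {
    path <- file.path(config$outDir, file)
    con <- file(path, open = "wt")
    on.exit(close(con))
    if (!is.null(comment)) writeLines(paste0("# ", comment), con)
    utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  repFrame <- do.call(rbind, lapply(reports, imputationReportFrame))
  repFrame <- cbind(panel = names(reports), repFrame)
  writeTsv(repFrame, "imputation_report.tsv")
  writeTsv(allResults, "metabolite_results.tsv",
           "fold changes are controls/patients")
  writeTsv(volcano, "volcano_selection.tsv",
           "fold changes are controls/patients")
  writeTsv(enrichment, "cluster_enrichment.tsv",
           "increased/decreased refer to patients vs controls")
  ratioFrame <- do.call(rbind, lapply(names(ratioTabs), function(nm)
    cbind(panel = nm, ratioTabs[[nm]])))
  writeTsv(ratioFrame, "subpathway_ratios.tsv",
           "mean_median_ratio is controls/patients")
  writeLines(c(
    paste0("MetaboPanel ", as.character(utils::packageVersion("MetaboPanel"))),
    paste0("seed: ", config$seed),
    paste0("alpha_altered: ", config$alphaAltered),
    paste0("volcano_fc_min: ", config$volcanoFcMin),
    paste0("volcano_p_max: ", config$volcanoPMax),
    paste0("q_cutoff: ", config$qCutoff),
    paste0("fc_center: ", config$fcCenter),
    paste0("min_cluster_size: ", config$minClusterSize)),
    file.path(config$outDir, "run_log.txt"))
  invisible(list(panels = imputed, reports = reports, results = allResults,
                 volcano = volcano, enrichment = enrichment,
                 ratios = ratioFrame))
}
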