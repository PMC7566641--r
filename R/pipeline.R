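#' Analysis configuration with every threshold surfaced
#'
#' Collects the tunable constants of the pipeline under their
#' conventional defaults: 10 kbp windows, 5x depth floor, FDR 0.005,
#' 95th percentile seeds with 75% purity, 1500/500 bp promoters, 1000 bp
#' DMR bandwidth with 3 constituent CpGs, M-value clamp 0.01, and 5/95
#' TR classification percentiles.
#'
#' @param ... Named overrides.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(windowWidth = 10000, minDepth = 5, fdrThreshold = 0.005,
              pct = 95, purity = 0.75, promoterUp = 1500,
              promoterDown = 500, bandwidth = 1000, minCpgs = 3,
              eps = 0.01, pctLo = 5, pctHi = 95,
              control = "beta", case = "insulinoma")
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  structure(cfg, class = "PipelineConfig")
}

.writeTsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nrow(df)
}

#' Run the full analysis end to end
#'
#' Chains every stage on a dataset — by default a simulated one —
#' writing one TSV per stage plus bedGraph tracks and a machine-readable
#' JSON run report (config, seed, per-file row counts). The same config
#' and seed reproduce the outputs exactly.
#'
#' Stages, in dependency order: coverage filter, window grid, cohort
#' methylation profiles + ATAC overlay + profile correlations, per-CpG
#' differential test, DMR merge, group signature + direction association,
#' region calling, element catalog + CpG attribution + TR-site density,
#' promoter-expression classification, TR enrichment classification, 4C
#' loop-score overlay.
#'
#' @param outDir Output directory (created if needed).
#' @param config A [pipelineConfig()].
#' @param simCfg A [simConfig()] describing the dataset to simulate, or
#'   `NULL` when `data` is supplied.
#' @param data Optional pre-built dataset as returned by
#'   [simulateDataset()] (a list with `me`, `region`, `annotations`).
#' @param seed Integer seed for the simulation.
#' @return Invisibly, the run report (also written to
#'   `run_report.json`).
#' @export
runPipeline <- function(outDir, config = pipelineConfig(),
                        simCfg = simConfig(), data = NULL, seed = 1) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(data)) {
    if (is.null(simCfg)) stop("either 'data' or 'simCfg' is required")
    data <- simulateDataset(simCfg, seed = seed)
  }
  if (is.null(data$annotations$expression))
    stop("stage promoter-expression: no expression table in input data")
  files <- list()
  emit <- function(name, df) {
    path <- file.path(outDir, paste0(name, ".tsv"))
    files[[name]] <<- list(path = basename(path), rows = .writeTsv(df, path))
  }

  me <- coverageFilter(data$me, config$minDepth)
  grid <- makeWindows(data$region, config$windowWidth)

  ## profiles
  profCtl <- windowMethylation(me, grid, config$control)
  profCase <- windowMethylation(me, grid, config$case)
  atac <- windowAtac(data$annotations$atacPeaks, grid, data$region)
  prof <- data.frame(profCtl[, c("window", "start", "end")],
                     meanControl = profCtl$mean, ciLoControl = profCtl$ciLo,
                     ciHiControl = profCtl$ciHi, meanCase = profCase$mean,
                     ciLoCase = profCase$ciLo, ciHiCase = profCase$ciHi,
                     atac = atac$atac)
  emit("window_profiles", prof)
  corCohort <- profileCorrelation(prof$meanControl, prof$meanCase)
  corAtacCtl <- profileCorrelation(prof$meanControl, prof$atac)
  gTrack <- grid
  S4Vectors::mcols(gTrack)$score <- prof$meanCase
  writeBedGraph(gTrack[!is.na(prof$meanCase)],
                file.path(outDir, "case_methylation.bedGraph"),
                name = "case_pct_methylation")

  ## differential test and DMRs
  res <- testCpGs(me, config$control, config$case, config$fdrThreshold)
  emit("diff_cpgs", res)
  dmrs <- callDMRs(res, config$bandwidth, config$minCpgs,
                   config$fdrThreshold)
  emit("dmrs", as.data.frame(dmrs))

  ## group signature
  sigSet <- groupSignature(me, config$control)
  emit("signature_cpgs", data.frame(site_id = sigSet$signatureIds))
  assoc <- tryCatch(
    directionSignatureAssociation(res, sigSet$signatureIds),
    error = function(e) list(statistic = NA, df = NA, p = NA))

  ## regions
  counts <- windowSigCounts(res, grid)
  emit("window_sig_counts", counts)
  regions <- callRegions(counts, dmrs, chrom = unique(res$chrom)[1],
                         pct = config$pct, purity = config$purity)
  emit("regions", as.data.frame(regions))

  ## elements
  catalog <- elementCatalog(data$annotations$isoforms,
                            data$annotations$enhancers, data$region,
                            config$promoterUp, config$promoterDown)
  emit("element_cpg_counts", countSigCpGsByElement(res, catalog))
  emit("element_site_density",
       siteDensityByElement(data$annotations$trSites, catalog, res))

  ## promoter methylation vs expression
  emit("promoter_expression",
       analyzePromoterExpression(me, data$annotations$isoforms,
                                 data$annotations$expression, data$region,
                                 config$promoterUp, config$promoterDown,
                                 config$eps, config$control, config$case))

  ## TR enrichment
  trRec <- trEnrichmentAnalysis(data$annotations$trSites, cpgSites(me),
                                res, pctLo = config$pctLo,
                                pctHi = config$pctHi)
  emit("tr_enrichment", trRec)

  ## 4C overlay
  overlay <- overlayLoopScores(data$annotations$loopScores, counts, grid,
                               data$region)
  emit("loop_overlay", overlay$loops)

  report <- list(
    package = "tdmeth",
    version = as.character(utils::packageVersion("tdmeth")),
    seed = seed,
    config = unclass(config),
    nSamples = ncol(me), nCpGs = nrow(me),
    nSignificant = sum(res$significant),
    nDMRs = length(dmrs), nRegions = length(regions),
    cohortProfileR = corCohort$r,
    atacMethylationR = corAtacCtl$r,
    directionSignatureChiSq = assoc$statistic,
    files = files)
  jsonlite::write_json(report, file.path(outDir, "run_report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}
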