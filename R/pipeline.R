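stageError <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full single-cell transfer pipeline
#'
#' Composes the analysis end to end, in the fixed stage order: imaging
#' (simulate or load a multi-plane ion stack + mask) -> drift correction ->
#' plane accumulation -> per-ROI isotope ratios -> detection-limit filter ->
#' per-cell rates -> colony partition -> summary statistics. All stages are
#' deterministic given the configured seeds; every output table carries the
#' configuration hash, and a JSON manifest records the hash, seeds and stage
#' list.
#'
#' @param config a configuration list or YAML path; see
#'   [readPipelineConfig()].
#' @param outDir output directory for the run; NULL computes in memory only.
#' @return list with elements \code{measurements}, \code{detection},
#'   \code{rates}, \code{partition}, \code{activitySummary}, \code{offsets},
#'   \code{truth} (simulation ground truth, if simulated), \code{manifest}.
#' @examples
#' \donttest{
#' res <- runPipeline(list(
#'   mode = "simulate",
#'   scenario = list(organism = "nodularia", condition = "in_situ",
#'                   nEpibionts = 20, imageSize = 96, planes = 6, seed = 7)))
#' res$partition
#' }
#' @export
runPipeline <- function(config, outDir = NULL) {
  config <- readPipelineConfig(config)
  hash <- configHash(config)
  truth <- NULL

  ## stage: imaging --------------------------------------------------------
  if (identical(config$mode, "simulate")) {
    sim <- stageError("imaging", {
      sc <- config$scenario
      scenario <- colonyScenario(sc$organism, sc$condition,
                                 nEpibionts = sc$nEpibionts,
                                 imageSize = sc$imageSize, seed = sc$seed)
      drift <- if (identical(sc$drift, "random_walk"))
        randomWalkDrift(sc$planes, seed = sc$seed + 1L)
      else matrix(0L, sc$planes, 2)
      acq <- AcquisitionParams(sc$imageSize, sc$imageSize, sc$planes, drift)
      out <- simulateIonStack(scenario$scene, acq, seed = sc$seed + 2L)
      out$scenario <- scenario
      out
    })
    stack <- sim$stack
    mask <- sim$mask
    truth <- sim$scenario$truth
    cellTypes <- stats::setNames(sim$scenario$scene@cells$type,
                                 sim$scenario$scene@cells$id)
  } else if (identical(config$mode, "load")) {
    loaded <- stageError("imaging", {
      inp <- config$input
      if (is.null(inp$maskPath) || !file.exists(inp$maskPath))
        stop("mask path missing or not found: ",
             if (is.null(inp$maskPath)) "<unset>" else inp$maskPath)
      stack <- readIonStack(unlist(inp$stackPaths), pixelSize = inp$pixelSize)
      list(stack = stack, mask = readMask(inp$maskPath),
           cellTypes = if (!is.null(inp$cellTypes)) unlist(inp$cellTypes))
    })
    stack <- loaded$stack
    mask <- loaded$mask
    cellTypes <- loaded$cellTypes
  } else stop("pipeline stage 'imaging' failed: unknown mode ", config$mode)

  ## stage: drift correction + accumulation --------------------------------
  dc <- stageError("drift_correction", driftCorrect(stack))
  acc <- stageError("accumulation", accumulate(dc$stack))

  ## stage: ROI ratios ------------------------------------------------------
  measurements <- stageError("roi_ratios",
    roiRatios(acc, mask, cellTypes = cellTypes))

  ## stage: detection-limit filter -----------------------------------------
  detection <- stageError("detection_limits",
    applyDetectionLimits(measurements,
                         dlC = config$detectionLimits$C,
                         dlN = config$detectionLimits$N))

  ## stage: per-cell rates --------------------------------------------------
  lab <- config$labeling
  cond <- LabelingConditions(
    sourceFraction = c(C = lab$sourceC, N = lab$sourceN),
    naturalAbundance = c(C = lab$naturalC, N = lab$naturalN),
    duration = lab$durationDays)
  conv <- if (identical(config$conversion$type, "power"))
    list(a = config$conversion$a, b = config$conversion$b)
  else config$conversion$value
  rates <- stageError("rates", {
    m <- detection$measurements
    epi <- m$cellType %in% "epibiont"
    rbind(
      if (any(epi)) cellRates(m[epi, ], cond,
                              cnMolar = config$composition$cnMolarEpibiont,
                              conversion = conv),
      if (any(!epi)) cellRates(m[!epi, ], cond,
                               cnMolar = config$composition$cnMolarCyano,
                               conversion = conv))
  })

  ## stage: partition -------------------------------------------------------
  epiRates <- rates[rates$cellType %in% "epibiont", ]
  cyanoRates <- rates[!rates$cellType %in% "epibiont", ]
  nPerCell <- config$epibiontsPerCell
  if (is.null(nPerCell) && !is.null(truth)) nPerCell <- truth$epiPerCell
  partition <- stageError("partition", {
    if (is.null(nPerCell)) stop("epibiontsPerCell is not configured")
    if (!nrow(epiRates) || !nrow(cyanoRates))
      stop("need both epibiont and cyanobacterial cells for the partition")
    colonyPartition(epiRates, cyanoRates, nPerCell,
                    nBoot = config$bootstrap$n, seed = config$bootstrap$seed)
  })

  ## stage: stats/report ----------------------------------------------------
  activitySummary <- stageError("stats", {
    do.call(rbind, lapply(c("C", "N"), function(el) {
      x <- epiRates[[paste0("activity", el)]]
      x <- x[!is.na(x)]
      s <- summaryStats(x, nBoot = config$bootstrap$n,
                        seed = config$bootstrap$seed)
      data.frame(element = el, group = "epibiont", n = s$n,
                 median = s$median, mean = s$mean, sd = s$sd,
                 seMedian = s$seMedian)
    }))
  })

  manifest <- list(configHash = hash, config = config,
                   stages = c("imaging", "drift_correction", "accumulation",
                              "roi_ratios", "detection_limits", "rates",
                              "partition", "stats"),
                   packageVersion =
                     as.character(utils::packageVersion("simsTransfer")))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTableCsv(measurements, file.path(outDir, "roi_measurements.csv"), hash)
    writeTableCsv(rates, file.path(outDir, "cell_rates.csv"), hash)
    writeTableCsv(partition, file.path(outDir, "partition.csv"), hash)
    writeTableCsv(activitySummary, file.path(outDir, "activity_summary.csv"),
                  hash)
    writeTableCsv(as.data.frame(dc$offsets),
                  file.path(outDir, "drift_offsets.csv"), hash)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  list(measurements = measurements, detection = detection, rates = rates,
       partition = partition, activitySummary = activitySummary,
       offsets = dc$offsets, truth = truth, manifest = manifest)
}
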