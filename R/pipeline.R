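#' Analysis configuration
#'
#' Bundles every tunable of the pipeline — analysis windows, latency
#' parameters, PSTH normalization mode, decay normalization mode and
#' significance levels — into one declarative, YAML-round-trippable object
#' so that each choice is explicit and logged with the outputs.
#'
#' @param windows an [analysisWindows()] list.
#' @param latency a [latencyParams()] list.
#' @param normalizationMode PSTH normalization: \code{"divide"},
#'   \code{"subtract"} or \code{"none"}.
#' @param decayNormalization decay-series normalization mode (see
#'   [buildDecaySeries()]).
#' @param alpha significance level for cell-level tests.
#' @param seed integer seed stamped into outputs for provenance.
#' @return list with class \code{"PipelineConfig"}.
#' @export
analysisConfig <- function(windows = analysisWindows(),
                           latency = latencyParams(),
                           normalizationMode = "divide",
                           decayNormalization = "last5_probe_mean",
                           alpha = 0.05, seed = 1L) {
  normalizationMode <- match.arg(normalizationMode,
                                 c("divide", "subtract", "none"))
  decayNormalization <- match.arg(decayNormalization,
                                  c("last5_probe_mean", "peak_memory",
                                    "stim_block_mean"))
  stopifnot(alpha > 0, alpha < 1)
  structure(list(windows = windows, latency = latency,
                 normalizationMode = normalizationMode,
                 decayNormalization = decayNormalization,
                 alpha = alpha, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Save / load a pipeline configuration
#'
#' @param config a [analysisConfig()] object.
#' @param path YAML file path.
#' @return \code{saveConfig} returns \code{path} invisibly;
#'   \code{loadConfig} returns a \code{PipelineConfig} equal to the one
#'   saved (round trip is the identity).
#' @export
saveConfig <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  obj <- list(schema = "lipmemory-config-1",
              windows = unclass(config$windows),
              latency = unclass(config$latency),
              normalizationMode = config$normalizationMode,
              decayNormalization = config$decayNormalization,
              alpha = config$alpha, seed = config$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname saveConfig
#' @export
loadConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$schema) || obj$schema != "lipmemory-config-1")
    stop("unrecognized config schema in ", path)
  analysisConfig(
    windows = do.call(analysisWindows, lapply(obj$windows, unlist)),
    latency = do.call(latencyParams, obj$latency),
    normalizationMode = obj$normalizationMode,
    decayNormalization = obj$decayNormalization,
    alpha = obj$alpha, seed = obj$seed)
}

#' Simulate a dataset to disk
#'
#' Generates a synthetic population ([generatePopulation()]) and writes it
#' in the two-table CSV layout together with the ground-truth table
#' (\code{ground_truth.csv}).
#'
#' @param outDir output directory.
#' @param nCells number of units.
#' @param task \code{"basic"} or \code{"no_rf"}.
#' @param seed master seed.
#' @param memoryFraction fraction of true memory cells.
#' @param baseParams template [syntheticCellParams()].
#' @return \code{outDir}, invisibly.
#' @export
simulateDataset <- function(outDir, nCells, task = "basic", seed = 1L,
                            memoryFraction = 0.45,
                            baseParams = syntheticCellParams(task = task)) {
  baseParams$task <- task
  pop <- generatePopulation(nCells, memoryFraction = memoryFraction,
                            seed = seed, baseParams = baseParams)
  writeCells(pop$cells, outDir)
  utils::write.csv(pop$truth, file.path(outDir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(outDir)
}

## analyze one cell; errors propagate to the caller's tryCatch
.analyzeCell <- function(cell, config) {
  win <- config$windows
  lat <- config$latency
  ev <- trialEvents(cell)
  fixOn <- max(ev$fixationOnMs)
  baseTrials <- trialsWhere(cell, block = 1L)
  memTrials <- trialsWhere(cell, condition = "probe_absent_memory")
  visTrials <- trialsWhere(cell, condition = "visual_max")
  if (!length(baseTrials)) stop("no block-1 trials")
  if (!length(memTrials)) stop("no probe-absent memory trials")
  if (!length(visTrials)) stop("no visual trials")

  excl <- excludeEyePosition(cell, win, alpha = config$alpha)
  cls <- classifyMemoryCell(cell, win, alpha = config$alpha)
  idx <- if (cls$rMem + cls$rPre > 0)
    memoryIndex(cls$rMem, cls$rPre)$index else NA_real_
  pkVis <- peakResponse(visTrials, win)
  latVis <- estimateLatency(visTrials, lat, win, fixationOnMs = fixOn)
  latMem <- estimateLatency(memTrials, lat, win, fixationOnMs = fixOn)
  series <- tryCatch(buildDecaySeries(cell, win,
                                      mode = config$decayNormalization),
                     error = function(e) NULL)
  list(
    summary = data.frame(
      cell_id = cellId(cell), monkey_id = cell@monkeyId, task = cell@task,
      r_baseline = baselineActivity(baseTrials, win),
      r_pre = cls$rPre, r_memory = cls$rMem, r_visual = pkVis$rPeak,
      memory_index = idx,
      visual_latency_ms = latVis$latencyMs,
      visual_latency_method = latVis$method,
      memory_latency_ms = latMem$latencyMs,
      memory_latency_method = latMem$method,
      is_memory_cell = cls$isMemoryCell, memory_p = cls$memoryP,
      excluded_eye_position = excl$excluded, exclusion_p = excl$p,
      error = ""),
    series = series)
}

#' Analyze a dataset
#'
#' Runs the full quantification on every cell: eye-position exclusion,
#' baseline/visual/memory response metrics, memory index, latency
#' estimation by both methods, memory-cell classification, and the
#' population summary (proportion of memory cells, index median,
#' medcouple, median-shift test) computed over the non-excluded cells.
#' The population forgetting decay is fit on the across-cell mean of the
#' per-cell normalized decay series. Cells that fail validation or lack
#' required blocks are reported with an error reason and skipped; the run
#' continues for the remaining cells. Deterministic given data and config.
#'
#' @param input directory written by [simulateDataset()] / [writeCells()],
#'   or a list of \linkS4class{CellRecording} objects.
#' @param config a [analysisConfig()] object.
#' @param outDir optional directory; when given, writes
#'   \code{cell_summary.csv}, \code{population_summary.csv},
#'   \code{decay.csv} and the resolved \code{config.yaml}.
#' @return list with \code{cellSummary} (one row per cell),
#'   \code{populationSummary} (one row), \code{decay} (population decay
#'   trace and fit) and \code{errors} (named reasons for skipped cells).
#' @export
analyzeDataset <- function(input, config = analysisConfig(),
                           outDir = NULL) {
  cells <- if (is.character(input)) readCells(input) else input
  rows <- list()
  seriesList <- list()
  errors <- character(0)
  for (cell in cells) {
    res <- tryCatch(.analyzeCell(cell, config), error = function(e) e)
    if (inherits(res, "error")) {
      errors[cellId(cell)] <- conditionMessage(res)
      rows[[cellId(cell)]] <- data.frame(
        cell_id = cellId(cell), monkey_id = cell@monkeyId,
        task = cell@task, r_baseline = NA_real_, r_pre = NA_real_,
        r_memory = NA_real_, r_visual = NA_real_, memory_index = NA_real_,
        visual_latency_ms = NA_real_, visual_latency_method = "none",
        memory_latency_ms = NA_real_, memory_latency_method = "none",
        is_memory_cell = NA, memory_p = NA_real_,
        excluded_eye_position = NA, exclusion_p = NA_real_,
        error = conditionMessage(res))
    } else {
      rows[[cellId(cell)]] <- res$summary
      if (!is.null(res$series)) seriesList[[cellId(cell)]] <- res$series
    }
  }
  cellSummary <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  ok <- !is.na(cellSummary$memory_index) &
    cellSummary$excluded_eye_position %in% FALSE
  popSummary <- NULL
  if (sum(ok) > 0) {
    s <- summarizePopulation(cellSummary$memory_index[ok],
                             cellSummary$is_memory_cell[ok])
    popSummary <- data.frame(
      task = cellSummary$task[1], n_total = s$nTotal, n_memory = s$nMemory,
      proportion_memory = s$proportionMemory, index_median = s$indexMedian,
      medcouple = s$medcouple, median_shift_p = s$medianShiftP)
  }

  decay <- NULL
  okSeries <- seriesList[names(seriesList) %in%
                           cellSummary$cell_id[ok]]
  if (length(okSeries) > 0 &&
      min(vapply(okSeries, function(s) length(s$normalized),
                 integer(1))) >= 10L)
    decay <- populationDecay(okSeries)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cellSummary, file.path(outDir, "cell_summary.csv"),
                     row.names = FALSE, na = "")
    if (!is.null(popSummary)) {
      ps <- popSummary
      if (!is.null(decay)) {
        ps$decay_k <- decay$fit$k
        ps$decay_r_squared <- decay$fit$rSquared
        ps$decay_first_last_p <- decay$firstLastP
      }
      utils::write.csv(ps, file.path(outDir, "population_summary.csv"),
                       row.names = FALSE, na = "")
    }
    if (!is.null(decay))
      utils::write.csv(
        data.frame(trial_ordinal = seq_along(decay$meanSeries) - 1L,
                   mean_normalized_activity = decay$meanSeries,
                   fitted_value = decay$fit$fitted),
        file.path(outDir, "decay.csv"), row.names = FALSE)
    saveConfig(config, file.path(outDir, "config.yaml"))
  }
  list(cellSummary = cellSummary, populationSummary = popSummary,
       decay = decay, errors = errors)
}

#' Score analysis outputs against ground truth
#'
#' Joins the per-cell summary with the generator's ground-truth table and
#' reports classification sensitivity/specificity and, for true memory
#' cells with an estimated memory latency, the latency bias and RMSE.
#'
#' @param cellSummary per-cell summary from [analyzeDataset()].
#' @param truth ground-truth data.frame from [generatePopulation()] or
#'   \code{ground_truth.csv}.
#' @return one-row data.frame with \code{n_cells}, \code{sensitivity},
#'   \code{specificity}, \code{latency_bias_ms}, \code{latency_rmse_ms}.
#' @export
recoveryReport <- function(cellSummary, truth) {
  m <- merge(cellSummary, truth, by = "cell_id",
             suffixes = c("_est", "_true"))
  if (nrow(m) == 0L) stop("recoveryReport: no cell_ids in common")
  estLat <- if ("memory_latency_ms_est" %in% names(m))
    m$memory_latency_ms_est else m$memory_latency_ms
  trueLat <- if ("memory_latency_ms_true" %in% names(m))
    m$memory_latency_ms_true else rep(NA_real_, nrow(m))
  pred <- m$is_memory_cell %in% TRUE
  isMem <- m$is_memory_true
  sens <- if (any(isMem)) mean(pred[isMem]) else NA_real_
  spec <- if (any(!isMem)) mean(!pred[!isMem]) else NA_real_
  d <- (estLat - trueLat)[isMem]
  d <- d[is.finite(d)]
  data.frame(n_cells = nrow(m), sensitivity = sens, specificity = spec,
             latency_bias_ms = if (length(d)) mean(d) else NA_real_,
             latency_rmse_ms = if (length(d)) sqrt(mean(d^2)) else NA_real_)
}
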