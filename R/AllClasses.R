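#' @import methods
NULL

## Block/condition layout for the two task designs. All analyses are aligned
## to saccade onset (t = 0); presaccadic times are negative.
.TASKS <- c("basic", "no_rf")
.CONDITIONS <- c("baseline", "visual_max", "probe_present_mixed",
                 "probe_absent_memory", "forget")
.SACCADES <- c("s1", "s2")

## condition -> block id, per task
.LAYOUT <- list(
  basic = c(baseline = 1L, visual_max = 2L, probe_present_mixed = 3L,
            probe_absent_memory = 3L, forget = 4L),
  no_rf = c(baseline = 1L, probe_present_mixed = 2L,
            probe_absent_memory = 2L, forget = 3L, visual_max = 4L)
)

## condition -> saccade id, per task
.SACCADE_LAYOUT <- list(
  basic = c(baseline = "s1", visual_max = "s1", probe_present_mixed = "s1",
            probe_absent_memory = "s1", forget = "s1"),
  no_rf = c(baseline = "s1", probe_present_mixed = "s2",
            probe_absent_memory = "s1", forget = "s1", visual_max = "s1")
)

## conditions that present the probe stimulus (probe_on_ms required)
.PROBE_CONDITIONS <- c("visual_max", "probe_present_mixed")

#' Single-unit recording for one task session
#'
#' A \code{CellRecording} holds every trial of one unit in one blocked task:
#' a per-trial events table (block, condition, saccade identity, fixation
#' onset, optional probe onset, trial end) and, in parallel, the spike times
#' of each trial. All times are milliseconds relative to saccade onset
#' (t = 0); fixation onset is negative and must precede -426 ms so that the
#' presaccadic baseline window is always covered.
#'
#' @slot cellId character scalar, unit identifier.
#' @slot monkeyId character scalar, subject identifier.
#' @slot task either \code{"basic"} (baseline / visual / mixed probe /
#'   forgetting blocks 1-4) or \code{"no_rf"} (baseline / mixed probe with
#'   saccade 2 / forgetting / visual blocks 1-4).
#' @slot events data.frame with one row per trial: \code{trialIndex},
#'   \code{blockId}, \code{condition}, \code{saccadeId}, \code{fixationOnMs},
#'   \code{probeOnMs} (NA when no probe), \code{trialEndMs}.
#' @slot spikes list of numeric vectors, one per trial (same order as
#'   \code{events}), each sorted and confined to
#'   \code{[fixationOnMs, trialEndMs]}.
#'
#' @seealso [CellRecording()] for the user-facing constructor,
#'   [readCells()] / [writeCells()] for on-disk round trips,
#'   [generateCell()] for the synthetic generator.
#' @export
setClass("CellRecording",
  representation(
    cellId = "character",
    monkeyId = "character",
    task = "character",
    events = "data.frame",
    spikes = "list"
  )
)

.validCellRecording <- function(object) {
  msg <- character(0)
  ev <- object@events
  needed <- c("trialIndex", "blockId", "condition", "saccadeId",
              "fixationOnMs", "probeOnMs", "trialEndMs")
  if (length(object@cellId) != 1L || !nzchar(object@cellId))
    msg <- c(msg, "cellId must be a non-empty character scalar")
  if (!object@task %in% .TASKS)
    msg <- c(msg, sprintf("task must be one of %s",
                          paste(.TASKS, collapse = ", ")))
  if (!all(needed %in% names(ev)))
    return(c(msg, sprintf("events must have columns %s",
                          paste(needed, collapse = ", "))))
  if (length(object@spikes) != nrow(ev))
    msg <- c(msg, "spikes list length must equal number of event rows")
  if (nrow(ev) == 0L)
    return(c(msg, "recording must contain at least one trial"))
  if (anyDuplicated(ev$trialIndex) || is.unsorted(ev$trialIndex))
    msg <- c(msg, sprintf("cell %s: trialIndex must be unique and ordered",
                          object@cellId))
  if (!all(ev$condition %in% .CONDITIONS))
    msg <- c(msg, sprintf("cell %s: unknown condition", object@cellId))
  if (!all(ev$saccadeId %in% .SACCADES))
    msg <- c(msg, sprintf("cell %s: unknown saccadeId", object@cellId))
  if (any(ev$fixationOnMs >= -426))
    msg <- c(msg, sprintf(
      "cell %s: fixationOnMs must be < -426 ms so the baseline window is covered",
      object@cellId))

  layout <- .LAYOUT[[object@task]]
  sacc <- .SACCADE_LAYOUT[[object@task]]
  if (object@task %in% .TASKS && all(ev$condition %in% .CONDITIONS)) {
    bad <- ev$blockId != unname(layout[ev$condition])
    if (any(bad))
      msg <- c(msg, sprintf(
        "cell %s, trial %d: condition '%s' belongs to block %d in the %s task",
        object@cellId, ev$trialIndex[which(bad)[1]],
        ev$condition[which(bad)[1]],
        layout[[ev$condition[which(bad)[1]]]], object@task))
    badSac <- ev$saccadeId != unname(sacc[ev$condition])
    if (any(badSac))
      msg <- c(msg, sprintf(
        "cell %s, trial %d: condition '%s' uses saccade %s in the %s task",
        object@cellId, ev$trialIndex[which(badSac)[1]],
        ev$condition[which(badSac)[1]],
        sacc[[ev$condition[which(badSac)[1]]]], object@task))
    missingBlocks <- setdiff(sort(unique(unname(layout))), unique(ev$blockId))
    if (length(missingBlocks))
      msg <- c(msg, sprintf("cell %s: no trials in block(s) %s",
                            object@cellId,
                            paste(missingBlocks, collapse = ", ")))
  }

  probeNeeded <- ev$condition %in% .PROBE_CONDITIONS
  if (any(probeNeeded & is.na(ev$probeOnMs)))
    msg <- c(msg, sprintf("cell %s: probeOnMs required on probe-present trials",
                          object@cellId))
  if (any(!probeNeeded & !is.na(ev$probeOnMs)))
    msg <- c(msg, sprintf("cell %s: probeOnMs must be absent on probe-absent trials",
                          object@cellId))

  if (length(object@spikes) == nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      s <- object@spikes[[i]]
      if (length(s) == 0L) next
      if (is.unsorted(s)) {
        msg <- c(msg, sprintf("cell %s, trial %d: spike times must be non-decreasing",
                              object@cellId, ev$trialIndex[i]))
        break
      }
      if (s[1] < ev$fixationOnMs[i] || s[length(s)] > ev$trialEndMs[i]) {
        msg <- c(msg, sprintf(
          "cell %s, trial %d: spike times outside [%g, %g] ms",
          object@cellId, ev$trialIndex[i], ev$fixationOnMs[i], ev$trialEndMs[i]))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("CellRecording", .validCellRecording)

#' Construct a CellRecording
#'
#' @param cellId,monkeyId identifiers.
#' @param task \code{"basic"} or \code{"no_rf"}.
#' @param events per-trial data.frame (see \linkS4class{CellRecording}).
#' @param spikes list of numeric spike-time vectors (ms relative to saccade
#'   onset), one per event row.
#' @return a validated \linkS4class{CellRecording}.
#' @examples
#' ev <- data.frame(
#'   trialIndex = 0:3, blockId = 1:4,
#'   condition = c("baseline", "visual_max", "probe_absent_memory", "forget"),
#'   saccadeId = "s1", fixationOnMs = -1200,
#'   probeOnMs = c(NA, -500, NA, NA), trialEndMs = 800)
#' cell <- CellRecording("u1", "A", "basic", ev,
#'                       spikes = list(c(-900, 10), numeric(0), 120, 400))
#' nTrials(cell)
#' @export
CellRecording <- function(cellId, monkeyId, task, events, spikes) {
  events$condition <- as.character(events$condition)
  events$saccadeId <- as.character(events$saccadeId)
  events$blockId <- as.integer(events$blockId)
  events$trialIndex <- as.integer(events$trialIndex)
  if (is.null(events$probeOnMs)) events$probeOnMs <- NA_real_
  events$probeOnMs <- as.numeric(events$probeOnMs)
  events$fixationOnMs <- as.numeric(events$fixationOnMs)
  events$trialEndMs <- as.numeric(events$trialEndMs)
  rownames(events) <- NULL
  spikes <- lapply(spikes, as.numeric)
  new("CellRecording", cellId = as.character(cellId),
      monkeyId = as.character(monkeyId), task = as.character(task),
      events = events, spikes = spikes)
}

#' Peristimulus time histogram
#'
#' Trial-averaged firing rate in contiguous half-open time bins
#' \code{[t, t + binWidth)} aligned to saccade onset, with the per-trial bin
#' rates retained so that the standard error can be recomputed after causal
#' smoothing. Rates are spikes/s, or dimensionless fold-change after
#' division by a baseline rate.
#'
#' @slot binWidthMs bin width (ms).
#' @slot binStartsMs left edge of every bin (ms).
#' @slot rate trial-averaged rate per bin.
#' @slot sem standard error of the mean across trials per bin.
#' @slot nTrials number of trials averaged.
#' @slot smoothed TRUE after [smoothCausal()].
#' @slot normalization one of \code{"none"}, \code{"divide"}, \code{"subtract"}.
#' @slot normalizationFactor the baseline rate used (1 when unnormalized).
#' @slot trialRates nTrials x nBins matrix of per-trial rates.
#' @seealso [buildPsth()], [smoothCausal()], [normalizeToBaseline()]
#' @export
setClass("Psth",
  representation(
    binWidthMs = "numeric",
    binStartsMs = "numeric",
    rate = "numeric",
    sem = "numeric",
    nTrials = "integer",
    smoothed = "logical",
    normalization = "character",
    normalizationFactor = "numeric",
    trialRates = "matrix"
  )
)

setValidity("Psth", function(object) {
  msg <- character(0)
  nb <- length(object@binStartsMs)
  if (length(object@rate) != nb || length(object@sem) != nb)
    msg <- c(msg, "rate, sem and binStartsMs must have equal length")
  if (nb > 1 && any(abs(diff(object@binStartsMs) - object@binWidthMs) > 1e-9))
    msg <- c(msg, "bins must be contiguous with spacing binWidthMs")
  if (object@binWidthMs <= 0)
    msg <- c(msg, "binWidthMs must be positive")
  if (any(object@sem < -1e-12, na.rm = TRUE))
    msg <- c(msg, "sem must be non-negative")
  if (object@normalization == "none" && any(object@rate < -1e-12))
    msg <- c(msg, "unnormalized rate must be non-negative")
  if (nb > 0 && ncol(object@trialRates) != nb)
    msg <- c(msg, "trialRates must have one column per bin")
  if (length(msg)) msg else TRUE
})

#' @describeIn CellRecording-class number of trials
#' @param object a CellRecording
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))

#' @export
setMethod("nTrials", "CellRecording", function(object) nrow(object@events))

#' @export
setMethod("nTrials", "Psth", function(object) object@nTrials)

#' @describeIn CellRecording-class unit identifier
#' @export
setGeneric("cellId", function(object) standardGeneric("cellId"))

#' @export
setMethod("cellId", "CellRecording", function(object) object@cellId)

#' @describeIn CellRecording-class per-trial events table
#' @export
setGeneric("trialEvents", function(object) standardGeneric("trialEvents"))

#' @export
setMethod("trialEvents", "CellRecording", function(object) object@events)

#' @describeIn CellRecording-class list of spike-time vectors
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))

#' @export
setMethod("spikeTimes", "CellRecording", function(object) object@spikes)

#' Select the spike trains of trials matching a condition or block
#'
#' @param object a \linkS4class{CellRecording}.
#' @param condition optional condition name to filter on.
#' @param block optional block id to filter on.
#' @return list of numeric spike-time vectors (possibly empty).
#' @export
trialsWhere <- function(object, condition = NULL, block = NULL) {
  stopifnot(is(object, "CellRecording"))
  keep <- rep(TRUE, nTrials(object))
  if (!is.null(condition)) keep <- keep & object@events$condition %in% condition
  if (!is.null(block)) keep <- keep & object@events$blockId %in% block
  object@spikes[keep]
}

#' @export
setMethod("show", "CellRecording", function(object) {
  ev <- object@events
  cat(sprintf("CellRecording '%s' (monkey %s, %s task)\n",
              object@cellId, object@monkeyId, object@task))
  cat(sprintf("  %d trials, %d spikes total\n",
              nrow(ev), sum(lengths(object@spikes))))
  tab <- table(ev$blockId)
  cat("  trials per block:",
      paste(sprintf("%s:%d", names(tab), tab), collapse = "  "), "\n")
})

#' @export
setMethod("show", "Psth", function(object) {
  cat(sprintf("Psth: %d bins of %g ms over [%g, %g) ms, %d trials\n",
              length(object@rate), object@binWidthMs,
              if (length(object@binStartsMs)) min(object@binStartsMs) else NA,
              if (length(object@binStartsMs))
                max(object@binStartsMs) + object@binWidthMs else NA,
              object@nTrials))
  cat(sprintf("  smoothed: %s, normalization: %s (factor %g)\n",
              object@smoothed, object@normalization,
              object@normalizationFactor))
})

#' Accessors for Psth slots
#' @param object a \linkS4class{Psth}.
#' @return numeric vector of per-bin rates / SEMs / bin left edges.
#' @export
setGeneric("psthRate", function(object) standardGeneric("psthRate"))
#' @export
setMethod("psthRate", "Psth", function(object) object@rate)

#' @rdname psthRate
#' @export
setGeneric("psthSem", function(object) standardGeneric("psthSem"))
#' @export
setMethod("psthSem", "Psth", function(object) object@sem)

#' @rdname psthRate
#' @export
setGeneric("binStarts", function(object) standardGeneric("binStarts"))
#' @export
setMethod("binStarts", "Psth", function(object) object@binStartsMs)

#' Default analysis windows
#'
#' The fixed epochs used throughout the quantification: the presaccadic
#' baseline window \code{[-426, -226)} ms, the peak-search window
#' \code{[-125, +500]} ms (extended before the saccade to capture predictive
#' remapping), the +/-100 ms half-width of the peak quantification window,
#' the 50-trial forgetting epoch, and the first/last 10-trial comparison.
#'
#' @param baseline length-2 numeric, baseline window (ms).
#' @param peakSearch length-2 numeric, peak-search window (ms).
#' @param peakHalfwidthMs half-width of the quantification window around the
#'   peak (ms).
#' @param decayEpochTrials number of forgetting trials analyzed.
#' @param firstLastN trials per tail in the first-vs-last comparison.
#' @param postsaccadic length-2 numeric, postsaccadic window used by the
#'   eye-position exclusion test (ms).
#' @return a list with class \code{"AnalysisWindows"}.
#' @export
analysisWindows <- function(baseline = c(-426, -226),
                            peakSearch = c(-125, 500),
                            peakHalfwidthMs = 100,
                            decayEpochTrials = 50L,
                            firstLastN = 10L,
                            postsaccadic = c(50, 250)) {
  stopifnot(baseline[1] < baseline[2], baseline[2] <= 0,
            peakSearch[1] < peakSearch[2], peakHalfwidthMs > 0,
            decayEpochTrials >= 2L, firstLastN >= 1L)
  structure(list(baseline = baseline, peakSearch = peakSearch,
                 peakHalfwidthMs = peakHalfwidthMs,
                 decayEpochTrials = as.integer(decayEpochTrials),
                 firstLastN = as.integer(firstLastN),
                 postsaccadic = postsaccadic),
            class = "AnalysisWindows")
}

#' Latency-estimation parameters
#'
#' @param binWidthMs histogram bin width for the threshold-crossing scan (ms).
#' @param scanSubwindowMs width of the sliding baseline subwindows (ms).
#' @param scanStepMs step of the sliding baseline scan (ms).
#' @param cutoffPercentile percentile of the per-bin median baseline counts
#'   that defines the threshold.
#' @param sustainedBins number of consecutive supra-threshold bins required
#'   (5 bins of 2 ms by default; set 10 for the 20 ms criterion).
#' @param integrationMs causal integration window for the per-bin median
#'   statistic of the threshold-crossing method (ms); see
#'   [latencyThresholdCrossing()].
#' @param ranksumWindowMs width of the sliding rank-sum window (ms).
#' @param ranksumStepMs step of the rank-sum scan (ms).
#' @param ranksumRun number of consecutive significant window positions
#'   required by the rank-sum method.
#' @param alpha significance level for the rank-sum scan.
#' @return a list with class \code{"LatencyParams"}.
#' @export
latencyParams <- function(binWidthMs = 2, scanSubwindowMs = 200,
                          scanStepMs = 1, cutoffPercentile = 75,
                          sustainedBins = 5L, integrationMs = 50,
                          ranksumWindowMs = 50, ranksumStepMs = 1,
                          ranksumRun = 20L, alpha = 0.05) {
  stopifnot(binWidthMs > 0, scanSubwindowMs > 0, scanStepMs > 0,
            cutoffPercentile > 0, cutoffPercentile < 100,
            sustainedBins >= 1L, integrationMs >= binWidthMs,
            ranksumWindowMs > 0, ranksumRun >= 1L,
            alpha > 0, alpha < 1)
  structure(list(binWidthMs = binWidthMs, scanSubwindowMs = scanSubwindowMs,
                 scanStepMs = scanStepMs, cutoffPercentile = cutoffPercentile,
                 sustainedBins = as.integer(sustainedBins),
                 integrationMs = integrationMs,
                 ranksumWindowMs = ranksumWindowMs,
                 ranksumStepMs = ranksumStepMs,
                 ranksumRun = as.integer(ranksumRun), alpha = alpha),
            class = "LatencyParams")
}
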