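#' Select a representative baseline subwindow
#'
#' Baseline activity can drift within a trial, so the latency estimators do
#' not use the whole pre-baseline span. Instead, 200-ms-wide subwindows are
#' slid in 1-ms steps through \code{[fixationOn, -226]} ms; for each the
#' median per-trial spike count is computed, and the subwindow whose median
#' matches the median of all those window-medians (within one spike),
#' starting as late as possible (closest to the response epoch), is
#' returned. The choice is deterministic.
#'
#' @param trials list of spike-time vectors (ms).
#' @param params a [latencyParams()] list.
#' @param fixationOnMs earliest usable time (ms, negative); at least one
#'   subwindow must fit before \code{-226} ms.
#' @param scanEndMs end of the scanned span (default -226 ms, the end of
#'   the presaccadic baseline epoch).
#' @return length-2 numeric, the selected \code{[t0, t0 + 200]} window.
#' @export
selectBaselineWindow <- function(trials, params = latencyParams(),
                                 fixationOnMs = -1200, scanEndMs = -226) {
  if (length(trials) == 0L) stop("selectBaselineWindow: empty trial list")
  w <- params$scanSubwindowMs
  lastStart <- scanEndMs - w
  if (fixationOnMs > lastStart)
    stop("selectBaselineWindow: span too short for one ", w, " ms subwindow")
  starts <- seq(fixationOnMs, lastStart, by = params$scanStepMs)
  counts <- .slidingCounts(trials, starts, w)
  meds <- .colMedians(counts)
  M <- stats::median(meds)
  ok <- which(abs(meds - M) <= 1)
  if (!length(ok)) ok <- which.min(abs(meds - M))
  t0 <- starts[max(ok)]
  c(t0, t0 + w)
}

## Per-bin detection statistic on the binWidth grid: the median across
## trials of the spike count in the causal window [binEnd - integ, binEnd).
## Per-trial 2-ms bins are almost always empty at cortical firing rates,
## so their across-trial median is degenerate at 0; integrating each trial
## over the preceding `integ` ms makes the median informative while
## keeping the bin-level time resolution and causality (a bin's statistic
## never sees spikes after the bin).
.binMedianCounts <- function(trials, t0, t1, binWidthMs, integ) {
  nBins <- floor((t1 - t0) / binWidthMs + 1e-9)
  starts <- t0 + binWidthMs * (seq_len(nBins) - 1)
  counts <- .slidingCounts(trials, starts + binWidthMs - integ, integ)
  list(starts = starts, medians = .colMedians(counts))
}

#' Onset latency by median threshold crossing
#'
#' Detects a sustained rise of the across-trial median activity above a
#' baseline-derived cut-off. The per-bin statistic, on the 2-ms bin grid,
#' is the median across trials of the spike count in the causal
#' \code{integrationMs} window ending at the bin (see Details). The
#' cut-off is the 75th percentile of that statistic over the bins of the
#' baseline subwindow selected by [selectBaselineWindow()]. The response
#' epoch \code{[-125, +500]} ms is scanned bin by bin; the latency is the
#' start of the first bin of the first run of at least
#' \code{sustainedBins} consecutive bins strictly exceeding the cut-off
#' (ties are conservative and do not count). Returns \code{NA} when no
#' sustained crossing exists — as happens for gradually building
#' responses, which fall through to [latencyRanksum()].
#'
#' @details Raw per-trial 2-ms bins are nearly always empty at cortical
#' firing rates, which would make their across-trial median identically
#' zero; each trial is therefore integrated over the preceding
#' \code{integrationMs} (default 50 ms, matching the rank-sum window)
#' before the median is taken. Because the integration window is causal,
#' the estimated latency can never precede the true onset by more than
#' one bin.
#'
#' @inheritParams selectBaselineWindow
#' @param windows an [analysisWindows()] list (provides the response epoch).
#' @param baselineWindow optional precomputed baseline subwindow.
#' @return latency in ms, or \code{NA_real_} when undetectable.
#' @export
latencyThresholdCrossing <- function(trials, params = latencyParams(),
                                     windows = analysisWindows(),
                                     fixationOnMs = -1200,
                                     baselineWindow = NULL) {
  if (is.null(baselineWindow))
    baselineWindow <- selectBaselineWindow(trials, params, fixationOnMs)
  integ <- params$integrationMs
  ## only baseline bins whose causal window is inside the recorded span
  b0 <- max(baselineWindow[1],
            fixationOnMs + integ - params$binWidthMs)
  base <- .binMedianCounts(trials, b0, baselineWindow[2],
                           params$binWidthMs, integ)
  cutoff <- stats::quantile(base$medians, params$cutoffPercentile / 100,
                            names = FALSE, type = 7)
  resp <- .binMedianCounts(trials, windows$peakSearch[1],
                           windows$peakSearch[2], params$binWidthMs, integ)
  i <- .firstRunStart(resp$medians > cutoff, params$sustainedBins)
  if (is.na(i)) NA_real_ else resp$starts[i]
}

#' Onset latency by sliding rank-sum comparison
#'
#' For every 50-ms window stepped 1 ms through the response epoch, the
#' per-trial spike counts in the window are compared against baseline
#' counts by a two-sided Wilcoxon rank sum. To put the two samples on a
#' common duration, the 200-ms baseline subwindow is split into its
#' disjoint 50-ms quarters and the per-trial counts of all quarters are
#' pooled: baseline and response counts then follow identical
#' distributions under stationary firing, which a rate conversion of
#' unequal-duration counts would not achieve (unequal durations leave a
#' dispersion difference that a rank test detects spuriously at large
#' trial counts). The latency is the start of the first run of at least
#' \code{ranksumRun} consecutive significant window positions (at
#' \code{alpha}); because the windows extend forward in time, the
#' estimate can precede a step onset by up to the window width. Returns
#' \code{NA} when no such run exists.
#'
#' @inheritParams latencyThresholdCrossing
#' @return latency in ms, or \code{NA_real_}.
#' @export
latencyRanksum <- function(trials, params = latencyParams(),
                           windows = analysisWindows(),
                           fixationOnMs = -1200, baselineWindow = NULL) {
  if (is.null(baselineWindow))
    baselineWindow <- selectBaselineWindow(trials, params, fixationOnMs)
  w <- params$ranksumWindowMs
  nQuarters <- max(1L, floor((baselineWindow[2] - baselineWindow[1]) / w))
  qStarts <- baselineWindow[1] + w * (seq_len(nQuarters) - 1)
  baseCounts <- as.vector(.slidingCounts(trials, qStarts, w))
  starts <- seq(windows$peakSearch[1], windows$peakSearch[2] - w,
                by = params$ranksumStepMs)
  counts <- .slidingCounts(trials, starts, w)
  sig <- vapply(seq_along(starts), function(j)
    .ranksumP(counts[, j], baseCounts) < params$alpha, logical(1))
  i <- .firstRunStart(sig, params$ranksumRun)
  if (is.na(i)) NA_real_ else starts[i]
}

#' Estimate onset latency
#'
#' Tries the median threshold-crossing method first; when that fails to
#' find a sustained crossing (as happens for gradually building responses),
#' falls back to the sliding rank-sum method. Reports which method
#' produced the estimate.
#'
#' @inheritParams latencyThresholdCrossing
#' @return list with \code{latencyMs} (\code{NA_real_} when neither method
#'   detects a response) and \code{method} (\code{"threshold_crossing"},
#'   \code{"ranksum"} or \code{"none"}).
#' @export
estimateLatency <- function(trials, params = latencyParams(),
                            windows = analysisWindows(),
                            fixationOnMs = -1200) {
  bw <- selectBaselineWindow(trials, params, fixationOnMs)
  lat <- latencyThresholdCrossing(trials, params, windows,
                                  baselineWindow = bw)
  if (!is.na(lat))
    return(list(latencyMs = lat, method = "threshold_crossing"))
  lat <- latencyRanksum(trials, params, windows, baselineWindow = bw)
  if (!is.na(lat))
    return(list(latencyMs = lat, method = "ranksum"))
  list(latencyMs = NA_real_, method = "none")
}
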