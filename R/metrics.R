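#' Baseline activity of a set of trials
#'
#' Median across trials of the spike count in the presaccadic baseline
#' window \code{[-426, -226)} ms (or the window in \code{windows$baseline}).
#'
#' @param trials list of spike-time vectors (ms).
#' @param windows an [analysisWindows()] list.
#' @return median per-trial spike count in the baseline window.
#' @export
baselineActivity <- function(trials, windows = analysisWindows()) {
  if (length(trials) == 0L) stop("baselineActivity: empty trial list")
  stats::median(.trialCounts(trials, windows$baseline[1],
                             windows$baseline[2]))
}

#' Locate and quantify the peak response
#'
#' The time of peak activity is the argmax of the smoothed (10 ms causal
#' filter over 2 ms bins), unnormalized PSTH within the peak-search window
#' \code{[-125, +500]} ms — extended before the saccade to capture
#' predictive remapping — with argmax ties broken by the earliest bin. The
#' response amplitude is the median across trials of the raw (unsmoothed)
#' spike count in the window extending 100 ms before and after the peak.
#'
#' When no spikes fall in the search window the degenerate return is the
#' earliest bin with amplitude 0.
#'
#' @param trials list of spike-time vectors (ms); every trial must cover
#'   \code{[peakSearch[1] - halfwidth, peakSearch[2] + halfwidth]}.
#' @param windows an [analysisWindows()] list.
#' @param binWidthMs PSTH bin width (ms).
#' @param smoothSpanMs causal filter span (ms).
#' @return list with \code{peakTimeMs} (bin start of the peak),
#'   \code{rPeak} (median raw count in the +/-100 ms window) and
#'   \code{window} (the length-2 quantification window, reusable on other
#'   conditions so that like is compared with like).
#' @export
peakResponse <- function(trials, windows = analysisWindows(),
                         binWidthMs = 2, smoothSpanMs = 10) {
  if (length(trials) == 0L) stop("peakResponse: empty trial list")
  ps <- windows$peakSearch
  ## pad the PSTH to the left so every bin inside the search window has a
  ## full smoothing history
  prePad <- smoothSpanMs - binWidthMs
  psth <- smoothCausal(buildPsth(trials, window = c(ps[1] - prePad, ps[2]),
                                 binWidthMs = binWidthMs),
                       spanMs = smoothSpanMs)
  inWin <- binStarts(psth) >= ps[1] - 1e-9
  r <- psthRate(psth)[inWin]
  peakIdx <- which.max(r)            # which.max takes the earliest tie
  peakTime <- binStarts(psth)[inWin][peakIdx]
  qw <- c(peakTime - windows$peakHalfwidthMs,
          peakTime + windows$peakHalfwidthMs)
  rPeak <- stats::median(.trialCounts(trials, qw[1], qw[2]))
  list(peakTimeMs = peakTime, rPeak = rPeak, window = qw)
}

#' Memory index
#'
#' Normalized difference between the postsaccadic memory response
#' (probe-absent trials after the memory has been established) and the
#' matched baseline-block response:
#' \deqn{index = (R_{mem} - R_{pre}) / (R_{mem} + R_{pre})}
#' The index lies in \code{[-1, 1]}: positive when the memory response
#' exceeds baseline, and antisymmetric under swapping its arguments.
#'
#' @param rMem memory-condition response (non-negative scalar).
#' @param rPre baseline-block response (non-negative scalar).
#' @return list with \code{rMem}, \code{rPre} and \code{index}.
#' @examples
#' memoryIndex(3, 1)$index   # 0.5
#' memoryIndex(10, 10)$index # 0
#' memoryIndex(0, 5)$index   # -1
#' @export
memoryIndex <- function(rMem, rPre) {
  stopifnot(length(rMem) == 1L, length(rPre) == 1L)
  if (rMem < 0 || rPre < 0)
    stop("memoryIndex: responses must be non-negative")
  if (rMem + rPre == 0)
    stop("memoryIndex: undefined when both responses are zero")
  list(rMem = rMem, rPre = rPre, index = (rMem - rPre) / (rMem + rPre))
}

#' Full response metrics for one condition of one cell
#'
#' Convenience wrapper combining [baselineActivity()], [peakResponse()] and
#' [estimateLatency()] for the trials of one condition.
#'
#' @param trials list of spike-time vectors (ms).
#' @param windows an [analysisWindows()] list.
#' @param params a [latencyParams()] list.
#' @param fixationOnMs fixation onset (ms, negative) bounding the baseline
#'   scan of the latency estimators.
#' @return list with \code{rBaseline}, \code{peakTimeMs}, \code{rPeak},
#'   \code{window}, \code{latencyMs} (NA when undetectable) and
#'   \code{latencyMethod} (\code{"threshold_crossing"}, \code{"ranksum"} or
#'   \code{"none"}).
#' @export
responseMetrics <- function(trials, windows = analysisWindows(),
                            params = latencyParams(),
                            fixationOnMs = -1200) {
  pk <- peakResponse(trials, windows)
  lat <- estimateLatency(trials, params = params, windows = windows,
                         fixationOnMs = fixationOnMs)
  list(rBaseline = baselineActivity(trials, windows),
       peakTimeMs = pk$peakTimeMs, rPeak = pk$rPeak, window = pk$window,
       latencyMs = lat$latencyMs, latencyMethod = lat$method)
}
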