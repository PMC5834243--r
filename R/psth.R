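#' Build a peristimulus time histogram
#'
#' Bins the spike trains of a set of saccade-aligned trials into contiguous
#' half-open bins \code{[t, t + binWidth)} and averages across trials. The
#' per-bin rate is \code{totalSpikes / (nTrials * binWidth)} in spikes/s, so
#' before smoothing or normalization the rate integrates back to the mean
#' per-trial spike count over any span of bins (mass conservation). The SEM
#' is the standard error across per-trial bin rates.
#'
#' @param trials list of numeric spike-time vectors (ms), e.g. from
#'   [trialsWhere()].
#' @param window length-2 numeric \code{c(t0, t1)} in ms; bins cover
#'   \code{[t0, t1)}.
#' @param binWidthMs bin width in ms (default 2).
#' @return a \linkS4class{Psth}.
#' @examples
#' p <- buildPsth(list(c(1, 3, 5)), window = c(0, 6), binWidthMs = 2)
#' psthRate(p)  # 500 spikes/s in each of the three bins
#' @export
buildPsth <- function(trials, window, binWidthMs = 2) {
  if (length(trials) == 0L) stop("buildPsth: empty trial list")
  stopifnot(length(window) == 2L, window[1] < window[2], binWidthMs > 0)
  nBins <- floor((window[2] - window[1]) / binWidthMs + 1e-9)
  starts <- window[1] + binWidthMs * (seq_len(nBins) - 1)
  n <- length(trials)
  widthS <- binWidthMs / 1000
  trialRates <- matrix(0, nrow = n, ncol = nBins)
  if (nBins > 0L) {
    breaks <- c(starts, window[1] + binWidthMs * nBins)
    for (i in seq_len(n)) {
      s <- trials[[i]]
      s <- s[s >= breaks[1] & s < breaks[nBins + 1L]]
      if (!length(s)) next
      idx <- findInterval(s, breaks)   # half-open [b_k, b_{k+1})
      trialRates[i, ] <- tabulate(idx, nbins = nBins) / widthS
    }
  }
  rate <- colMeans(trialRates)
  sem <- if (n > 1) apply(trialRates, 2, stats::sd) / sqrt(n) else
    rep(0, nBins)
  new("Psth", binWidthMs = binWidthMs, binStartsMs = starts, rate = rate,
      sem = sem, nTrials = as.integer(n), smoothed = FALSE,
      normalization = "none", normalizationFactor = 1,
      trialRates = trialRates)
}

## trailing boxcar over k bins with shorter means in the prefix region
.causalBoxcar <- function(x, k) {
  n <- length(x)
  if (n == 0L) return(x)
  cs <- cumsum(x)
  denom <- pmin(seq_len(n), k)
  lag <- c(rep(0, min(k, n)), cs[seq_len(max(0L, n - k))])
  (cs - lag) / denom
}

#' Smooth a PSTH with a sliding causal filter
#'
#' Applies a trailing boxcar: each output bin is the mean of the current bin
#' and the preceding bins spanning \code{spanMs} in total (10 ms over 2-ms
#' bins = the current bin plus the 4 before it). Bins too early to have a
#' full history are averaged over the available prefix, so the output has
#' the same length as the input and a constant rate is left unchanged. Per-
#' trial rates are smoothed identically and the SEM is recomputed from them.
#'
#' @param psth a \linkS4class{Psth}.
#' @param spanMs filter span in ms; must be a positive integer multiple of
#'   the bin width (default 10).
#' @return a smoothed \linkS4class{Psth}.
#' @export
smoothCausal <- function(psth, spanMs = 10) {
  stopifnot(is(psth, "Psth"))
  k <- spanMs / psth@binWidthMs
  if (spanMs < psth@binWidthMs || abs(k - round(k)) > 1e-9)
    stop("spanMs must be a positive integer multiple of the bin width")
  k <- as.integer(round(k))
  if (ncol(psth@trialRates) <= 1L) {
    tr <- psth@trialRates        # nothing to smooth over
  } else {
    tr <- t(apply(psth@trialRates, 1, .causalBoxcar, k = k))
    if (nrow(psth@trialRates) == 1L) tr <- matrix(tr, nrow = 1L)
  }
  n <- psth@nTrials
  sem <- if (n > 1) apply(tr, 2, stats::sd) / sqrt(n) else
    rep(0, ncol(tr))
  initialize(psth, rate = .causalBoxcar(psth@rate, k), sem = sem,
             smoothed = TRUE, trialRates = tr)
}

#' Normalize a PSTH to baseline activity
#'
#' Scales the PSTH by the block-1 baseline firing rate so that baseline
#' activity reads as 1 and response amplitudes as fold-changes
#' (\code{mode = "divide"}, the default). \code{mode = "subtract"} removes
#' the baseline rate instead; \code{mode = "none"} returns the input.
#'
#' @param psth a \linkS4class{Psth}.
#' @param baselineRate baseline firing rate in spikes/s; must be positive
#'   for division (a cell with zero baseline is excluded upstream).
#' @param mode \code{"divide"}, \code{"subtract"} or \code{"none"}.
#' @return a \linkS4class{Psth}; dimensionless when divided.
#' @export
normalizeToBaseline <- function(psth, baselineRate, mode = "divide") {
  stopifnot(is(psth, "Psth"))
  mode <- match.arg(mode, c("divide", "subtract", "none"))
  if (mode == "none") return(psth)
  if (mode == "divide" && baselineRate <= 0)
    stop("baselineRate must be positive for division")
  if (mode == "divide")
    initialize(psth, rate = psth@rate / baselineRate,
               sem = psth@sem / baselineRate,
               trialRates = psth@trialRates / baselineRate,
               normalization = "divide", normalizationFactor = baselineRate)
  else
    initialize(psth, rate = psth@rate - baselineRate,
               trialRates = psth@trialRates - baselineRate,
               normalization = "subtract", normalizationFactor = baselineRate)
}

#' Export a PSTH as a data.frame
#'
#' @param psth a \linkS4class{Psth}.
#' @return data.frame with \code{bin_start_ms}, \code{rate}, \code{sem}.
#' @export
psthToFrame <- function(psth) {
  stopifnot(is(psth, "Psth"))
  data.frame(bin_start_ms = psth@binStartsMs, rate = psth@rate,
             sem = psth@sem)
}
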