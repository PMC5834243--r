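#' Per-trial memory activity through the forgetting block
#'
#' After the probe stimulus stops appearing, the memory response decays
#' over trials. This extracts, for the first \code{decayEpochTrials}
#' (default 50) trials of the forgetting block, the spike count in the
#' cell's memory quantification window (the +/-100 ms window around the
#' memory-condition PSTH peak), and normalizes it by one of:
#' \describe{
#'   \item{\code{"last5_probe_mean"}}{mean activity over the last five
#'     probe-present trials before forgetting begins (default);}
#'   \item{\code{"peak_memory"}}{the cell's peak memory activity (median
#'     count in the quantification window on probe-absent memory trials);}
#'   \item{\code{"stim_block_mean"}}{mean activity over all probe-present
#'     trials of the stimulus-presentation block.}
#' }
#'
#' @param cell a \linkS4class{CellRecording} with a forgetting block.
#' @param windows an [analysisWindows()] list.
#' @param mode normalization mode (see above).
#' @return list with \code{trialOrdinal} (0-based within the forgetting
#'   epoch), \code{activity} (raw counts), \code{normalized},
#'   \code{normalizer}, \code{mode} and \code{window}.
#' @export
buildDecaySeries <- function(cell, windows = analysisWindows(),
                             mode = c("last5_probe_mean", "peak_memory",
                                      "stim_block_mean")) {
  stopifnot(is(cell, "CellRecording"))
  mode <- match.arg(mode)
  forget <- trialsWhere(cell, condition = "forget")
  if (length(forget) == 0L)
    stop(sprintf("cell %s: no forgetting-block trials", cellId(cell)))
  memTrials <- trialsWhere(cell, condition = "probe_absent_memory")
  if (length(memTrials) == 0L)
    stop(sprintf("cell %s: no probe-absent memory trials", cellId(cell)))
  pk <- peakResponse(memTrials, windows)
  nKeep <- min(length(forget), windows$decayEpochTrials)
  forget <- forget[seq_len(nKeep)]
  activity <- .trialCounts(forget, pk$window[1], pk$window[2])

  probeTrials <- trialsWhere(cell, condition = "probe_present_mixed")
  normalizer <- switch(mode,
    last5_probe_mean = {
      if (length(probeTrials) == 0L)
        stop(sprintf("cell %s: no probe-present trials for normalization",
                     cellId(cell)))
      last5 <- probeTrials[seq(max(1L, length(probeTrials) - 4L),
                               length(probeTrials))]
      mean(.trialCounts(last5, pk$window[1], pk$window[2]))
    },
    peak_memory = pk$rPeak,
    stim_block_mean = {
      if (length(probeTrials) == 0L)
        stop(sprintf("cell %s: no probe-present trials for normalization",
                     cellId(cell)))
      mean(.trialCounts(probeTrials, pk$window[1], pk$window[2]))
    })
  if (!is.finite(normalizer) || normalizer <= 0)
    stop(sprintf("cell %s: decay normalizer is zero; cannot normalize",
                 cellId(cell)))
  list(trialOrdinal = seq_along(activity) - 1L, activity = activity,
       normalized = activity / normalizer, normalizer = normalizer,
       mode = mode, window = pk$window)
}

#' Fit a first-order exponential decay
#'
#' Least-squares fit of \eqn{y(n) = a e^{-k n} + c} with the decay rate
#' constrained to \eqn{k \ge 0} (n in trials). The offset term is included
#' because population forgetting traces do not decay to zero. The fit uses
#' Levenberg-Marquardt from a fixed grid of initial rate constants (best
#' start by residual sum of squares), so it is deterministic. \eqn{R^2 =
#' 1 - SS_{res}/SS_{tot}} and may be negative when the exponential is a
#' poor model of a slowly decaying trace. A constant series returns the
#' degenerate fit \eqn{k = 0, a = 0, c = \bar{y}, R^2 = 0}.
#'
#' @param y numeric vector of (normalized) activities, one per trial, or a
#'   series from [buildDecaySeries()].
#' @param trialOrdinal 0-based trial ordinals (default \code{0:(n-1)}).
#' @return list with \code{k} (per trial), \code{tau} (= 1/k, trials),
#'   \code{a}, \code{c}, \code{rSquared}, \code{nTrials}, \code{fitted}.
#' @examples
#' f <- fitExponential(exp(-0.3 * 0:49))
#' f$k        # 0.3
#' f$rSquared # 1
#' @export
fitExponential <- function(y, trialOrdinal = NULL) {
  if (is.list(y) && !is.null(y$normalized)) {
    trialOrdinal <- y$trialOrdinal
    y <- y$normalized
  }
  y <- as.numeric(y)
  n <- length(y)
  if (n < 10L) stop("fitExponential requires at least 10 trials")
  if (is.null(trialOrdinal)) trialOrdinal <- seq_len(n) - 1
  tt <- as.numeric(trialOrdinal)
  ssTot <- sum((y - mean(y))^2)
  if (ssTot == 0)
    return(list(k = 0, tau = Inf, a = 0, c = mean(y), rSquared = 0,
                nTrials = n, fitted = rep(mean(y), n)))

  c0 <- mean(utils::tail(y, 5))
  a0 <- y[1] - c0
  if (a0 == 0) a0 <- max(abs(y - c0), stats::sd(y))
  best <- NULL
  for (k0 in c(0.01, 0.05, 0.1, 0.3, 1)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-k * tt) + c,
                        data = data.frame(y = y, tt = tt),
                        start = list(a = a0, k = k0, c = c0),
                        lower = c(a = -Inf, k = 0, c = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(stats::resid(fit)^2)
    if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
  }
  if (is.null(best))
    return(list(k = 0, tau = Inf, a = 0, c = mean(y),
                rSquared = 0, nTrials = n, fitted = rep(mean(y), n)))
  cf <- stats::coef(best$fit)
  list(k = unname(cf["k"]),
       tau = if (cf["k"] > 0) unname(1 / cf["k"]) else Inf,
       a = unname(cf["a"]), c = unname(cf["c"]),
       rSquared = 1 - best$ss / ssTot, nTrials = n,
       fitted = as.numeric(stats::fitted(best$fit)))
}

#' Compare early and late forgetting trials
#'
#' Two-sample Wilcoxon rank sum of the first \code{n} versus the last
#' \code{n} activities inside the forgetting epoch (default first/last 10
#' of a 50-trial epoch). The trials are independent draws, so a two-sample
#' test is used. Returns the two-sided p-value (1 when the two segments
#' are entirely tied).
#'
#' @param y numeric vector of per-trial activities (or a series from
#'   [buildDecaySeries()]).
#' @param n trials per tail (default 10).
#' @param epoch epoch length considered (default 50); when fewer trials
#'   are available the full series is used, provided it has at least
#'   \code{2n} trials.
#' @return two-sided p-value.
#' @export
compareFirstLast <- function(y, n = 10L, epoch = 50L) {
  if (is.list(y) && !is.null(y$normalized)) y <- y$normalized
  y <- as.numeric(y)
  y <- y[seq_len(min(length(y), epoch))]
  if (length(y) < 2L * n)
    stop("compareFirstLast: need at least ", 2L * n, " trials")
  first <- y[seq_len(n)]
  last <- y[seq(length(y) - n + 1L, length(y))]
  if (length(unique(c(first, last))) <= 1L) return(1)
  p <- suppressWarnings(stats::wilcox.test(first, last)$p.value)
  if (!is.finite(p)) p <- 1
  p
}

#' Population forgetting-decay fit
#'
#' Averages the per-cell normalized decay series across cells (trial-wise,
#' over the trials all cells share) and fits the first-order exponential to
#' the population mean trace, as the population-level decay estimate.
#'
#' @param seriesList list of series from [buildDecaySeries()].
#' @return list with \code{meanSeries} (the across-cell mean trace),
#'   \code{fit} (from [fitExponential()]) and \code{firstLastP} (from
#'   [compareFirstLast()] on the mean trace).
#' @export
populationDecay <- function(seriesList) {
  if (length(seriesList) == 0L) stop("populationDecay: no series")
  nCommon <- min(vapply(seriesList, function(s) length(s$normalized),
                        integer(1)))
  m <- vapply(seriesList, function(s) s$normalized[seq_len(nCommon)],
              numeric(nCommon))
  meanSeries <- rowMeans(as.matrix(m))
  list(meanSeries = meanSeries, fit = fitExponential(meanSeries),
       firstLastP = tryCatch(compareFirstLast(meanSeries),
                             error = function(e) NA_real_))
}
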