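## Internal helpers shared across modules. Windows are half-open [t0, t1).

.countInWindow <- function(spikes, t0, t1) {
  sum(spikes >= t0 & spikes < t1)
}

## per-trial spike counts in one window
.trialCounts <- function(spikesList, t0, t1) {
  vapply(spikesList, .countInWindow, numeric(1), t0 = t0, t1 = t1)
}

## per-trial counts in many sliding windows [starts[j], starts[j] + width).
## Returns an nTrials x nWindows matrix. Uses cumulative 1-ms (or finer)
## binning so the scan is O(trials * span) rather than O(trials * windows).
.slidingCounts <- function(spikesList, starts, width) {
  nW <- length(starts)
  n <- length(spikesList)
  out <- matrix(0, nrow = n, ncol = nW)
  if (nW == 0L || n == 0L) return(out)
  for (i in seq_len(n)) {
    s <- spikesList[[i]]
    if (length(s) == 0L) next
    ## counts up to each window edge; findInterval on the sorted spikes
    left <- findInterval(starts, s, left.open = TRUE)       # spikes < start... see below
    ## number of spikes < t is findInterval(t - eps); with left.open = TRUE,
    ## findInterval returns #{s_j <= t} excluding ties at t, i.e. #{s_j < t}
    right <- findInterval(starts + width, s, left.open = TRUE)
    out[i, ] <- right - left
  }
  out
}

## median across trials, column-wise, for a counts matrix
.colMedians <- function(m) apply(m, 2, stats::median)

## Wilcoxon rank-sum p-value robust to degenerate (all-tied) samples.
## When every value in both samples is identical there is no evidence of a
## shift; return p = 1 instead of the NaN of the normal approximation.
.ranksumP <- function(x, y) {
  if (length(unique(c(x, y))) <= 1L) return(1)
  suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
}

## start of the first run of at least runLength consecutive TRUEs, or NA
.firstRunStart <- function(flags, runLength) {
  if (!any(flags)) return(NA_integer_)
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= runLength)
  if (!length(hit)) return(NA_integer_)
  ends[hit[1]] - r$lengths[hit[1]] + 1L
}
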