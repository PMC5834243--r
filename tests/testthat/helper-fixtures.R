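# Deterministic fixtures and independent oracles used across the suite.

# evenly spaced spikes with a fixed period; deterministic
regTrain <- function(periodMs, t0 = -1200, t1 = 800, phase = 0) {
  s <- seq(t0 + phase, t1, by = periodMs)
  s[s >= t0 & s <= t1]
}

# a minimal valid basic-task recording: one trial per condition plus
# extras, all spike trains supplied by the caller (recycled)
makeBasicCell <- function(spikes, cellId = "fix1",
                          conditions = c("baseline", "visual_max",
                                         "probe_present_mixed",
                                         "probe_absent_memory", "forget"),
                          fixationOnMs = -1200, trialEndMs = 800) {
  n <- length(conditions)
  blockOf <- c(baseline = 1L, visual_max = 2L, probe_present_mixed = 3L,
               probe_absent_memory = 3L, forget = 4L)
  ev <- data.frame(
    trialIndex = seq_len(n) - 1L,
    blockId = unname(blockOf[conditions]),
    condition = conditions, saccadeId = "s1",
    fixationOnMs = fixationOnMs,
    probeOnMs = ifelse(conditions %in% c("visual_max",
                                         "probe_present_mixed"),
                       -500, NA_real_),
    trialEndMs = trialEndMs)
  if (length(spikes) < n)
    spikes <- rep(spikes, length.out = n)
  CellRecording(cellId, "fixA", "basic", ev, spikes[seq_len(n)])
}

# independent homogeneous/step Poisson trial simulator (not the package
# generator) for latency oracles
simStepTrials <- function(n, baseHz, ampHz, onsetMs, seed,
                          t0 = -1200, t1 = 800) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    rateMax <- baseHz + ampHz
    if (rateMax <= 0) return(numeric(0))
    nn <- rpois(1, rateMax * (t1 - t0) / 1000)
    cand <- sort(runif(nn, t0, t1))
    keep <- runif(nn) < (baseHz + ampHz * (cand >= onsetMs)) / rateMax
    cand[keep]
  })
}

# exhaustive-pair medcouple oracle: explicit double loop over the sorted
# sample with the standard -1/0/+1 kernel for pairs tied at the median
medcoupleOracle <- function(x) {
  z <- sort(x)
  n <- length(z)
  m <- stats::median(z)
  if (z[1] == z[n]) return(0)
  lowIdx <- which(z <= m)
  upIdx <- which(z >= m)
  kLow <- sum(z[lowIdx] == m)
  kUp <- sum(z[upIdx] == m)
  stopifnot(kLow == kUp)
  h <- numeric(0)
  for (a in seq_along(upIdx)) {
    for (b in seq_along(lowIdx)) {
      xu <- z[upIdx[a]]
      xl <- z[lowIdx[b]]
      if (xu == m && xl == m) {
        # a ranks the tied values inside the upper list (ascending, they
        # come first); b ranks them inside the lower list (they come
        # last): positions within the tie block
        i <- a
        j <- b - (length(lowIdx) - kLow)
        h <- c(h, sign(i + j - (kUp + 1)))
      } else {
        h <- c(h, ((xu - m) - (m - xl)) / (xu - xl))
      }
    }
  }
  stats::median(h)
}

# trailing-boxcar smoothing oracle: direct loop with prefix handling
boxcarOracle <- function(x, k) {
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    lo <- max(1L, i - k + 1L)
    out[i] <- mean(x[lo:i])
  }
  out
}
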