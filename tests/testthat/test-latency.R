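test_that("baseline-window selection obeys the latest-match tie-break", {
  # homogeneous trains: every subwindow has the same median, so the
  # latest one (closest to the response epoch) wins
  trials <- rep(list(regTrain(20)), 5)
  expect_equal(selectBaselineWindow(trials), c(-426, -226))
  # a single fitting subwindow is returned as-is
  expect_equal(selectBaselineWindow(trials, fixationOnMs = -426.5),
               c(-426.5, -226.5))
  expect_error(selectBaselineWindow(trials, fixationOnMs = -300),
               "too short")
})

test_that("baseline selection skips a window inflated by an early burst", {
  # tonic 10 Hz-equivalent regular train plus a dense burst confined to
  # [-1200, -1000]: windows overlapping the burst have inflated medians
  trials <- rep(list(sort(c(regTrain(100),
                            seq(-1190, -1010, by = 4)))), 7)
  win <- selectBaselineWindow(trials)
  expect_gte(win[1], -1000)
  # exhaustive oracle: recompute every window median and apply the rule
  starts <- seq(-1200, -426, by = 1)
  meds <- vapply(starts, function(s)
    median(vapply(trials, function(sp)
      sum(sp >= s & sp < s + 200), numeric(1))), numeric(1))
  M <- median(meds)
  expect_equal(win[1], max(starts[abs(meds - M) <= 1]))
})

test_that("threshold crossing recovers a deterministic onset exactly", {
  # silent baseline, then 3 spikes in every 2-ms bin from +80 ms on:
  # cutoff 0 and an immediate sustained run
  resp <- sort(c(seq(80, 500, by = 2), seq(80.5, 500, by = 2),
                 seq(81, 500, by = 2)))
  trials <- rep(list(resp), 9)
  lat <- latencyThresholdCrossing(trials)
  # recovered to within one bin of the true 80 ms onset (the scan grid is
  # anchored at the response-epoch start, so bin edges need not fall on 80)
  expect_lte(abs(lat - 80), 2)
  # and never earlier than onset minus one bin on deterministic data
  expect_gte(lat, 80 - 2)
  # pure baseline continuation: no crossing
  expect_true(is.na(latencyThresholdCrossing(rep(list(regTrain(100)), 9))))
  expect_true(is.na(latencyThresholdCrossing(rep(list(numeric(0)), 9))))
})

test_that("rank-sum latency detects a deterministic step ahead of onset", {
  # identical distributions in baseline and response epochs: absent
  flat <- rep(list(regTrain(25)), 30)
  expect_true(is.na(latencyRanksum(flat)))
  # strong deterministic step at +100 over a phase-balanced tonic train
  # (one spike per 25 ms, so every 50-ms window holds exactly 2): the
  # forward 50-ms window first overlaps the response up to 50 ms early,
  # never later than onset
  resp <- lapply(1:30, function(i)
    sort(c(regTrain(25), seq(100 + (i %% 2), 500, by = 4))))
  lat <- latencyRanksum(resp)
  expect_false(is.na(lat))
  expect_gte(lat, 100 - 51)
  expect_lte(lat, 100)
})

test_that("latency estimation falls back from threshold to rank-sum", {
  # detectable step -> threshold method
  resp <- rep(list(sort(c(seq(80, 500, by = 2), seq(81, 500, by = 2),
                          seq(81.5, 500, by = 2)))), 9)
  est <- estimateLatency(resp)
  expect_equal(est$method, "threshold_crossing")
  expect_lte(abs(est$latencyMs - 80), 2)
  # a response carried by a 40% subset of trials leaves the across-trial
  # median at baseline (defeating the sustained-run criterion) but shifts
  # the distribution, which the rank test detects
  baselinePat <- regTrain(25)
  hot <- sort(c(baselinePat, seq(100, 500, by = 4)))
  trials <- c(rep(list(hot), 16), rep(list(baselinePat), 24))
  expect_true(is.na(latencyThresholdCrossing(trials)))
  est2 <- estimateLatency(trials)
  expect_equal(est2$method, "ranksum")
  expect_gte(est2$latencyMs, 100 - 51)
  expect_lte(est2$latencyMs, 100)
  # flat deterministic activity: neither method reports a latency
  est3 <- estimateLatency(rep(list(regTrain(50)), 20))
  expect_equal(est3$method, "none")
  expect_true(is.na(est3$latencyMs))
})

test_that("latency estimates are deterministic given identical inputs", {
  trials <- simStepTrials(80, 10, 50, 100, seed = 21)
  expect_identical(latencyThresholdCrossing(trials),
                   latencyThresholdCrossing(trials))
  expect_identical(latencyRanksum(trials), latencyRanksum(trials))
})

test_that("stronger responses are not detected later, and the two methods
           bracket a step onset from opposite sides", {
  # seeded Poisson step cells; expected threshold latency decreases (or
  # stays) as amplitude grows, and sits within [onset, onset + 12] while
  # the forward-window rank-sum sits within [onset - 51, onset]
  onset <- 100
  meanLat <- sapply(c(20, 50, 100), function(amp) {
    lats <- sapply(1:6, function(s)
      latencyThresholdCrossing(simStepTrials(200, 10, amp, onset,
                                             seed = 1000 * amp + s)))
    mean(lats, na.rm = TRUE)
  })
  expect_false(is.unsorted(rev(meanLat)))   # non-increasing in amplitude
  trials <- simStepTrials(300, 10, 80, onset, seed = 77)
  tc <- latencyThresholdCrossing(trials)
  rs <- latencyRanksum(trials)
  expect_gte(tc, onset)
  expect_lte(tc, onset + 12)
  expect_gte(rs, onset - 51)
  expect_lte(rs, onset)
})
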