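test_that("binned rates match counts exactly on a deterministic train", {
  p <- buildPsth(list(c(1, 3, 5)), window = c(0, 6), binWidthMs = 2)
  expect_equal(binStarts(p), c(0, 2, 4))
  expect_equal(psthRate(p), c(500, 500, 500))  # 1 spike / 2 ms
  expect_equal(psthSem(p), c(0, 0, 0))         # single trial
  expect_equal(nTrials(p), 1L)
})

test_that("a window too narrow for one bin yields empty arrays", {
  p <- buildPsth(list(c(0.2, 0.4)), window = c(0, 1), binWidthMs = 2)
  expect_length(psthRate(p), 0L)
  expect_length(psthSem(p), 0L)
  expect_length(binStarts(p), 0L)
  expect_error(buildPsth(list(), c(0, 6), 2), "empty")
})

test_that("rate mass equals mean per-trial spike count before smoothing", {
  set.seed(101)
  for (rep in 1:5) {
    trials <- lapply(1:20, function(i) sort(runif(rpois(1, 30), -200, 400)))
    p <- buildPsth(trials, window = c(-200, 400), binWidthMs = 2)
    mass <- sum(psthRate(p)) * 2 / 1000
    meanCount <- mean(vapply(trials, function(s)
      sum(s >= -200 & s < 400), numeric(1)))
    expect_equal(mass, meanCount, tolerance = 1e-12)
  }
})

test_that("trial-averaged rate of homogeneous Poisson trains is unbiased", {
  # 200 trials at 20 Hz: grand mean within 3 standard errors of 20 spikes/s
  trials <- simStepTrials(200, baseHz = 20, ampHz = 0, onsetMs = 0,
                          seed = 7, t0 = 0, t1 = 1000)
  p <- buildPsth(trials, window = c(0, 1000), binWidthMs = 2)
  counts <- vapply(trials, length, numeric(1))
  se <- sd(counts) / sqrt(length(counts))  # spikes per 1-s trial
  expect_lt(abs(mean(psthRate(p)) - 20), 3 * se)
})

test_that("causal smoothing is a trailing boxcar with prefix handling", {
  # constants are invariant
  const <- buildPsth(list(regTrain(2, 0, 100, phase = 1)), c(0, 100), 2)
  expect_equal(psthRate(smoothCausal(const, 10)), psthRate(const))
  # a unit impulse spreads 1/5 over its own and the 4 following bins
  imp <- buildPsth(list(rep(51, 10)), c(0, 100), 2)
  sm <- smoothCausal(imp, 10)
  iPk <- which(psthRate(imp) > 0)
  expect_equal(psthRate(sm)[iPk + 0:4], rep(psthRate(imp)[iPk] / 5, 5))
  expect_equal(sum(psthRate(sm) > 0), 5L)
  # random input agrees with an independent loop oracle
  set.seed(33)
  trials <- lapply(1:8, function(i) sort(runif(40, 0, 200)))
  p <- buildPsth(trials, c(0, 200), 2)
  expect_equal(psthRate(smoothCausal(p, 10)), boxcarOracle(psthRate(p), 5))
  expect_equal(psthRate(smoothCausal(p, 20)), boxcarOracle(psthRate(p), 10))
  expect_error(smoothCausal(p, 5), "multiple")
  # monotone input stays monotone: bin i holds i spikes
  stair <- sort(unlist(lapply(1:10, function(i) rep(2 * i - 1, i))))
  rampOut <- psthRate(smoothCausal(buildPsth(list(stair), c(0, 20), 2), 10))
  expect_false(is.unsorted(rampOut))
})

test_that("baseline normalization divides rates and commutes with smoothing", {
  trials <- lapply(1:6, function(i) regTrain(10, 0, 200, phase = i))
  p <- buildPsth(trials, c(0, 200), 2)
  # dividing by 1 is the identity
  expect_equal(psthRate(normalizeToBaseline(p, 1)), psthRate(p))
  # dividing by r then 1/r restores the original
  expect_equal(psthRate(normalizeToBaseline(normalizeToBaseline(p, 4),
                                            1 / 4)), psthRate(p))
  # normalizing by the psth's own mean gives mean 1
  expect_equal(mean(psthRate(normalizeToBaseline(p, mean(psthRate(p))))), 1)
  # sem scales with the rate
  expect_equal(psthSem(normalizeToBaseline(p, 4)), psthSem(p) / 4)
  expect_error(normalizeToBaseline(p, 0), "positive")
  # commutes with smoothing
  expect_equal(psthRate(smoothCausal(normalizeToBaseline(p, 4), 10)),
               psthRate(normalizeToBaseline(smoothCausal(p, 10), 4)))
  # subtract mode shifts instead
  expect_equal(psthRate(normalizeToBaseline(p, 10, mode = "subtract")),
               psthRate(p) - 10)
})

test_that("per-bin SEM is recomputed from per-trial smoothed rates", {
  set.seed(9)
  trials <- lapply(1:30, function(i) sort(runif(20, 0, 200)))
  sm <- smoothCausal(buildPsth(trials, c(0, 200), 2), 10)
  # oracle: smooth each trial's binned rates, then sd/sqrt(n)
  perTrial <- t(vapply(trials, function(s) {
    cnt <- tabulate(findInterval(s, seq(0, 200, by = 2)), nbins = 100)
    boxcarOracle(cnt / 0.002, 5)
  }, numeric(100)))
  expect_equal(psthSem(sm), apply(perTrial, 2, sd) / sqrt(30))
})
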