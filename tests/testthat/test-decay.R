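test_that("decay series normalizes per-trial counts as specified", {
  # every trial identical: forgetting activity equals the probe-trial
  # normalizer, so the normalized series is all ones
  train <- sort(c(regTrain(40), seq(110, 290, by = 10)))
  cell <- makeBasicCell(
    rep(list(train), 75),
    conditions = c(rep("baseline", 5), rep("visual_max", 5),
                   rep("probe_present_mixed", 5),
                   rep("probe_absent_memory", 5), rep("forget", 55)))
  s <- buildDecaySeries(cell)
  expect_equal(length(s$normalized), 50L)  # capped at the 50-trial epoch
  expect_equal(s$trialOrdinal, 0:49)
  expect_equal(s$normalized, rep(1, 50))
  # silent forgetting block: zeros
  silent <- makeBasicCell(
    c(rep(list(train), 20), rep(list(numeric(0)), 55)),
    conditions = c(rep("baseline", 5), rep("visual_max", 5),
                   rep("probe_present_mixed", 5),
                   rep("probe_absent_memory", 5), rep("forget", 55)))
  sSilent <- buildDecaySeries(silent)
  expect_equal(sSilent$normalized, rep(0, 50))
  # the three normalization modes agree on identical-trial data
  expect_equal(buildDecaySeries(cell, mode = "stim_block_mean")$normalized,
               rep(1, 50))
  expect_equal(buildDecaySeries(cell, mode = "peak_memory")$normalized,
               rep(1, 50))
})

test_that("zero normalizer is an explicit error", {
  quietProbe <- makeBasicCell(
    c(rep(list(regTrain(40)), 10), rep(list(numeric(0)), 10),
      rep(list(c(150, 160, 170)), 15)),
    conditions = c(rep("baseline", 5), rep("visual_max", 5),
                   rep("probe_present_mixed", 10),
                   rep("probe_absent_memory", 5), rep("forget", 10)))
  expect_error(buildDecaySeries(quietProbe), "normalizer")
})

test_that("noiseless exponentials are recovered to machine precision", {
  f <- fitExponential(exp(-0.3 * (0:49)))
  expect_equal(f$k, 0.3, tolerance = 1e-6)
  expect_equal(f$rSquared, 1, tolerance = 1e-9)
  expect_equal(f$a, 1, tolerance = 1e-5)
  expect_equal(f$c, 0, tolerance = 1e-5)
  expect_equal(f$tau, 1 / f$k)
  # with an offset
  f2 <- fitExponential(2.5 * exp(-0.1 * (0:49)) + 0.7)
  expect_equal(f2$k, 0.1, tolerance = 1e-6)
  expect_equal(f2$c, 0.7, tolerance = 1e-5)
  # constant series degenerate fit
  f3 <- fitExponential(rep(2, 20))
  expect_equal(f3$k, 0)
  expect_equal(f3$a, 0)
  expect_equal(f3$c, 2)
  expect_equal(f3$rSquared, 0)
  expect_error(fitExponential(1:5), "at least 10")
})

test_that("exponential fitting is scale-equivariant", {
  set.seed(14)
  y <- exp(-0.2 * (0:39)) + rnorm(40, sd = 0.05)
  f1 <- fitExponential(y)
  f2 <- fitExponential(5 * y)
  expect_equal(f2$k, f1$k, tolerance = 1e-6)
  expect_equal(f2$a, 5 * f1$a, tolerance = 1e-5)
  expect_equal(f2$c, 5 * f1$c, tolerance = 1e-5)
  expect_equal(f2$rSquared, f1$rSquared, tolerance = 1e-9)
})

test_that("noisy decay rates are recovered within 20% at the median", {
  set.seed(61)
  kh <- replicate(100, {
    y <- exp(-0.3 * (0:49)) + rnorm(50, sd = 0.1)
    fitExponential(y)$k
  })
  expect_lt(abs(median(kh) - 0.3), 0.2 * 0.3)
})

test_that("first/last trial comparison behaves at its boundaries", {
  # identical segments: no evidence
  expect_equal(compareFirstLast(rep(2, 50)), 1)
  # strictly decreasing noiseless series attains the minimal two-sided
  # exact rank-sum p for 10 vs 10: 2 / choose(20, 10)
  expect_equal(compareFirstLast(seq(1, 0.02, length.out = 50)),
               2 / choose(20, 10))
  expect_error(compareFirstLast(rep(1, 15)), "at least 20")
  # null constant-rate series reject at about the nominal level
  set.seed(71)
  rej <- mean(replicate(200, {
    compareFirstLast(rpois(50, 5)) < 0.05
  }))
  expect_gte(rej, 0.005)
  expect_lte(rej, 0.12)
})

test_that("population decay fit recovers an injected forgetting rate", {
  bp <- syntheticCellParams(decayKPerTrial = 0.2,
                            nBlockTrials = c(10L, 15L, 40L, 50L))
  pop <- generatePopulation(25, memoryFraction = 1, seed = 301,
                            baseParams = bp)
  sl <- lapply(pop$cells, buildDecaySeries)
  pd <- populationDecay(sl)
  expect_equal(length(pd$meanSeries), 50L)
  expect_lt(abs(pd$fit$k - 0.2), 0.3 * 0.2)
  expect_lt(pd$firstLastP, 0.05)
})
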