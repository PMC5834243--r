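test_that("medcouple matches anchor values and the exhaustive-pair oracle", {
  expect_equal(medcouple(c(1, 2, 3)), 0)
  expect_equal(medcouple(c(1, 2, 4, 7, 8)), 1 / 7)
  expect_equal(medcouple(c(1, 2, 4, 7, 8)),
               medcoupleOracle(c(1, 2, 4, 7, 8)))
  expect_equal(medcouple(rep(3, 6)), 0)
  expect_error(medcouple(c(1, 2)), "at least 3")
  set.seed(88)
  for (i in 1:60) {
    n <- sample(3:40, 1)
    x <- if (i %% 3 == 0) sample(0:4, n, replace = TRUE) else rnorm(n)
    if (length(unique(x)) == 1L) x[1] <- x[1] + 1
    expect_equal(medcouple(x), medcoupleOracle(x))
  }
})

test_that("medcouple is antisymmetric, bounded and affine-invariant", {
  set.seed(99)
  for (i in 1:30) {
    x <- rexp(sample(5:60, 1))
    mc <- medcouple(x)
    expect_gte(mc, -1); expect_lte(mc, 1)
    expect_equal(medcouple(-x), -mc)
    expect_equal(medcouple(3.7 * x + 11), mc)
  }
})

test_that("median-shift test reduces to an exact sign decision", {
  # mean exactly zero: all paired differences vanish, no evidence
  expect_equal(medianShiftTest(c(-2, -1, 0, 1, 2)), 1)
  # non-zero mean: all n differences share one sign; the two-sided
  # p-value equals the exact signed-rank tail 2 * (1/2)^n -- oracle: the
  # tied-rank statistic is a scaled Binomial(n, 1/2) count, so the tail
  # is pbinom at n
  x <- rnorm(20) + 5
  pOracle <- 2 * pbinom(19, 20, 0.5, lower.tail = FALSE)
  expect_equal(medianShiftTest(x), pOracle)
  expect_equal(medianShiftTest(x), 2 * 0.5^20)
  # p depends only on n, not the magnitude of the mean
  expect_equal(medianShiftTest(rnorm(20) + 0.001 + 10),
               medianShiftTest(rnorm(20) - 50))
  expect_error(medianShiftTest(1:4), "at least 5")
})

test_that("identical conditions never classify as memory cells", {
  train <- sort(c(regTrain(40), seq(120, 300, by = 10)))
  cell <- makeBasicCell(
    rep(list(train), 20),
    conditions = c(rep("baseline", 6), "visual_max",
                   rep("probe_present_mixed", 3),
                   rep("probe_absent_memory", 6), rep("forget", 4)))
  cls <- classifyMemoryCell(cell)
  expect_false(cls$isMemoryCell)
  expect_equal(cls$rMem, cls$rPre)
  # too few trials per condition is an error, not a silent result
  tiny <- makeBasicCell(rep(list(train), 5))
  expect_error(classifyMemoryCell(tiny), "trials")
})

test_that("classification detects a strong synthetic memory response", {
  cell <- generateCell(syntheticCellParams(memoryAmpHz = 20, seed = 5))
  cls <- classifyMemoryCell(cell)
  expect_true(cls$isMemoryCell)
  expect_lt(cls$memoryP, 0.05)
  expect_gt(cls$rMem, cls$rPre)
  null <- generateCell(syntheticCellParams(memoryAmpHz = 0, seed = 6))
  expect_false(classifyMemoryCell(null)$isMemoryCell)
})

test_that("eye-position exclusion flags postsaccadic tonic modulation only", {
  # block-1 trials silent: identical samples, not excluded
  quiet <- makeBasicCell(rep(list(numeric(0)), 8),
                         conditions = c(rep("baseline", 4), "visual_max",
                                        "probe_present_mixed",
                                        "probe_absent_memory", "forget"))
  ex <- excludeEyePosition(quiet)
  expect_false(ex$excluded)
  expect_equal(ex$p, 1)
  # stationary Poisson block 1: not excluded (seeded)
  blocks <- c(60L, 10L, 20L, 10L)  # enough block-1 trials for the test
  null <- generateCell(syntheticCellParams(seed = 31,
                                           nBlockTrials = blocks))
  expect_false(excludeEyePosition(null)$excluded)
  # tonic postsaccadic rate doubling: excluded
  mod <- generateCell(syntheticCellParams(eyePositionModulationHz = 10,
                                          seed = 32,
                                          nBlockTrials = blocks))
  expect_true(excludeEyePosition(mod)$excluded)
})

test_that("population summary aggregates counts, median, skewness and shift", {
  idx <- c(0.6, 0.5, 0.4, 0.3, -0.1, -0.05, 0, 0.05, 0.1, 0.2)
  isMem <- c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 6))
  s <- summarizePopulation(idx, isMem)
  expect_equal(s$nTotal, 10L)
  expect_equal(s$nMemory, 4L)
  expect_equal(s$proportionMemory, 0.4)
  expect_equal(s$indexMedian, median(idx))
  expect_equal(s$medcouple, medcoupleOracle(idx))
  expect_equal(s$medianShiftP, 2 * 0.5^10)
  expect_equal(summarizePopulation(rep(0.2, 8), rep(FALSE, 8))$medcouple, 0)
  expect_error(summarizePopulation(numeric(0), logical(0)), "empty")
})
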