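test_that("step-count histograms respect the conditional-binomial law", {
  # full labelling: every spot shows all four steps
  h <- simulateStepCounts(100, 4, 1.0, seed = 3)
  expect_equal(nSpots(h), 100L)
  expect_equal(unname(stepCounts(h)[["4"]]), 100L)
  expect_equal(sum(stepCounts(h)[c("1", "2", "3")]), 0L)

  # dimer at p = 0.5: conditioning drops the (0,0) outcome, so the
  # enumerated pmf is {1: 2/3, 2: 1/3}; large-sample proportions agree
  # within 3 standard errors
  h2 <- simulateStepCounts(300000, 2, 0.5, seed = 9)
  prop <- stepCounts(h2) / nSpots(h2)
  se <- sqrt(c(2 / 3 * 1 / 3, 1 / 3 * 2 / 3) / 300000)
  expect_lt(abs(prop[["1"]] - 2 / 3), 3 * se[1])
  expect_lt(abs(prop[["2"]] - 1 / 3), 3 * se[2])

  # convergence to the conditional pmf: total-variation distance shrinks
  # with sample size (checked at two sizes, fixed seeds)
  pmf <- conditionalBinomialPmf(4, 0.776)
  tv <- function(n) {
    h <- simulateStepCounts(n, 4, 0.776, seed = 21)
    sum(abs(stepCounts(h) / n - pmf)) / 2
  }
  expect_gt(tv(200), tv(200000))
  expect_lt(tv(200000), 0.01)

  expect_error(simulateStepCounts(0, 4, 0.5), "nSpots")
  expect_error(simulateStepCounts(10, 4, 1.5), "pFluor")
  expect_error(simulateStepCounts(10, 4, 0), "dark")
})

test_that("bleach traces are a noisy staircase with recorded truth", {
  cfg0 <- traceSimConfig(noiseSd = 0)
  # no fluorophores: flat zero, no steps
  tr0 <- simulateBleachTrace(cfg0, 0)
  expect_true(all(intensities(tr0) == 0))
  expect_length(groundTruthSteps(tr0), 0)

  # noiseless: exactly nFluor unit drops ending at zero
  tr3 <- simulateBleachTrace(cfg0, 3, seed = 8)
  x <- intensities(tr3)
  drops <- diff(x)
  expect_equal(sum(drops < 0), 3)
  expect_true(all(drops[drops < 0] == -cfg0$stepAmplitude))
  expect_equal(x[1], 3 * cfg0$stepAmplitude)
  expect_equal(x[length(x)], 0)
  expect_equal(length(groundTruthSteps(tr3)), 3)

  # level at each frame equals nFluor minus bleaches so far
  t_frames <- (seq_len(nFrames(tr3)) - 1) * frameInterval(tr3) / 1000
  lvl <- 3 - findInterval(t_frames, groundTruthSteps(tr3))
  expect_equal(intensities(tr3), lvl * cfg0$stepAmplitude)

  expect_error(simulateBleachTrace(cfg0, 5), "nFluor")
})

test_that("reversal pairs invert the GHK relation exactly at zero noise", {
  # symmetric baths, nonselective channel: no shift at all
  rec1 <- simulateReversalPairs(electroSimConfig(trueRatio = 1,
                                                 erevNoiseSd = 0))
  expect_equal(rec1$erev_na_mV - rec1$erev_k_mV, rep(0, nrow(rec1)))

  # trueRatio 2 at 295.15 K: (RT/F) ln 2 = 17.63 mV
  rec2 <- simulateReversalPairs(electroSimConfig(trueRatio = 2,
                                                 erevNoiseSd = 0))
  expect_equal(rec2$erev_na_mV - rec2$erev_k_mV,
               rep(1000 * 8.314 * 295.15 / 96485 * log(2), nrow(rec2)),
               tolerance = 1e-12)
  expect_equal(rec2$erev_na_mV[1] - rec2$erev_k_mV[1], 17.63,
               tolerance = 1e-3)

  # round-trip identity for arbitrary ratios and asymmetric baths
  for (ratio in c(0.1, 0.5, 1, 2, 10)) {
    cfg <- electroSimConfig(trueRatio = ratio, naOut = 98, kOut = 49,
                            erevNoiseSd = 0, nCells = 4)
    rec <- simulateReversalPairs(cfg)
    got <- permeabilityRatio(rec, ionCondition(98, 49))$ratio
    expect_equal(got, rep(ratio, 4), tolerance = 1e-12)
  }
})

test_that("pose fixtures plant the partition they claim", {
  ctr <- rbind(c(0, 0, 0), c(40, 0, 0), c(0, 40, 0))
  ps <- generatePoseFixture(poseSimConfig(ctr, c(4, 4, 2), spreadSd = 0.5))
  expect_equal(nPoses(ps), 10)
  expect_equal(poseRanks(ps), 1:10)
  expect_equal(trueClusters(ps), rep(1:3, c(4, 4, 2)))
  # affinities ordered: rank #1 most favorable
  expect_true(all(diff(affinities(ps)) > 0))

  # spread 0, single pose: exactly at its center
  one <- generatePoseFixture(poseSimConfig(matrix(c(1, 2, 3), 1), 1,
                                           spreadSd = 0))
  expect_equal(colMeans(poseCoords(one)[[1]]), c(1, 2, 3),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("alignment fixtures carry the stated TM overlap structure", {
  # identical annotations, no distortion: perfect consistency
  fx0 <- generateAlignmentFixture(30, 30, cbind(c(5, 20), c(10, 26)))
  expect_equal(overallScore(tmConsistencyScore(fx0$aln, fx0$tmA, fx0$tmB)), 1)

  # distortion at least the TM length: disjoint, zero overlap
  fxd <- generateAlignmentFixture(30, 30, cbind(5, 10), distortion = 6)
  expect_equal(overallScore(tmConsistencyScore(fxd$aln, fxd$tmA, fxd$tmB)), 0)

  expect_error(generateAlignmentFixture(10, 10, cbind(8, 12)), "bounds")
  expect_error(generateAlignmentFixture(10, 10, cbind(3, 6), distortion = 5),
               "bounds")
})

test_that("generators are deterministic in the seed and vary across seeds", {
  a <- simulateStepCounts(500, 4, 0.7, seed = 5)
  b <- simulateStepCounts(500, 4, 0.7, seed = 5)
  c <- simulateStepCounts(500, 4, 0.7, seed = 6)
  expect_identical(stepCounts(a), stepCounts(b))
  expect_false(identical(stepCounts(a), stepCounts(c)))

  r1 <- simulateReversalPairs(electroSimConfig(seed = 5))
  r2 <- simulateReversalPairs(electroSimConfig(seed = 5))
  r3 <- simulateReversalPairs(electroSimConfig(seed = 6))
  expect_identical(r1, r2)
  expect_false(identical(r1$erev_na_mV, r3$erev_na_mV))

  # generators do not disturb the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(simulateStepCounts(100, 4, 0.7, seed = 1))
  expect_identical(runif(3), before)
})
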