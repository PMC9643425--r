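test_that("conditional binomial pmf matches exhaustive enumeration", {
  # oracle: enumerate all 2^n fluorophore on/off configurations, drop the
  # all-dark one, renormalize
  enumPmf <- function(n, p) {
    states <- expand.grid(rep(list(c(0, 1)), n))
    prob <- apply(states, 1, function(s) prod(ifelse(s == 1, p, 1 - p)))
    k <- rowSums(states)
    keep <- k >= 1
    tab <- tapply(prob[keep], k[keep], sum) / sum(prob[keep])
    as.numeric(tab[as.character(1:n)])
  }
  for (n in 1:6)
    for (p in c(0.1, 0.5, 0.776, 0.95))
      expect_equal(unname(conditionalBinomialPmf(n, p)), enumPmf(n, p),
                   tolerance = 1e-12)

  expect_equal(conditionalBinomialPmf(4, 1.0),
               c(`1` = 0, `2` = 0, `3` = 0, `4` = 1))
  expect_equal(unname(conditionalBinomialPmf(2, 0.5)), c(2 / 3, 1 / 3),
               tolerance = 1e-15)
  expect_equal(unname(conditionalBinomialPmf(4, 0.776)),
               c(0.0350, 0.1817, 0.4197, 0.3635), tolerance = 2e-4)
  expect_error(conditionalBinomialPmf(4, 0), "p = 0")
})

test_that("conditional pmf sums to one across the (n, p) grid", {
  for (n in 1:8)
    for (p in seq(0.01, 1, by = 0.09))
      expect_equal(sum(conditionalBinomialPmf(n, p)), 1, tolerance = 1e-12)
})

test_that("fitP maximizes the conditional multinomial likelihood", {
  # all mass at the top bin: boundary MLE at p = 1
  expect_equal(as.numeric(fitP(StepCountHistogram(c(`4` = 569)), 4)), 1)

  # histogram built from the pmf at P = 0.776; oracle = grid search
  h <- StepCountHistogram(c(`1` = 35, `2` = 182, `3` = 420, `4` = 363))
  grid <- seq(1e-4, 1, by = 1e-4)
  ll <- vapply(grid, function(p)
    sum(c(35, 182, 420, 363) * log(conditionalBinomialPmf(4, p))),
    numeric(1))
  pGrid <- grid[which.max(ll)]
  expect_equal(as.numeric(fitP(h, 4)), pGrid, tolerance = 1e-4)
  expect_equal(as.numeric(fitP(h, 4)), 0.776, tolerance = 0.01)

  # least-squares variant lands close by on the same data
  expect_equal(as.numeric(fitP(h, 4, method = "ls")), 0.776,
               tolerance = 0.02)

  # degenerate: everything in the first bin pushes p to the 0+ boundary
  pLow <- fitP(StepCountHistogram(c(`1` = 100)), 4)
  expect_lt(as.numeric(pLow), 1e-4)
  expect_true(attr(pLow, "degenerate"))

  expect_error(fitP(StepCountHistogram(c(`5` = 10)), 4), "above")
})

test_that("fitP is order-invariant and monotone in the mass location", {
  h1 <- StepCountHistogram(c(`1` = 10, `2` = 50, `3` = 100, `4` = 40))
  h2 <- StepCountHistogram(c(`4` = 40, `2` = 50, `1` = 10, `3` = 100))
  expect_identical(as.numeric(fitP(h1, 4)), as.numeric(fitP(h2, 4)))

  # moving spots from low to high step counts can only raise p_hat
  h3 <- StepCountHistogram(c(`1` = 5, `2` = 50, `3` = 100, `4` = 45))
  expect_gt(as.numeric(fitP(h3, 4)), as.numeric(fitP(h1, 4)))
})

test_that("p_hat recovery at the tetramer operating point is unbiased", {
  ph <- vapply(1:200, function(s)
    as.numeric(fitP(simulateStepCounts(569, 4, 0.776, seed = s), 4)),
    numeric(1))
  expect_lt(abs(mean(ph) - 0.776), 0.01)
})

test_that("gofTest reproduces hand-computed Pearson statistics", {
  # observed {1:10, 2:10} under the (2, 0.5) model: expected {40/3, 20/3}
  g <- gofTest(StepCountHistogram(c(`1` = 10, `2` = 10)), 2, p = 0.5,
               pFitted = FALSE)
  handChisq <- (10 - 40 / 3)^2 / (40 / 3) + (10 - 20 / 3)^2 / (20 / 3)
  expect_equal(g$chisq, handChisq, tolerance = 1e-10)
  expect_equal(g$chisq, 2.5, tolerance = 1e-10)
  expect_equal(g$df, 1L)
  expect_equal(g$pValue, pchisq(2.5, 1, lower.tail = FALSE))

  # 3-bin toy with a fitted-p df convention
  h3 <- StepCountHistogram(c(`1` = 30, `2` = 50, `3` = 20))
  p3 <- 0.4
  e3 <- 100 * conditionalBinomialPmf(3, p3)
  hand3 <- sum((c(30, 50, 20) - e3)^2 / e3)
  g3 <- gofTest(h3, 3, p = p3, pFitted = TRUE)
  expect_equal(g3$chisq, hand3, tolerance = 1e-10)
  expect_equal(g3$df, 1L)       # 3 bins - 1 - 1 fitted parameter
  expect_equal(g3$dfAlt, 2L)

  # perfect agreement: zero statistic, p-value 1
  pmf <- conditionalBinomialPmf(4, 0.7)
  hExact <- StepCountHistogram(setNames(round(pmf * 1e6), 1:4))
  gExact <- gofTest(hExact, 4, p = 0.7, pFitted = FALSE)
  expect_lt(gExact$chisq, 1e-3)
  expect_gt(gExact$pValue, 0.999)

  # empty expected bin with observed mass: flagged certain rejection
  gInf <- gofTest(StepCountHistogram(c(`1` = 5, `4` = 5)), 4, p = 1)
  expect_true(gInf$emptyExpected)
  expect_identical(gInf$chisq, Inf)
  expect_identical(gInf$pValue, 0)

  # observed counts above the model's support also reject with certainty
  gAbove <- gofTest(StepCountHistogram(c(`2` = 50, `3` = 40, `5` = 1)), 4,
                    p = 0.7)
  expect_true(gAbove$emptyExpected)
  expect_identical(gAbove$chisq, Inf)
  # ... while the fit simply ignores the out-of-support spot
  expect_gt(as.numeric(fitP(StepCountHistogram(c(`2` = 50, `3` = 40,
                                                 `5` = 1)), 4)), 0)
})

test_that("goodness-of-fit p-values are uniform under the true model", {
  # correctly specified tetramer data, p refitted per replicate: the
  # chi-squared p-value is asymptotically uniform on (0, 1)
  pv <- vapply(1:400, function(s) {
    h <- simulateStepCounts(569, 4, 0.776, seed = 10000 + s)
    g <- gofTest(h, 4, p = as.numeric(fitP(h, 4)), pFitted = TRUE)
    g$pValue
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 1e-3)
})

test_that("selectOligomer keeps the generating model and rejects others", {
  h <- simulateStepCounts(569, 4, 0.776, seed = 7)
  fits <- selectOligomer(h, candidates = c(4L, 5L, 6L), alpha = 0.05)
  expect_length(fits, 3)
  expect_equal(vapply(fits, nSubunits, integer(1)), c(4L, 5L, 6L))
  expect_true(isRetained(fits[[1]]))
  expect_false(isRetained(fits[[2]]))
  expect_false(isRetained(fits[[3]]))

  # degenerate single-bin data is flagged rather than silently fitted
  f1 <- selectOligomer(StepCountHistogram(c(`1` = 100)), candidates = 4L)
  expect_true(f1[[1]]@degenerate)

  expect_error(selectOligomer(h, candidates = integer(0)), "nonempty")
  expect_error(selectOligomer(h, alpha = 0), "alpha")
})

test_that("detectSteps counts noiseless staircases exactly", {
  expect_equal(detectSteps(BleachTrace(rep(5, 100))), 0L)
  expect_equal(detectSteps(BleachTrace(rep(3:0, each = 25))), 3L)
  for (k in 0:4) {
    tr <- simulateBleachTrace(traceSimConfig(noiseSd = 0), k, seed = k + 1)
    expect_equal(detectSteps(tr), length(groundTruthSteps(tr)))
  }
  # traces shorter than 2 frames are rejected at construction
  expect_error(BleachTrace(3), "2 samples")
})

test_that("detectSteps recovers ground truth on noisy traces", {
  # SNR 5 (unit steps, noise SD 0.2): at least 95% exact recovery
  traces <- simulateTraces(traceSimConfig(noiseSd = 0.2, seed = 42), 500)
  truth <- vapply(traces, function(t) length(groundTruthSteps(t)),
                  integer(1))
  det <- vapply(traces, detectSteps, integer(1))
  expect_gte(mean(det == truth), 0.95)

  # monotone contract: halving the noise cannot hurt recovery
  lowNoise <- simulateTraces(traceSimConfig(noiseSd = 0.1, seed = 42), 200)
  truthL <- vapply(lowNoise, function(t) length(groundTruthSteps(t)),
                   integer(1))
  accL <- mean(vapply(lowNoise, detectSteps, integer(1)) == truthL)
  expect_gte(accL, mean(det[1:200] == truth[1:200]))
})

test_that("countSteps aggregates traces into a histogram", {
  traces <- simulateTraces(traceSimConfig(noiseSd = 0.1, seed = 2), 50)
  h <- countSteps(traces)
  expect_s4_class(h, "StepCountHistogram")
  expect_equal(nSpots(h), 50L)
  truth <- table(vapply(traces, function(t) length(groundTruthSteps(t)),
                        integer(1)))
  expect_equal(unname(stepCounts(h)[names(truth)]),
               unname(as.integer(truth)))
})
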