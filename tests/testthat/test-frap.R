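## iFRAP module: normalization, constrained exponential fits, model
## selection and the soluble/dynamic/stable partition.

noiselessCurve <- function(...) {
  simulateFrapExperiment(frapTruth(..., noiseSd = 0, nCells = 1))[[1]]
}

test_that("normalization anchors every curve at 1 and preserves the decay", {
  cur <- noiselessCurve(stableFracOfBound = 0, kOffDynamic = 1 / 13.7,
                        times = 0:40)
  d <- normalizeIfrap(cur)
  expect_equal(d$signal[1], 1)
  expect_equal(d$signal, exp(-(0:40) / 13.7), tolerance = 1e-12)

  ## noisy curves are still anchored exactly
  curN <- simulateFrapExperiment(frapTruth(noiseSd = 0.05, nCells = 1,
                                           seed = 3))[[1]]
  expect_equal(normalizeIfrap(curN)$signal[1], 1)

  ## full recovery: the difference signal vanishes
  curFast <- noiselessCurve(stableFracOfBound = 0, kOffDynamic = 1,
                            times = 0:30)
  expect_lt(tail(normalizeIfrap(curFast)$signal, 1), 1e-10)

  bad <- new("FrapCurve", cellId = "x", condition = "G1", times = 0:5,
             bleached = rep(1, 6), unbleached = rep(1, 6),
             prebleachMean = 10)
  expect_error(normalizeIfrap(bad), "zero difference")
})

test_that("single-exponential fit recovers the dissociation rate", {
  d <- data.frame(time = 0:40, signal = exp(-(0:40) / 13.7))
  fit <- fitSingleExponential(d)
  expect_equal(residenceDynamic(fit), 13.7, tolerance = 1e-6)

  ## constant signal: rate pinned at the lower bound with a warning
  expect_warning(
    fitFlat <- fitSingleExponential(data.frame(time = 0:20,
                                               signal = rep(1, 21))),
    "lower bound")
  expect_lte(kOff1(fitFlat), 1e-6 * (1 + 1e-6))

  ## 19 noisy cells: mean residence within 10% of the generating 13.7 min
  curves <- simulateFrapExperiment(frapTruth(
    stableFracOfBound = 0, kOffDynamic = 1 / 13.7, noiseSd = 0.03,
    nCells = 19, times = 0:40, seed = 21))
  res <- vapply(curves, function(cur)
    residenceDynamic(fitSingleExponential(normalizeIfrap(cur))), numeric(1))
  expect_lt(abs(mean(res) - 13.7) / 13.7, 0.10)
})

test_that("double-exponential fit respects the slow-residence constraint", {
  t <- 0:60
  mk <- function(a, r1min, r2hr)
    data.frame(time = t, signal = a * exp(-t / r1min) +
                 (1 - a) * exp(-t / (r2hr * 60)))

  ## noiseless recovery inside the constraint box
  fit <- fitDoubleExponential(mk(0.49, 10, 8.6))
  expect_equal(fastAmplitude(fit), 0.49, tolerance = 1e-4)
  expect_equal(residenceDynamic(fit), 10, tolerance = 1e-4)
  expect_equal(residenceStable(fit), 8.6, tolerance = 1e-3)
  expect_false(fit@boundary)

  ## truth outside the box: pinned at 15 hr and flagged
  fitOut <- fitDoubleExponential(mk(0.5, 10, 30))
  expect_equal(residenceStable(fitOut), 15, tolerance = 1e-6)
  expect_true(fitOut@boundary)

  ## a = 1 truth degenerates to the single-exponential answer
  dSingle <- data.frame(time = t, signal = exp(-t / 12))
  fitD <- fitDoubleExponential(dSingle)
  fitS <- fitSingleExponential(dSingle)
  expect_equal(fastAmplitude(fitD), 1, tolerance = 1e-3)
  expect_equal(kOff1(fitD), kOff1(fitS), tolerance = 1e-3)

  ## nested-model consistency with the amplitude fixed at 1
  fitFix <- fitDoubleExponential(dSingle, fixA = 1)
  expect_equal(kOff1(fitFix), kOff1(fitS), tolerance = 1e-6)
})

test_that("model selection follows AICc with a parsimony tie-break", {
  set.seed(5)
  curG1 <- noiselessCurve(stableFracOfBound = 0, kOffDynamic = 1 / 13.7,
                          times = 0:40)
  curG1@bleached <- curG1@bleached +
    rnorm(41, 0, 0.02 * 100 / sqrt(2))      # realistic noise level
  d1 <- normalizeIfrap(curG1)
  sel1 <- selectModel(fitSingleExponential(d1), fitDoubleExponential(d1))
  expect_equal(modelType(sel1), "single")

  curG2 <- noiselessCurve(stableFracOfBound = 0.5, kOffDynamic = 1 / 10,
                          kOffStable = 1 / (8.6 * 60), solubleFrac = 0.27,
                          times = 0:60)
  curG2@bleached <- curG2@bleached + rnorm(61, 0, 0.02 * 100 / sqrt(2))
  d2 <- normalizeIfrap(curG2)
  sel2 <- selectModel(fitSingleExponential(d2), fitDoubleExponential(d2))
  expect_equal(modelType(sel2), "double")

  ## exact tie goes to the single model
  s <- new("FrapFit", model = "single", kOff1 = 0.1,
           residenceDynamic = 10, rss = 1, aicc = -50, nPoints = 40L)
  dd <- new("FrapFit", model = "double", kOff1 = 0.1, kOff2 = 0.005,
            a = 0.5, residenceDynamic = 10, residenceStable = 3.3,
            rss = 1, aicc = -50, nPoints = 40L)
  expect_equal(modelType(selectModel(s, dd)), "single")
  sFail <- s; sFail@converged <- FALSE
  dFail <- dd; dFail@converged <- FALSE
  expect_error(selectModel(sFail, dFail), "both")
})

test_that("soluble fraction arithmetic and clipping behave as specified", {
  expect_equal(solubleFraction(100, 100, 0.5), 0)
  expect_equal(solubleFraction(100, 86.5, 0.5), 0.27)
  expect_equal(solubleFraction(100, 50, 0.5), 1)
  expect_warning(sNeg <- solubleFraction(100, 110, 0.5), "returning 0")
  expect_equal(sNeg, 0)
  expect_warning(sBig <- solubleFraction(100, 30, 0.5), "clipped")
  expect_equal(sBig, 1)
  expect_error(solubleFraction(0, 10, 0.5), "positive")
})

test_that("population partition matches the published fraction arithmetic", {
  d <- data.frame(time = 0:40, signal = exp(-(0:40) / 13.7))
  single <- fitSingleExponential(d)
  p1 <- partitionPopulations(0.365, single)
  expect_equal(c(solubleFrac(p1), dynamicFrac(p1), stableFrac(p1)),
               c(0.365, 0.635, 0))

  t <- 0:60
  dbl <- fitDoubleExponential(data.frame(
    time = t, signal = 0.493 * exp(-t / 10) + 0.507 * exp(-t / 516)))
  p2 <- partitionPopulations(0.27, dbl)
  expect_equal(stableFrac(p2), 0.37, tolerance = 0.01)
  expect_equal(dynamicFrac(p2), 0.36, tolerance = 0.01)

  pAll <- partitionPopulations(1, single)
  expect_equal(c(solubleFrac(pAll), dynamicFrac(pAll), stableFrac(pAll)),
               c(1, 0, 0))
})

test_that("copy-number partition reproduces the published partition table", {
  g1 <- copyNumberPartition(250755, populationFractions(0.3642, 0.6358, 0))
  expect_equal(g1$copies[g1$population == "soluble"], 91318,
               tolerance = 1e-3)
  expect_equal(g1$copies[g1$population == "dynamic"], 159437,
               tolerance = 1e-3)
  ## conservation is exact
  expect_equal(sum(g1$copies[g1$population != "total"]),
               g1$copies[g1$population == "total"])
  expect_equal(g1$copies[g1$population == "total"], 250755)

  g2 <- copyNumberPartition(291939, populationFractions(0.27, 0.36, 0.37))
  expect_equal(g2$copies[g2$population == "soluble"], 79239,
               tolerance = 0.01)
  expect_equal(g2$copies[g2$population == "dynamic"], 104952,
               tolerance = 0.01)
  expect_equal(g2$copies[g2$population == "stable"], 107748,
               tolerance = 0.01)

  all1 <- copyNumberPartition(1000, populationFractions(1, 0, 0))
  expect_equal(all1$copies, c(1000, 0, 0, 1000))
})

test_that("large synthetic G2 ensembles recover rates and fractions", {
  curves <- simulateFrapExperiment(frapTruth(
    solubleFrac = 0.27, stableFracOfBound = 0.5, kOffDynamic = 1 / 10,
    kOffStable = 1 / (8.6 * 60), noiseSd = 0.03, nCells = 200,
    times = 0:60, seed = 11))
  fits <- lapply(curves, function(cur) {
    d <- normalizeIfrap(cur)
    selectModel(fitSingleExponential(d), fitDoubleExponential(d))
  })
  dbl <- fits[vapply(fits, modelType, "") == "double"]
  expect_gt(length(dbl) / length(fits), 0.9)
  r1 <- vapply(dbl, residenceDynamic, numeric(1))
  r2 <- vapply(dbl, residenceStable, numeric(1))
  expect_lt(abs(median(r1) - 10) / 10, 0.15)
  expect_lt(abs(median(r2) - 8.6) / 8.6, 0.15)
  fracs <- lapply(dbl, partitionPopulations, soluble = 0.27)
  avg <- averagePopulationFractions(fracs)
  expect_lt(abs(dynamicFrac(avg) - 0.73 * 0.5), 0.05)
  expect_lt(abs(stableFrac(avg) - 0.73 * 0.5), 0.05)
})
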