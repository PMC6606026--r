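## FCS module: correlator, model fitting, QC, volume/copy conversions,
## bootstrap method comparison.

test_that("trace autocorrelation matches a brute-force oracle", {
  ## constant trace: no fluctuations
  rec <- correlateTrace(rep(5, 200), binWidth = 1)
  expect_true(all(acfValues(rec) == 0))

  ## i.i.d. noise: |G| below 3/sqrt(n) for tau > 0
  set.seed(1)
  tr <- rpois(20000, 20)
  recN <- correlateTrace(tr, binWidth = 0.5)
  expect_true(all(abs(acfValues(recN)) < 3 / sqrt(length(tr))))

  ## periodic trace agrees with the direct O(n^2) autocovariance
  t <- seq_len(600)
  trP <- 10 * (1 + 0.5 * sin(2 * pi * t / 50))
  recP <- correlateTrace(trP, binWidth = 1, maxLag = 100)
  lagBins <- round(acfLags(recP))
  oracle <- bruteAutocorrelation(trP, lagBins)
  ## implementation normalises by n - k as well; agreement is exact
  expect_equal(acfValues(recP), oracle, tolerance = 1e-10)

  expect_error(correlateTrace(rep(0, 100), 1), "zero mean")
  expect_error(correlateTrace(c(1), 1), "at least 2")
})

test_that("noiseless ACF fits recover the generating parameters", {
  ## single component: exact N and R^2 = 1
  rec1 <- simulateFcsMeasurement(fcsTruth(nParticles = 10, tau1 = 2,
                                          tau2 = 2, frac1 = 1))
  f1 <- fitAcf(rec1)
  expect_true(isConverged(f1))
  expect_equal(nParticles(f1), 10, tolerance = 1e-6)
  expect_equal(rSquared(f1), 1, tolerance = 1e-6)

  ## two components: full round trip below 1e-4 relative error
  tr <- fcsTruth(nParticles = 7, tau1 = 0.4, tau2 = 60, frac1 = 0.35,
                 offset = 0.002)
  f2 <- fitAcf(simulateFcsMeasurement(tr))
  expect_equal(nParticles(f2), 7, tolerance = 1e-4)
  expect_equal(f2@tau1, 0.4, tolerance = 1e-4)
  expect_equal(f2@tau2, 60, tolerance = 1e-4)
  expect_equal(f2@frac1, 0.35, tolerance = 1e-4)
  expect_equal(f2@offset, 0.002, tolerance = 1e-3)
})

test_that("noisy ensembles recover N and pure noise is rejected by QC", {
  fits <- lapply(1:200, function(i) {
    fitAcf(simulateFcsMeasurement(
      fcsTruth(nParticles = 12, tau1 = 0.5, tau2 = 30, frac1 = 0.4,
               cpm = 10, noiseSdScale = 0.03, seed = i)))
  })
  medN <- median(vapply(fits, nParticles, numeric(1)), na.rm = TRUE)
  expect_lt(abs(medN - 12) / 12, 0.05)

  ## a curve of pure noise around zero has R^2 near 0 and fails QC
  set.seed(99)
  noiseRec <- new("AcfRecord", cellId = "noise", lags = multipleTauGrid(),
                  acf = rnorm(length(multipleTauGrid()), 0, 0.01),
                  meanIntensity = 100, duration = 30)
  fN <- fitAcf(noiseRec)
  if (isConverged(fN)) expect_lt(rSquared(fN), 0.5)
  qc <- qcFilter(c(fits[1:20], list(fN)), megfpMeanCpm = 10)
  expect_equal(qc$report$nInput - qc$report$nRetained -
                 sum(qc$report$nFailedGoodness, qc$report$nCpmOutlier,
                     qc$report$nCpmCap, qc$report$nNotConverged), 0)
})

test_that("the QC cascade applies the published thresholds", {
  mkFit <- function(r2, chisq, cpmVal) {
    new("AcfFit", nParticles = 10, tau1 = 0.5, tau2 = 30, frac1 = 0.5,
        structureParam = 5, offset = 0, rSquared = r2,
        chisqPerPoint = chisq, cpm = cpmVal, converged = TRUE,
        nPoints = 100L)
  }
  good <- mkFit(0.99, 1.0, 10)
  ## R^2 = 0.90 fails the R^2 > 0.92 rule
  qc1 <- qcFilter(list(good, mkFit(0.90, 1.0, 10)), megfpMeanCpm = 10)
  expect_equal(qc1$report$nFailedGoodness, 1)
  ## chi^2/N = 1.3 fails the chi^2/N < 1.2 rule
  qc2 <- qcFilter(list(good, mkFit(0.99, 1.3, 10)), megfpMeanCpm = 10)
  expect_equal(qc2$report$nFailedGoodness, 1)
  ## identical passing fits: everything retained
  qc3 <- qcFilter(rep(list(good), 5), megfpMeanCpm = 10)
  expect_equal(qc3$report$retainedFraction, 1)
  ## CPM at 10x the reference is removed (cap reads: keep < 10x)
  qc4 <- qcFilter(rep(list(good, mkFit(0.99, 1.0, 100)), 10),
                  megfpMeanCpm = 10, tukeyK = 1e6)
  expect_equal(qc4$report$nCpmCap, 10)
  ## empty input: empty output with a complete report
  qc5 <- qcFilter(list(), megfpMeanCpm = 10)
  expect_length(qc5$retained, 0)
  expect_equal(qc5$report$nInput, 0)

  ## loosening any threshold never shrinks the retained set
  fits <- lapply(1:40, function(i) {
    fitAcf(simulateFcsMeasurement(
      fcsTruth(nParticles = 10, tau1 = 0.5, tau2 = 30, frac1 = 0.4,
               cpm = 10, noiseSdScale = 0.04, seed = i)))
  })
  base <- qcFilter(fits, 10)$report$nRetained
  expect_gte(qcFilter(fits, 10, r2Min = 0.5)$report$nRetained, base)
  expect_gte(qcFilter(fits, 10, chisqMax = 5)$report$nRetained, base)
  expect_gte(qcFilter(fits, 10, tukeyK = 10)$report$nRetained, base)
  expect_gte(qcFilter(fits, 10, cpmCap = 100)$report$nRetained, base)
})

test_that("confocal calibration and concentration conversion are exact", {
  dye <- fitAcf(simulateFcsMeasurement(fcsTruth(nParticles = 15, tau1 = 0.03,
                                                tau2 = 0.03, frac1 = 1)))
  cal <- calibrateConfocalVolume(dye, 50)
  expect_equal(effectiveVolume(cal), 15 / (50e-9 * 6.02214076e23),
               tolerance = 1e-6)
  ## calibration identity: the dye's own fit reads back 50 nM
  expect_equal(concentrationFromFit(dye, cal), 50, tolerance = 1e-9)
  ## linearity: doubling N doubles V_eff
  dye2 <- fitAcf(simulateFcsMeasurement(fcsTruth(nParticles = 30,
                                                 tau1 = 0.03, tau2 = 0.03,
                                                 frac1 = 1)))
  expect_equal(effectiveVolume(calibrateConfocalVolume(dye2, 50)) /
                 effectiveVolume(cal), 2, tolerance = 1e-4)
  ## N = 66 in the calibrated volume reads 220 nM
  f66 <- dye
  f66@nParticles <- 66
  expect_equal(concentrationFromFit(f66, cal), 220, tolerance = 1e-3)

  badFit <- dye
  badFit@converged <- FALSE
  expect_error(calibrateConfocalVolume(badFit, 50), "converge")
  expect_error(concentrationFromFit(dye), "ConfocalCalibration")
})

test_that("copy-number arithmetic follows C * V * N_A", {
  expect_equal(copiesFromConcentration(0, 100), 0)
  ## 330 nM in a 1262 um^3 nucleus: ~250,000 copies
  expect_equal(copiesFromConcentration(330, 1262), 250755,
               tolerance = 5e-3)
  expect_equal(copiesFromConcentration(100, 200) * 2,
               copiesFromConcentration(100, 400))
  expect_error(copiesFromConcentration(-1, 10), "non-negative")

  expect_equal(cytoplasmicVolume(1000, 3.04), 2040)
  expect_equal(cytoplasmicVolume(500, 5.72), 2360)
  expect_equal(cytoplasmicVolume(1000, 1 + 1e-9), 1e-6, tolerance = 1e-3)
  expect_error(cytoplasmicVolume(1000, 1), "exceed")

  ## conservation: compartment copies recombine to the concentration-
  ## weighted total volume product
  cNuc <- 330; cCyt <- 14; vNuc <- 1200
  vCyt <- cytoplasmicVolume(vNuc, 3.04)
  total <- copiesFromConcentration(cNuc, vNuc) +
    copiesFromConcentration(cCyt, vCyt)
  expect_equal(total, (cNuc * vNuc + cCyt * vCyt) * 1e-24 * 6.02214076e23)
})

test_that("condition summaries use median and central 68% interval", {
  s <- summarizeCondition(1:100)
  expect_equal(s$median, 50.5)
  expect_equal(s$lo68, brutePercentile(1:100, 0.16))
  expect_equal(s$hi68, brutePercentile(1:100, 0.84))
  expect_equal(c(s$lo68, s$hi68), c(16.84, 84.16))

  sv <- summarizeCondition(rep(7, 5))
  expect_equal(c(sv$median, sv$lo68, sv$hi68), c(7, 7, 7))
  s1 <- summarizeCondition(3)
  expect_equal(c(s1$lo68, s1$hi68), c(3, 3))
  expect_error(summarizeCondition(numeric(0)), "no values")
})

test_that("CPM stoichiometry flags monomers and dimers", {
  expect_equal(cpmStoichiometry(c(4, 5, 6), c(4, 5, 6)), 1)
  expect_equal(cpmStoichiometry(c(8, 10, 12), c(4, 5, 6)), 2)
  set.seed(3)
  poi <- rlnorm(100, log(10), 0.2)
  ref <- rlnorm(100, log(10), 0.2)
  r <- cpmStoichiometry(poi, ref)
  expect_gt(r, 0.9); expect_lt(r, 1.1)
  expect_error(cpmStoichiometry(c(1, 2), c(0, 0)), "zero reference")
})

test_that("bootstrap ratio handles degenerate and analytic cases", {
  b1 <- bootstrapMethodRatio(c(5, 5, 5), c(5, 5, 5), nBoot = 100, seed = 1)
  expect_equal(b1$median, 1)
  expect_equal(b1$interval68, c(1, 1))

  b2 <- bootstrapMethodRatio(rep(8, 4), rep(4, 4), nBoot = 100, seed = 1)
  expect_equal(b2$median, 2)

  set.seed(5)
  a <- rnorm(100, 150, 10); b <- rnorm(100, 100, 10)
  b3 <- bootstrapMethodRatio(a, b, nBoot = 1e5, seed = 2)
  expect_lt(abs(b3$median - 1.5) / 1.5, 0.02)

  ## seeded determinism
  expect_identical(bootstrapMethodRatio(a, b, nBoot = 500, seed = 9),
                   bootstrapMethodRatio(a, b, nBoot = 500, seed = 9))

  ## zero denominators are redrawn, never returned
  bz <- bootstrapMethodRatio(c(1, 2), c(0, 5), nBoot = 200, seed = 3,
                             statistic = "mean")
  expect_true(all(is.finite(c(bz$median, bz$interval68))))
})
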