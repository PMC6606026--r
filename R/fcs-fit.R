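## Fitting and quality control of FCS autocorrelation curves.

.acfFitFailed <- function(nPoints = 0L) {
  new("AcfFit", nParticles = NA_real_, tau1 = NA_real_, tau2 = NA_real_,
      frac1 = NA_real_, structureParam = NA_real_, offset = NA_real_,
      rSquared = NA_real_, chisqPerPoint = NA_real_, cpm = NA_real_,
      converged = FALSE, nPoints = as.integer(nPoints))
}

#' Fit an autocorrelation curve to the two-component diffusion model
#'
#' Bounded Levenberg-Marquardt least squares
#' (\code{\link[minpack.lm]{nlsLM}}) of the two-component 3D diffusion form
#' (see [acfDiffusionModel()]) to an [AcfRecord-class]. The structure
#' parameter kappa is held fixed (from the dye calibration, or the default)
#' unless `freeKappa = TRUE`. `frac1` is constrained to `[0, 1]` and the two
#' diffusion times are relabelled post-fit so that `tau1 <= tau2`, breaking
#' the component-exchange symmetry. An optional triplet (blinking)
#' correction factor `1 + T/(1-T) exp(-tau/tauT)` can be enabled with
#' `triplet = TRUE`; it is off by default.
#'
#' Goodness of fit is reported as R-squared and as chi-squared per point,
#' where the per-point variance is estimated from the fit residuals in the
#' last decade of lags (the flat ACF tail); for a well-described curve the
#' statistic is close to 1.
#'
#' Non-convergence of the full model triggers one fallback fit with a single
#' diffusing component; if that also fails the fit is flagged
#' (`isConverged()` returns `FALSE`) and is later removed by [qcFilter()] --
#' it is never silently returned as a parameter estimate.
#'
#' @param record an [AcfRecord-class] with at least 10 lag points.
#' @param kappa structure parameter to fix (default 5; pass the
#'   calibration's value when available).
#' @param freeKappa fit kappa instead of fixing it.
#' @param triplet include the triplet correction term.
#' @param components 2 (default) or 1 diffusing components.
#' @return an [AcfFit-class].
#' @examples
#' rec <- simulateFcsMeasurement(fcsTruth(nParticles = 10))
#' fitAcf(rec)
#' @export
fitAcf <- function(record, kappa = 5, freeKappa = FALSE, triplet = FALSE,
                   components = 2) {
  stopifnot(is(record, "AcfRecord"))
  lag <- record@lags
  g <- record@acf
  n <- length(lag)
  if (n < 10) stop("need at least 10 lag points")

  offset0 <- mean(g[lag >= max(lag) / 10])
  amp0 <- max(g[1] - offset0, 1e-6)
  half <- g[1] - amp0 / 2
  tauMid <- lag[which.min(abs(g - half))]
  if (tauMid <= min(lag)) tauMid <- exp(mean(log(range(lag))))
  dat <- data.frame(lag = lag, g = g)

  tripletFactor <- function(tau, tf, tauT)
    1 + tf / (1 - tf) * exp(-tau / tauT)

  buildFit <- function(ncomp) {
    start <- list(N = 1 / amp0, offset = offset0)
    lower <- c(N = 1e-8, offset = -Inf)
    upper <- c(N = Inf, offset = Inf)
    if (ncomp == 2) {
      start <- c(start, list(t1 = tauMid / 5, t2 = tauMid * 5, f1 = 0.5))
      lower <- c(lower, t1 = 1e-8, t2 = 1e-8, f1 = 0)
      upper <- c(upper, t1 = 1e8, t2 = 1e8, f1 = 1)
      rhs <- "acfDiffusionModel(lag, N, t1, t2, f1, kap, offset)"
    } else {
      start <- c(start, list(t1 = tauMid))
      lower <- c(lower, t1 = 1e-8)
      upper <- c(upper, t1 = 1e8)
      rhs <- "acfDiffusionModel(lag, N, t1, t1, 1, kap, offset)"
    }
    if (freeKappa) {
      start <- c(start, list(kap = kappa))
      lower <- c(lower, kap = 1 + 1e-6)
      upper <- c(upper, kap = 100)
    }
    if (triplet) {
      start <- c(start, list(tf = 0.1, tauT = min(lag) * 3))
      lower <- c(lower, tf = 0, tauT = 1e-8)
      upper <- c(upper, tf = 0.9, tauT = max(lag))
      rhs <- paste0("(", rhs, " - offset) * tripletFactor(lag, tf, tauT)",
                    " + offset")
    }
    form <- stats::as.formula(paste("g ~", rhs))
    env <- environment(form)
    env$kap <- kappa
    env$acfDiffusionModel <- acfDiffusionModel
    env$tripletFactor <- tripletFactor
    minpack.lm::nlsLM(form, data = dat, start = start, lower = lower,
                      upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }

  fit <- tryCatch(buildFit(components), error = function(e) NULL)
  usedComponents <- components
  if (is.null(fit) && components == 2) {
    fit <- tryCatch(buildFit(1), error = function(e) NULL)
    usedComponents <- 1
  }
  if (is.null(fit)) return(.acfFitFailed(n))

  p <- coef(fit)
  res <- resid(fit)
  rss <- sum(res^2)
  r2 <- 1 - rss / sum((g - mean(g))^2)
  ## chi-squared per point: the flat ACF tail (last decade of lags) anchors
  ## the noise scale; the per-lag variance profile follows photon
  ## statistics, SD proportional to G(tau) + 1/N, so short lags are allowed
  ## proportionally larger residuals.
  gHat <- g - res
  Nhat <- unname(p["N"])
  profile <- gHat - unname(p["offset"]) + 1 / Nhat
  profile <- pmax(profile, 1e-12)
  tailIdx <- lag >= max(lag) / 10
  tailScale2 <- mean((res[tailIdx] / profile[tailIdx])^2)
  chisqN <- if (tailScale2 > 0)
    mean((res / profile)^2) / tailScale2 else NA_real_

  t1 <- unname(p["t1"])
  t2 <- if (usedComponents == 2) unname(p["t2"]) else t1
  f1 <- if (usedComponents == 2) unname(p["f1"]) else 1
  if (t1 > t2) {            # relabel so tau1 is the fast component
    tmp <- t1; t1 <- t2; t2 <- tmp
    f1 <- 1 - f1
  }
  N <- unname(p["N"])
  new("AcfFit", nParticles = N, tau1 = t1, tau2 = t2,
      frac1 = min(max(f1, 0), 1),
      structureParam = if (freeKappa) unname(p["kap"]) else kappa,
      offset = unname(p["offset"]), rSquared = r2, chisqPerPoint = chisqN,
      cpm = if (is.na(record@meanIntensity)) NA_real_
            else record@meanIntensity / N,
      converged = TRUE, nPoints = as.integer(n))
}

#' Calibrate the effective confocal volume from a dye standard
#'
#' Converts the fitted particle number of a dye solution of known
#' concentration into the effective confocal detection volume:
#' `V_eff = N / (C * N_A)` with C in mol/L.
#'
#' @param dyeFit converged [AcfFit-class] of the dye measurement.
#' @param knownConcentration dye concentration in nM (default 50).
#' @return a [ConfocalCalibration-class].
#' @examples
#' fit <- fitAcf(simulateFcsMeasurement(fcsTruth(nParticles = 15)))
#' calibrateConfocalVolume(fit, 50)
#' @export
calibrateConfocalVolume <- function(dyeFit, knownConcentration = 50) {
  stopifnot(is(dyeFit, "AcfFit"))
  if (!dyeFit@converged) stop("dye fit did not converge")
  if (knownConcentration <= 0) stop("concentration must be positive")
  if (!(dyeFit@nParticles > 0)) stop("non-positive particle number")
  new("ConfocalCalibration",
      effectiveVolume = dyeFit@nParticles /
        (knownConcentration * 1e-9 * AVOGADRO),
      structureParam = dyeFit@structureParam,
      dyeConcentration = knownConcentration)
}

#' Concentration from a fitted particle number
#'
#' `C = N / (V_eff * N_A)`, reported in nM.
#'
#' @param fit converged [AcfFit-class].
#' @param calibration a [ConfocalCalibration-class].
#' @return concentration in nM.
#' @examples
#' dye <- fitAcf(simulateFcsMeasurement(fcsTruth(nParticles = 15)))
#' cal <- calibrateConfocalVolume(dye, 50)
#' concentrationFromFit(dye, cal)  # calibration identity: 50 nM
#' @export
concentrationFromFit <- function(fit, calibration) {
  stopifnot(is(fit, "AcfFit"))
  if (missing(calibration) || !is(calibration, "ConfocalCalibration"))
    stop("a ConfocalCalibration is required")
  if (!fit@converged) stop("fit did not converge")
  fit@nParticles / (calibration@effectiveVolume * AVOGADRO) / 1e-9
}

#' Quality-control cascade for ACF fits
#'
#' Applies, in order: (1) removal of non-converged fits; (2) goodness
#' thresholds `R^2 > r2Min` and `chi^2/N < chisqMax`; (3) Tukey's fences of
#' `tukeyK` times the interquartile range of the retained CPMs; (4) removal
#' of fits whose CPM is at or above `cpmCap` times the mean CPM of the free
#' mEGFP reference (aggregates and other bright species). The cap is read as
#' keep CPM < cap x reference; the per-rule rejection counts in the report
#' make the rule auditable.
#'
#' @param fits list of [AcfFit-class].
#' @param megfpMeanCpm mean CPM (kHz) of the free-mEGFP reference (> 0).
#' @param r2Min,chisqMax,tukeyK,cpmCap thresholds; defaults 0.92, 1.2, 3, 10.
#' @return list with `retained` (list of fits) and `report` (named list of
#'   per-rule rejection counts and the retained fraction).
#' @examples
#' tr <- fcsTruth(nParticles = 10, noiseSdScale = 0.03)
#' fits <- lapply(1:20, function(i)
#'   fitAcf(simulateFcsMeasurement(fcsTruth(nParticles = 10,
#'          noiseSdScale = 0.03, seed = i))))
#' qcFilter(fits, megfpMeanCpm = 10)$report
#' @export
qcFilter <- function(fits, megfpMeanCpm, r2Min = 0.92, chisqMax = 1.2,
                     tukeyK = 3, cpmCap = 10) {
  if (megfpMeanCpm <= 0) stop("megfpMeanCpm must be positive")
  report <- list(nInput = length(fits), nNotConverged = 0L,
                 nFailedGoodness = 0L, nCpmOutlier = 0L, nCpmCap = 0L,
                 nRetained = 0L, retainedFraction = NA_real_)
  if (!length(fits)) return(list(retained = list(), report = report))
  conv <- vapply(fits, function(f) isTRUE(f@converged), logical(1))
  report$nNotConverged <- sum(!conv)
  fits <- fits[conv]

  good <- vapply(fits, function(f)
    !is.na(f@rSquared) && f@rSquared > r2Min &&
    !is.na(f@chisqPerPoint) && f@chisqPerPoint < chisqMax, logical(1))
  report$nFailedGoodness <- sum(!good)
  fits <- fits[good]

  cpms <- vapply(fits, cpm, numeric(1))
  if (length(cpms)) {
    q <- quantile(cpms, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- q[2] - q[1]
    inFence <- !is.na(cpms) & cpms >= q[1] - tukeyK * iqr &
      cpms <= q[2] + tukeyK * iqr
    report$nCpmOutlier <- sum(!inFence)
    fits <- fits[inFence]
    cpms <- cpms[inFence]
    underCap <- cpms < cpmCap * megfpMeanCpm
    report$nCpmCap <- sum(!underCap)
    fits <- fits[underCap]
  }
  report$nRetained <- length(fits)
  report$retainedFraction <- length(fits) / report$nInput
  list(retained = fits, report = report)
}
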