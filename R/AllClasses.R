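#' @import methods
#' @importFrom stats median quantile var sd qt setNames rnorm rlnorm rexp
#'   runif coef resid as.formula approx
#' @importFrom utils head tail
NULL

## Avogadro's constant (mol^-1), 2019 SI exact value. Used for every
## concentration <-> copy-number conversion in the package.
AVOGADRO <- 6.02214076e23

#' AcfRecord: one FCS measurement's autocorrelation curve
#'
#' Container for a single fluorescence correlation spectroscopy (FCS)
#' measurement: the autocorrelation function G(tau) evaluated on a lag grid,
#' together with the mean photon count rate and acquisition metadata.
#'
#' @slot cellId character scalar, identifier of the measured cell.
#' @slot compartment one of `"nucleus_chromatin"` or `"cytoplasm"`.
#' @slot condition cell-cycle stage, one of `"G1"`, `"G2"`, `"prometaphase"`.
#' @slot lags numeric, strictly increasing positive lag times (ms).
#' @slot acf numeric, autocorrelation amplitudes G(tau) (dimensionless).
#' @slot meanIntensity mean photon count rate (kHz).
#' @slot duration acquisition time (s).
#'
#' @seealso [simulateFcsMeasurement()], [correlateTrace()], [fitAcf()]
#' @export
setClass("AcfRecord",
  representation(
    cellId = "character",
    compartment = "character",
    condition = "character",
    lags = "numeric",
    acf = "numeric",
    meanIntensity = "numeric",
    duration = "numeric"
  ),
  prototype(
    cellId = "cell_1",
    compartment = "nucleus_chromatin",
    condition = "G1",
    meanIntensity = NA_real_,
    duration = 30
  )
)

setValidity("AcfRecord", function(object) {
  msg <- character()
  if (length(object@lags) != length(object@acf))
    msg <- c(msg, "lags and acf must have equal length")
  if (length(object@lags) && any(object@lags <= 0))
    msg <- c(msg, "lags must be positive")
  if (length(object@lags) > 1 && any(diff(object@lags) <= 0))
    msg <- c(msg, "lags must be strictly increasing")
  if (!is.na(object@duration) && object@duration <= 0)
    msg <- c(msg, "duration must be positive")
  if (!object@compartment %in% c("nucleus_chromatin", "cytoplasm"))
    msg <- c(msg, "compartment must be 'nucleus_chromatin' or 'cytoplasm'")
  if (!object@condition %in% c("G1", "G2", "prometaphase"))
    msg <- c(msg, "condition must be 'G1', 'G2' or 'prometaphase'")
  if (length(msg)) msg else TRUE
})

#' AcfFit: fitted two-component diffusion model parameters
#'
#' Result of fitting an [AcfRecord-class] to the two-component 3D diffusion
#' model
#' \deqn{G(\tau) = o + \frac{1}{N}\sum_{i=1,2} f_i
#'   \left(1+\tau/\tau_i\right)^{-1}
#'   \left(1+\tau/(\kappa^2\tau_i)\right)^{-1/2}}
#' with particle number N, diffusion times tau_i, fast fraction f_1
#' (f_2 = 1 - f_1), structure parameter kappa and baseline offset o.
#'
#' @slot nParticles fitted particle number N in the focal volume.
#' @slot tau1,tau2 diffusion times (ms), relabelled post-fit so tau1 <= tau2.
#' @slot frac1 fraction of the fast component, in `[0, 1]`.
#' @slot structureParam axial/lateral focal volume ratio kappa.
#' @slot offset baseline of the ACF.
#' @slot rSquared coefficient of determination of the fit.
#' @slot chisqPerPoint residual chi-squared divided by the number of lag
#'   points, with the per-point variance estimated from the last decade of
#'   lags (see [fitAcf()]).
#' @slot cpm counts per molecule (kHz), `meanIntensity / N`; `NA` when the
#'   record carries no intensity.
#' @slot converged logical; failed fits are flagged, never silently returned.
#' @slot nPoints number of lag points used.
#'
#' @seealso [fitAcf()], [qcFilter()], [concentrationFromFit()]
#' @export
setClass("AcfFit",
  representation(
    nParticles = "numeric",
    tau1 = "numeric",
    tau2 = "numeric",
    frac1 = "numeric",
    structureParam = "numeric",
    offset = "numeric",
    rSquared = "numeric",
    chisqPerPoint = "numeric",
    cpm = "numeric",
    converged = "logical",
    nPoints = "integer"
  ),
  prototype(converged = TRUE, cpm = NA_real_, nPoints = 0L)
)

setValidity("AcfFit", function(object) {
  msg <- character()
  if (isTRUE(object@converged)) {
    if (!is.na(object@nParticles) && object@nParticles <= 0)
      msg <- c(msg, "nParticles must be positive")
    if (!is.na(object@frac1) && (object@frac1 < 0 || object@frac1 > 1))
      msg <- c(msg, "frac1 must lie in [0, 1]")
    if (!is.na(object@rSquared) && object@rSquared > 1 + 1e-12)
      msg <- c(msg, "rSquared cannot exceed 1")
  }
  if (length(msg)) msg else TRUE
})

#' ConfocalCalibration: effective confocal volume from a dye standard
#'
#' Calibration of the effective confocal detection volume from an FCS
#' measurement of a fluorescent dye solution of known concentration
#' (50 nM by convention): `effectiveVolume = N / (C * N_A)`.
#'
#' @slot effectiveVolume effective confocal volume (litres).
#' @slot structureParam structure parameter kappa of the calibration fit.
#' @slot dyeConcentration dye concentration used (nM).
#'
#' @seealso [calibrateConfocalVolume()]
#' @export
setClass("ConfocalCalibration",
  representation(
    effectiveVolume = "numeric",
    structureParam = "numeric",
    dyeConcentration = "numeric"
  )
)

setValidity("ConfocalCalibration", function(object) {
  if (object@effectiveVolume <= 0) "effectiveVolume must be positive" else TRUE
})

#' FrapCurve: one cell's inverse-FRAP intensity time series
#'
#' Background-subtracted mean fluorescence in the bleached and unbleached
#' halves of one nucleus, sampled from the first post-bleach frame onward,
#' plus the pre-bleach mean used for normalisation.
#'
#' @slot cellId character scalar.
#' @slot condition `"G1"` or `"G2"`.
#' @slot times minutes from the first post-bleach frame (first element 0).
#' @slot bleached,unbleached background-subtracted intensities per frame.
#' @slot prebleachMean mean pre-bleach intensity (> 0).
#' @slot prebleachUnbleached,postbleachUnbleached unbleached-region intensity
#'   immediately before and after the bleach, used to estimate the soluble
#'   fraction; may be `NA` when not recorded.
#'
#' @seealso [normalizeIfrap()], [simulateFrapExperiment()]
#' @export
setClass("FrapCurve",
  representation(
    cellId = "character",
    condition = "character",
    times = "numeric",
    bleached = "numeric",
    unbleached = "numeric",
    prebleachMean = "numeric",
    prebleachUnbleached = "numeric",
    postbleachUnbleached = "numeric"
  ),
  prototype(prebleachUnbleached = NA_real_, postbleachUnbleached = NA_real_)
)

setValidity("FrapCurve", function(object) {
  msg <- character()
  n <- length(object@times)
  if (length(object@bleached) != n || length(object@unbleached) != n)
    msg <- c(msg, "times, bleached and unbleached must have equal length")
  if (n && object@times[1] < 0)
    msg <- c(msg, "times must be non-negative")
  if (n > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (is.na(object@prebleachMean) || object@prebleachMean <= 0)
    msg <- c(msg, "prebleachMean must be positive")
  if (!object@condition %in% c("G1", "G2"))
    msg <- c(msg, "condition must be 'G1' or 'G2'")
  if (length(msg)) msg else TRUE
})

#' FrapFit: exponential fit of a normalized iFRAP difference curve
#'
#' Single-exponential `exp(-kOff1 t)` or double-exponential
#' `a exp(-kOff1 t) + (1-a) exp(-kOff2 t)` fit of the normalized
#' bleached/unbleached difference signal. For double fits the slow residence
#' time `1/kOff2` is constrained to the interval `[1.5, 15]` hours.
#'
#' @slot model `"single"` or `"double"`.
#' @slot kOff1 fast dissociation rate constant (1/min).
#' @slot kOff2 slow dissociation rate constant (1/min); `NA` for single fits.
#' @slot a fast-component amplitude in `[0, 1]`; `NA` for single fits.
#' @slot residenceDynamic `1/kOff1` (min).
#' @slot residenceStable `1/kOff2` expressed in hours; `NA` for single fits.
#' @slot rss residual sum of squares.
#' @slot aicc small-sample-corrected Akaike information criterion.
#' @slot nPoints number of time points fitted.
#' @slot converged logical.
#' @slot boundary logical; `TRUE` when the slow residence time is pinned at a
#'   constraint boundary (the estimate is then a censored value).
#'
#' @seealso [fitSingleExponential()], [fitDoubleExponential()],
#'   [selectModel()]
#' @export
setClass("FrapFit",
  representation(
    model = "character",
    kOff1 = "numeric",
    kOff2 = "numeric",
    a = "numeric",
    residenceDynamic = "numeric",
    residenceStable = "numeric",
    rss = "numeric",
    aicc = "numeric",
    nPoints = "integer",
    converged = "logical",
    boundary = "logical"
  ),
  prototype(kOff2 = NA_real_, a = NA_real_, residenceStable = NA_real_,
            converged = TRUE, boundary = FALSE)
)

setValidity("FrapFit", function(object) {
  msg <- character()
  if (!object@model %in% c("single", "double"))
    msg <- c(msg, "model must be 'single' or 'double'")
  if (isTRUE(object@converged)) {
    if (!is.na(object@kOff1) && object@kOff1 < 0)
      msg <- c(msg, "kOff1 must be non-negative")
    if (object@model == "double") {
      if (is.na(object@kOff2) || is.na(object@a))
        msg <- c(msg, "double fits must carry kOff2 and a")
      else {
        if (object@kOff1 < object@kOff2)
          msg <- c(msg, "kOff1 must exceed kOff2 (fast vs slow)")
        if (object@a < 0 || object@a > 1)
          msg <- c(msg, "a must lie in [0, 1]")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' PopulationFractions: soluble / dynamic / stable partition of nuclear pool
#'
#' The three-way partition of the nuclear pool of a chromatin-binding protein
#' into soluble (unbound), dynamically chromatin-bound and stably
#' chromatin-bound fractions, summing to one.
#'
#' @slot soluble,dynamic,stable fractions in `[0, 1]` summing to 1.
#' @slot solubleSd,dynamicSd,stableSd across-cell standard deviations
#'   (`NA` when unknown).
#'
#' @seealso [partitionPopulations()], [copyNumberPartition()]
#' @export
setClass("PopulationFractions",
  representation(
    soluble = "numeric",
    dynamic = "numeric",
    stable = "numeric",
    solubleSd = "numeric",
    dynamicSd = "numeric",
    stableSd = "numeric"
  ),
  prototype(solubleSd = NA_real_, dynamicSd = NA_real_, stableSd = NA_real_)
)

setValidity("PopulationFractions", function(object) {
  msg <- character()
  f <- c(object@soluble, object@dynamic, object@stable)
  if (any(f < -1e-9) || any(f > 1 + 1e-9))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-9)
    msg <- c(msg, "soluble + dynamic + stable must equal 1")
  if (length(msg)) msg else TRUE
})

#' EquilibriumParams: on/off rate parameters of the chromatin-binding model
#'
#' First-order rate constants of the equilibrium between unbound and
#' dynamically chromatin-bound cohesin. The bound fraction is affine in the
#' stable fraction s:
#' \deqn{b_T = \frac{k_{on}}{k_{on}+k_{off}} + \frac{k_{off}}{k_{on}+k_{off}} s}
#' Only the ratio of the rates is identified from fractions; absolute rates
#' are carried when anchored by a supplied `kOff` (e.g. 1/residence time).
#'
#' @slot intercept `kOn / (kOn + kOff)`, the bound fraction at s = 0.
#' @slot slope `kOff / (kOn + kOff)`; `intercept + slope = 1`.
#' @slot kOn,kOff absolute rate constants (1/min), `NA` when only the ratio
#'   is identified.
#'
#' @seealso [calibrateFromG1()], [boundFraction()], [partitionEquilibrium()]
#' @export
setClass("EquilibriumParams",
  representation(
    intercept = "numeric",
    slope = "numeric",
    kOn = "numeric",
    kOff = "numeric"
  ),
  prototype(kOn = NA_real_, kOff = NA_real_)
)

setValidity("EquilibriumParams", function(object) {
  msg <- character()
  if (object@intercept <= 0 || object@intercept >= 1)
    msg <- c(msg, "intercept must lie strictly between 0 and 1")
  if (abs(object@intercept + object@slope - 1) > 1e-12)
    msg <- c(msg, "intercept + slope must equal 1")
  if (!is.na(object@kOn) && object@kOn <= 0)
    msg <- c(msg, "kOn must be positive")
  if (!is.na(object@kOff) && object@kOff <= 0)
    msg <- c(msg, "kOff must be positive")
  if (length(msg)) msg else TRUE
})

#' EquilibriumState: U/D/S partition of total nuclear cohesin
#'
#' Copy numbers of unbound (U), dynamically bound (D) and stably bound (S)
#' nuclear cohesin under the equilibrium binding model, with
#' `U + D + S = C_T` and bound fraction `b_T = (D + S) / C_T`.
#'
#' @slot cT total nuclear copies.
#' @slot U,D,S copy numbers of the three forms.
#' @slot u,d,s,bT the corresponding fractions.
#'
#' @seealso [partitionEquilibrium()]
#' @export
setClass("EquilibriumState",
  representation(
    cT = "numeric",
    U = "numeric", D = "numeric", S = "numeric",
    u = "numeric", d = "numeric", s = "numeric",
    bT = "numeric"
  )
)

setValidity("EquilibriumState", function(object) {
  msg <- character()
  if (abs(object@U + object@D + object@S - object@cT) >
        1e-9 * max(1, object@cT))
    msg <- c(msg, "U + D + S must equal cT")
  fr <- c(object@u, object@d, object@s, object@bT)
  if (any(fr < -1e-12) || any(fr > 1 + 1e-12))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
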