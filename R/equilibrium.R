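## Equilibrium model of cohesin-chromatin binding.
##
## Total nuclear cohesin C_T = U + D + S partitions into unbound (U),
## dynamically bound (D) and stably bound (S) forms. At steady state
## kOn * U = kOff * D, which makes the chromatin-bound fraction affine in
## the stable fraction s:
##   bT = kOn/(kOn+kOff) + kOff/(kOn+kOff) * s,   slope + intercept = 1.

#' Calibrate the equilibrium model from the G1 bound fraction
#'
#' Cells without stable cohesin (s = 0) pin the intercept:
#' `intercept = bT(G1)`, `slope = 1 - intercept`, and
#' `kOn/kOff = bT / (1 - bT)`. The rates are identified only up to scale;
#' supplying `kOff` (e.g. 1/residence time from FRAP) anchors both.
#'
#' @param bTg1 chromatin-bound fraction in G1, strictly between 0 and 1.
#' @param kOff optional absolute dissociation rate (1/min).
#' @return an [EquilibriumParams-class].
#' @examples
#' calibrateFromG1(0.635)
#' calibrateFromG1(0.635, kOff = 1 / 13.7)
#' @export
calibrateFromG1 <- function(bTg1, kOff = NA_real_) {
  if (!is.finite(bTg1) || bTg1 <= 0 || bTg1 >= 1)
    stop("bTg1 must lie strictly between 0 and 1 (degenerate kinetics)")
  kOn <- if (is.na(kOff)) NA_real_ else kOff * bTg1 / (1 - bTg1)
  new("EquilibriumParams", intercept = bTg1, slope = 1 - bTg1,
      kOn = kOn, kOff = kOff)
}

#' Chromatin-bound fraction as a function of the stable fraction
#'
#' `bT(s) = intercept + slope * s`, affine in s; stabilisation of a fraction
#' of the bound pool increases the total bound fraction. At s = 1 the whole
#' pool is bound (`bT = 1`).
#'
#' @param s stable fraction(s) in `[0, 1]`.
#' @param params an [EquilibriumParams-class].
#' @return bound fraction(s).
#' @examples
#' boundFraction(0.367, calibrateFromG1(0.635))  # 0.769
#' @export
boundFraction <- function(s, params) {
  stopifnot(is(params, "EquilibriumParams"))
  if (any(s < 0 | s > 1)) stop("s must lie in [0, 1]")
  params@intercept + params@slope * s
}

#' Partition total nuclear cohesin into U, D and S copy numbers
#'
#' Given total copies `cT` and stable fraction `s`, computes
#' `bT = intercept + slope * s`, then `S = s cT`, `D = (bT - s) cT`,
#' `U = (1 - bT) cT`. Conservation `U + D + S = cT` holds exactly, and when
#' absolute rates are carried the steady-state balance `kOn U = kOff D`
#' holds to machine precision.
#'
#' @param cT total nuclear copies (>= 0).
#' @param s stable fraction in `[0, 1]`.
#' @param params an [EquilibriumParams-class].
#' @return an [EquilibriumState-class].
#' @examples
#' partitionEquilibrium(250755, 0, calibrateFromG1(0.635))
#' @export
partitionEquilibrium <- function(cT, s, params) {
  stopifnot(is(params, "EquilibriumParams"))
  if (cT < 0) stop("cT must be non-negative")
  if (s < 0 || s > 1) stop("s must lie in [0, 1]")
  bT <- boundFraction(s, params)
  if (s > bT + 1e-12)
    stop("s exceeds the bound fraction: impossible under the model ",
         "(the stable pool is part of the bound pool)")
  d <- bT - s
  u <- 1 - bT
  new("EquilibriumState", cT = cT, U = u * cT, D = d * cT, S = s * cT,
      u = u, d = d, s = s, bT = bT)
}

#' Compare a predicted bound fraction with an observed one
#'
#' @param observed,predicted bound fractions in `[0, 1]`.
#' @return list with `observed`, `predicted`, `absoluteDifference`,
#'   `relativeDifference` (relative to the observed value).
#' @examples
#' comparePrediction(0.728, 0.769)  # absolute difference 0.041
#' @export
comparePrediction <- function(observed, predicted) {
  stopifnot(observed >= 0, observed <= 1, predicted >= 0, predicted <= 1)
  list(observed = observed, predicted = predicted,
       absoluteDifference = abs(predicted - observed),
       relativeDifference = abs(predicted - observed) / observed)
}
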