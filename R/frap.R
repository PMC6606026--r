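## Normalisation and exponential fitting of inverse-FRAP curves, and the
## soluble/dynamic/stable partition of the nuclear pool.

## slow-residence constraint for the double-exponential fit (hours)
.SLOW_RESIDENCE_HR <- c(1.5, 15)

#' Normalize an inverse-FRAP curve
#'
#' Forms the bleached/unbleached difference signal, normalises it to the
#' mean pre-bleach intensity and anchors it to 1 at the first post-bleach
#' frame: `d(t) = (unbleached - bleached) / prebleachMean`, rescaled so
#' `d(t0) = 1`. The signal decays toward 0 as the two halves of the nucleus
#' re-equilibrate.
#'
#' @param curve a [FrapCurve-class] with at least 3 post-bleach frames.
#' @return data.frame with columns `time` (min) and `signal`.
#' @examples
#' cur <- simulateFrapExperiment(frapTruth(nCells = 1, noiseSd = 0))[[1]]
#' head(normalizeIfrap(cur))
#' @export
normalizeIfrap <- function(curve) {
  stopifnot(is(curve, "FrapCurve"))
  if (length(curve@times) < 3) stop("need at least 3 post-bleach frames")
  d <- (curve@unbleached - curve@bleached) / curve@prebleachMean
  if (d[1] == 0) stop("zero difference at first post-bleach frame")
  data.frame(time = curve@times, signal = d / d[1])
}

.frapAicc <- function(rss, n, nPar) {
  k <- nPar + 1                       # + residual variance
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a single-exponential dissociation model
#'
#' Least-squares fit of `f(t) = exp(-kOff1 t)` to a normalized iFRAP
#' difference signal. The dynamic residence time is `1/kOff1`. A rate pinned
#' at the lower bound (no measurable decay) is returned with a warning.
#'
#' @param normalized data.frame from [normalizeIfrap()] (columns `time`,
#'   `signal`).
#' @return a [FrapFit-class] with `model = "single"`.
#' @examples
#' d <- data.frame(time = 0:40, signal = exp(-(0:40) / 13.7))
#' fitSingleExponential(d)
#' @export
fitSingleExponential <- function(normalized) {
  t <- normalized$time
  y <- normalized$signal
  n <- length(t)
  kMin <- 1e-6
  halfIdx <- which(y <= 0.5)[1]
  k0 <- if (!is.na(halfIdx) && t[halfIdx] > 0) log(2) / t[halfIdx] else
    max(kMin * 10, 1 / max(t))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ exp(-k * t), start = list(k = k0),
                      lower = c(k = kMin), upper = c(k = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(new("FrapFit", model = "single", kOff1 = NA_real_,
               residenceDynamic = NA_real_, rss = NA_real_, aicc = NA_real_,
               nPoints = as.integer(n), converged = FALSE))
  k <- unname(coef(fit)["k"])
  if (k <= kMin * (1 + 1e-8))
    warning("dissociation rate at lower bound: no measurable decay")
  rss <- sum(resid(fit)^2)
  new("FrapFit", model = "single", kOff1 = k, residenceDynamic = 1 / k,
      rss = rss, aicc = .frapAicc(rss, n, 1), nPoints = as.integer(n),
      converged = TRUE)
}

#' Fit a constrained double-exponential dissociation model
#'
#' Least-squares fit of `f(t) = a exp(-kOff1 t) + (1-a) exp(-kOff2 t)` with
#' `a` constrained to `[0, 1]` and the slow residence time `1/kOff2`
#' constrained by hard box bounds to `[1.5, 15]` hours. Components are
#' relabelled post-fit so `kOff1 > kOff2` (fast vs slow). A slow component
#' pinned at a constraint boundary is flagged in the fit (`@boundary`); the
#' estimate is then a censored value, not a free optimum.
#'
#' @param normalized data.frame from [normalizeIfrap()].
#' @param fixA optional value in `[0, 1]` at which to fix the fast-component
#'   amplitude (used for nested-model checks).
#' @return a [FrapFit-class] with `model = "double"`.
#' @examples
#' t <- 0:40
#' d <- data.frame(time = t,
#'                 signal = 0.5 * exp(-t / 10) + 0.5 * exp(-t / 516))
#' fitDoubleExponential(d)
#' @export
fitDoubleExponential <- function(normalized, fixA = NULL) {
  t <- normalized$time
  y <- normalized$signal
  n <- length(t)
  k2Box <- rev(1 / (.SLOW_RESIDENCE_HR * 60))   # 1/min, [1/900, 1/90]
  k2Start <- exp(mean(log(k2Box)))
  failed <- function() new("FrapFit", model = "double", kOff1 = NA_real_,
                           kOff2 = NA_real_, a = NA_real_,
                           residenceDynamic = NA_real_,
                           residenceStable = NA_real_, rss = NA_real_,
                           aicc = NA_real_, nPoints = as.integer(n),
                           converged = FALSE)
  ## nls.lm (rather than the nls wrapper) so that a degenerate second
  ## component (a pinned at 0 or 1) still returns the parameter vector
  ## instead of failing on a singular gradient at the solution
  if (is.null(fixA)) {
    residFun <- function(p)
      y - (p[1] * exp(-p[2] * t) + (1 - p[1]) * exp(-p[3] * t))
    out <- tryCatch(
      minpack.lm::nls.lm(par = c(0.5, 0.1, k2Start), fn = residFun,
                         lower = c(0, 1e-6, k2Box[1]),
                         upper = c(1, 1e6, k2Box[2]),
                         control = minpack.lm::nls.lm.control(maxiter =
                                                                400)),
      error = function(e) NULL)
    if (is.null(out) || out$info == 0 || out$info == 9) return(failed())
    a <- out$par[1]; k1 <- out$par[2]; k2 <- out$par[3]
    nPar <- 3
  } else {
    stopifnot(fixA >= 0, fixA <= 1)
    a <- fixA
    residFun <- function(p)
      y - (a * exp(-p[1] * t) + (1 - a) * exp(-p[2] * t))
    out <- tryCatch(
      minpack.lm::nls.lm(par = c(0.1, k2Start), fn = residFun,
                         lower = c(1e-6, k2Box[1]),
                         upper = c(1e6, k2Box[2]),
                         control = minpack.lm::nls.lm.control(maxiter =
                                                                400)),
      error = function(e) NULL)
    if (is.null(out) || out$info == 0 || out$info == 9) return(failed())
    k1 <- out$par[1]; k2 <- out$par[2]
    nPar <- 2
  }
  if (k1 < k2) {                       # relabel: kOff1 is the fast rate
    tmp <- k1; k1 <- k2; k2 <- tmp
    a <- 1 - a
  }
  rss <- out$deviance
  relTol <- 1e-6
  boundary <- k2 <= k2Box[1] * (1 + relTol) || k2 >= k2Box[2] * (1 - relTol)
  new("FrapFit", model = "double", kOff1 = k1, kOff2 = k2,
      a = min(max(a, 0), 1), residenceDynamic = 1 / k1,
      residenceStable = 1 / k2 / 60, rss = rss,
      aicc = .frapAicc(rss, n, nPar), nPoints = as.integer(n),
      converged = TRUE, boundary = boundary)
}

#' Choose between the single- and double-exponential fits
#'
#' Selects by the small-sample-corrected Akaike information criterion
#' (AICc); ties go to the single-exponential model (parsimony). Both fits
#' and both scores are retained in the attributes of the returned fit.
#'
#' @param single,double the two [FrapFit-class] candidates.
#' @return the chosen [FrapFit-class]; its `"aiccSingle"`/`"aiccDouble"`
#'   attributes carry both scores.
#' @examples
#' t <- 0:40
#' d <- data.frame(time = t, signal = exp(-t / 13.7))
#' selectModel(fitSingleExponential(d), fitDoubleExponential(d))
#' @export
selectModel <- function(single, double) {
  stopifnot(is(single, "FrapFit"), is(double, "FrapFit"),
            single@model == "single", double@model == "double")
  if (!single@converged && !double@converged)
    stop("both exponential fits failed")
  chosen <- if (!double@converged) single
    else if (!single@converged) double
    else if (double@aicc < single@aicc) double
    else single                         # tie -> parsimony
  attr(chosen, "aiccSingle") <- single@aicc
  attr(chosen, "aiccDouble") <- double@aicc
  chosen
}

#' Soluble fraction from the unbleached-region signal drop
#'
#' Highly mobile (soluble) molecules diffuse into the bleached region during
#' the bleach, so the fractional drop of the unbleached-region signal,
#' scaled by the bleached volume fraction, estimates the soluble fraction:
#' `soluble = ((pre - post)/pre) / bleachedVolumeFraction`, clipped to
#' `[0, 1]` with a warning if clipping occurs.
#'
#' @param prebleachUnbleached,postbleachUnbleached unbleached-region
#'   intensities immediately before and after the bleach.
#' @param bleachedVolumeFraction fraction of the compartment bleached, in
#'   (0, 1); default 0.5 (half the nucleus).
#' @return soluble fraction in `[0, 1]`.
#' @examples
#' solubleFraction(100, 86.5, 0.5)  # 0.27
#' @export
solubleFraction <- function(prebleachUnbleached, postbleachUnbleached,
                            bleachedVolumeFraction = 0.5) {
  if (prebleachUnbleached <= 0) stop("pre-bleach intensity must be positive")
  if (bleachedVolumeFraction <= 0 || bleachedVolumeFraction >= 1)
    stop("bleachedVolumeFraction must lie in (0, 1)")
  drop <- (prebleachUnbleached - postbleachUnbleached) / prebleachUnbleached
  if (drop < 0) {
    warning("post-bleach signal exceeds pre-bleach; returning 0")
    return(0)
  }
  s <- drop / bleachedVolumeFraction
  if (s > 1) {
    warning("soluble fraction clipped to 1")
    s <- 1
  }
  s
}

#' Partition the nuclear pool into soluble, dynamic and stable fractions
#'
#' The chromatin-bound fraction is `1 - soluble`; the fitted fast-component
#' amplitude `a` splits it into dynamic (`(1-soluble) a`) and stable
#' (`(1-soluble)(1-a)`; 0 for single-exponential fits). The three fractions
#' sum to one by construction.
#'
#' @param soluble soluble fraction in `[0, 1]`.
#' @param fit the selected [FrapFit-class].
#' @return a [PopulationFractions-class].
#' @examples
#' d <- data.frame(time = 0:40, signal = exp(-(0:40) / 13.7))
#' partitionPopulations(0.365, fitSingleExponential(d))
#' @export
partitionPopulations <- function(soluble, fit) {
  stopifnot(is(fit, "FrapFit"), soluble >= 0, soluble <= 1)
  if (!fit@converged) stop("cannot partition from a failed fit")
  bound <- 1 - soluble
  a <- if (fit@model == "single") 1 else fit@a
  new("PopulationFractions", soluble = soluble, dynamic = bound * a,
      stable = bound * (1 - a))
}

#' Construct population fractions directly
#'
#' For use when the fractions (and their across-cell standard deviations)
#' are known rather than derived from a single fit, e.g. when averaging over
#' cells or reproducing tabulated values.
#'
#' @param soluble,dynamic,stable fractions summing to 1.
#' @param solubleSd,dynamicSd,stableSd optional standard deviations.
#' @return a [PopulationFractions-class].
#' @examples
#' populationFractions(0.27, 0.36, 0.37)
#' @export
populationFractions <- function(soluble, dynamic, stable,
                                solubleSd = NA_real_, dynamicSd = NA_real_,
                                stableSd = NA_real_) {
  new("PopulationFractions", soluble = soluble, dynamic = dynamic,
      stable = stable, solubleSd = solubleSd, dynamicSd = dynamicSd,
      stableSd = stableSd)
}

#' Average per-cell population fractions
#'
#' Mean and standard deviation of each fraction across cells, matching
#' mean +- SD reporting.
#'
#' @param fractionsList list of [PopulationFractions-class], one per cell.
#' @return a [PopulationFractions-class] whose `*Sd` slots carry the
#'   across-cell SDs.
#' @export
averagePopulationFractions <- function(fractionsList) {
  stopifnot(length(fractionsList) >= 1)
  m <- vapply(fractionsList, function(f)
    c(f@soluble, f@dynamic, f@stable), numeric(3))
  mu <- rowMeans(m)
  mu <- mu / sum(mu)                   # guard rounding drift
  sds <- apply(m, 1, sd)
  new("PopulationFractions", soluble = mu[1], dynamic = mu[2],
      stable = mu[3], solubleSd = sds[1], dynamicSd = sds[2],
      stableSd = sds[3])
}

#' Copy numbers per population from the nuclear median and fractions
#'
#' Multiplies the median nuclear copy number by the soluble/dynamic/stable
#' fractions; the three populations sum exactly to the nuclear total. When
#' the fractions carry SDs, the copy-number SDs are `copies * fractionSd`.
#'
#' @param nuclearCopies median nuclear copy number (> 0).
#' @param fractions a [PopulationFractions-class].
#' @return data.frame with columns `population`, `copies`, `sd` (rows
#'   soluble, dynamic, stable, total).
#' @examples
#' copyNumberPartition(250755, populationFractions(0.365, 0.635, 0))
#' @export
copyNumberPartition <- function(nuclearCopies, fractions) {
  stopifnot(is(fractions, "PopulationFractions"), nuclearCopies > 0)
  f <- c(soluble = fractions@soluble, dynamic = fractions@dynamic,
         stable = fractions@stable)
  sds <- c(fractions@solubleSd, fractions@dynamicSd, fractions@stableSd)
  copies <- nuclearCopies * f
  data.frame(
    population = c(names(f), "total"),
    copies = c(copies, sum(copies)),
    sd = c(nuclearCopies * sds, NA_real_),
    stringsAsFactors = FALSE)
}
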