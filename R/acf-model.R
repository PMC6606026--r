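#' Two-component 3D diffusion autocorrelation model
#'
#' Closed form of the FCS autocorrelation function for two species diffusing
#' through a 3D Gaussian focal volume:
#' \deqn{G(\tau) = o + \frac{1}{N}\sum_{i=1,2} f_i
#'   \left(1+\frac{\tau}{\tau_i}\right)^{-1}
#'   \left(1+\frac{\tau}{\kappa^2\tau_i}\right)^{-1/2}}
#' with `f1 = frac1`, `f2 = 1 - frac1`. No triplet/blinking term is included
#' (see the methods vignette).
#'
#' @param tau lag times (ms), positive.
#' @param nParticles mean particle number N in the focal volume (> 0).
#' @param tau1,tau2 diffusion times of the two components (ms).
#' @param frac1 fraction of component 1, in `[0, 1]`.
#' @param kappa structure parameter (axial/lateral focal ratio, > 1).
#' @param offset additive baseline.
#' @return numeric vector of G(tau) values.
#' @examples
#' acfDiffusionModel(0.5, nParticles = 5, tau1 = 0.5, tau2 = 50,
#'                   frac1 = 0.6, kappa = 5)
#' @export
acfDiffusionModel <- function(tau, nParticles, tau1, tau2 = tau1, frac1 = 1,
                              kappa = 5, offset = 0) {
  stopifnot(nParticles > 0, tau1 > 0, tau2 > 0, frac1 >= 0, frac1 <= 1,
            kappa > 1)
  if (any(tau <= 0)) stop("lag times must be positive")
  comp <- function(td) (1 + tau / td)^-1 * (1 + tau / (kappa^2 * td))^-0.5
  offset + (frac1 * comp(tau1) + (1 - frac1) * comp(tau2)) / nParticles
}

#' Quasi-logarithmic (multiple-tau) lag grid
#'
#' Builds the lag ladder of a multiple-tau correlator: `m` linearly spaced
#' lags at the base resolution, then repeated doubling of the lag spacing,
#' matching the output of hardware/software correlators.
#'
#' @param minLag smallest lag (ms).
#' @param maxLag largest lag (ms).
#' @param pointsPerOctave lags per doubling (default 8).
#' @return strictly increasing numeric vector of lags in ms.
#' @examples
#' multipleTauGrid(1e-3, 1e3)
#' @export
multipleTauGrid <- function(minLag = 1e-3, maxLag = 1e3,
                            pointsPerOctave = 8) {
  stopifnot(minLag > 0, maxLag > minLag, pointsPerOctave >= 2)
  lags <- minLag * seq_len(2 * pointsPerOctave)
  step <- minLag
  while (max(lags) < maxLag) {
    step <- step * 2
    lags <- c(lags, max(lags) + step * seq_len(pointsPerOctave))
  }
  lags[lags <= maxLag]
}

#' Autocorrelate a binned photon-count trace
#'
#' Computes the normalized intensity autocorrelation
#' `G(tau) = <dI(t) dI(t+tau)> / <I>^2` of a binned photon-count trace on a
#' multiple-tau lag ladder, returning an [AcfRecord-class].
#'
#' @param binnedIntensity counts per bin (numeric vector, >= 2 bins).
#' @param binWidth bin width (ms).
#' @param maxLag largest lag to evaluate (ms); default a quarter of the
#'   trace length, beyond which the estimator becomes noise-dominated.
#' @param cellId,compartment,condition metadata copied into the record.
#' @return an [AcfRecord-class]; `meanIntensity` is the mean count rate in
#'   kHz implied by `binWidth`.
#' @examples
#' set.seed(1)
#' tr <- rpois(2000, 5)
#' correlateTrace(tr, binWidth = 0.1)
#' @export
correlateTrace <- function(binnedIntensity, binWidth, maxLag = NULL,
                           cellId = "trace", compartment = "nucleus_chromatin",
                           condition = "G1") {
  n <- length(binnedIntensity)
  if (n < 2) stop("need at least 2 bins")
  stopifnot(binWidth > 0)
  mu <- mean(binnedIntensity)
  if (mu == 0) stop("zero mean intensity: normalization undefined")
  if (is.null(maxLag)) maxLag <- n * binWidth / 4
  lagBins <- unique(round(multipleTauGrid(binWidth, maxLag) / binWidth))
  lagBins <- lagBins[lagBins >= 1 & lagBins < n]
  if (!length(lagBins)) stop("trace too short for requested lags")
  dI <- binnedIntensity - mu
  g <- vapply(lagBins, function(k) {
    mean(dI[seq_len(n - k)] * dI[seq_len(n - k) + k]) / mu^2
  }, numeric(1))
  new("AcfRecord", cellId = cellId, compartment = compartment,
      condition = condition, lags = lagBins * binWidth, acf = g,
      meanIntensity = mu / binWidth,   # counts/ms == kHz
      duration = n * binWidth / 1000)
}
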