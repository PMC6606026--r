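## Conversion of FCS concentrations to absolute copy numbers and the
## bootstrap comparison between quantification methods.

#' Copy number from a concentration and a compartment volume
#'
#' `copies = C[mol/L] * V[L] * N_A`, with the compartment volume given in
#' cubic micrometres (1 um^3 = 1e-15 L).
#'
#' @param concentration concentration in nM (>= 0), vectorized.
#' @param volume compartment volume in um^3 (> 0), vectorized.
#' @return copy number(s).
#' @examples
#' copiesFromConcentration(330, 1262)  # ~250,000 copies
#' @export
copiesFromConcentration <- function(concentration, volume) {
  if (any(concentration < 0)) stop("concentration must be non-negative")
  if (any(volume <= 0)) stop("volume must be positive")
  concentration * 1e-9 * volume * 1e-15 * AVOGADRO
}

#' Cytoplasmic volume from nuclear volume and the cell/nucleus volume ratio
#'
#' `Vcyt = Vcell - Vnuc ~ Vnuc * (Vr - 1)`, assuming the cell-to-nucleus
#' volume ratio `Vr` is constant for a given cell-cycle stage (3.04 for
#' G1/G2, 5.72 for prometaphase).
#'
#' @param vNucleus nuclear volume (um^3, > 0), vectorized.
#' @param vRatio cell/nucleus volume ratio (> 1), vectorized.
#' @return cytoplasmic volume (um^3).
#' @examples
#' cytoplasmicVolume(1000, 3.04)  # 2040
#' @export
cytoplasmicVolume <- function(vNucleus, vRatio) {
  if (any(vNucleus <= 0)) stop("vNucleus must be positive")
  if (any(vRatio <= 1)) stop("vRatio must exceed 1")
  vNucleus * (vRatio - 1)
}

#' Standard cell-to-nucleus volume ratios per cell-cycle stage
#'
#' @param condition `"G1"`, `"G2"` or `"prometaphase"`.
#' @return the volume ratio `Vr` (3.04 for G1/G2, 5.72 for prometaphase).
#' @export
volumeRatio <- function(condition = c("G1", "G2", "prometaphase")) {
  condition <- match.arg(condition)
  if (condition == "prometaphase") 5.72 else 3.04
}

#' Summarize copy numbers for one protein x condition x compartment cell
#'
#' Median and central 68% interval (16th to 84th percentile, linear
#' interpolation between order statistics), the format used to tabulate
#' copy-number distributions.
#'
#' @param values numeric copy numbers (>= 1 value).
#' @param protein,condition,compartment labels carried into the row.
#' @return one-row data.frame with columns `protein`, `condition`,
#'   `compartment`, `median`, `lo68`, `hi68`, `n`.
#' @examples
#' summarizeCondition(1:100)
#' @export
summarizeCondition <- function(values, protein = NA_character_,
                               condition = NA_character_,
                               compartment = NA_character_) {
  if (!length(values)) stop("no values to summarize")
  q <- quantile(values, c(0.16, 0.5, 0.84), type = 7, names = FALSE)
  data.frame(protein = protein, condition = condition,
             compartment = compartment, median = q[2], lo68 = q[1],
             hi68 = q[3], n = length(values), stringsAsFactors = FALSE)
}

#' CPM-based stoichiometry relative to free mEGFP
#'
#' Ratio of the median counts-per-molecule of the tagged protein of interest
#' to the median CPM of freely diffusing monomeric EGFP. A ratio near 1
#' indicates monomers, near 2 dimers.
#'
#' @param proteinCpms CPM values (kHz) of the tagged protein.
#' @param megfpCpms CPM values (kHz) of the free mEGFP reference.
#' @return the ratio of medians.
#' @examples
#' cpmStoichiometry(c(9, 10, 11), c(10, 10, 10))
#' @export
cpmStoichiometry <- function(proteinCpms, megfpCpms) {
  if (!length(proteinCpms) || !length(megfpCpms))
    stop("both CPM samples must be non-empty")
  ref <- median(megfpCpms)
  if (ref == 0) stop("zero reference median CPM")
  median(proteinCpms) / ref
}

#' Bootstrap ratio between two measurement samples
#'
#' Compares two sets of measurements of the same quantity (e.g. copy numbers
#' from two orthogonal methods) by resampling. Each bootstrap iteration
#' resamples both samples with replacement, computes a summary statistic for
#' each (median by default), and records the ratio statistic(A)/statistic(B).
#' The median and central 68% interval of the `nBoot` ratios are returned.
#' Iterations with a zero denominator are redrawn (and counted) so all ratios
#' are finite.
#'
#' @param sampleA,sampleB non-empty numeric samples.
#' @param nBoot number of bootstrap pairs (default 100000).
#' @param seed integer seed.
#' @param statistic `"median"` or `"mean"`.
#' @return list with `median`, `interval68` (length-2), `nBoot`, `nRedrawn`.
#' @examples
#' bootstrapMethodRatio(rnorm(50, 150, 10), rnorm(50, 100, 10),
#'                      nBoot = 1000, seed = 1)
#' @export
bootstrapMethodRatio <- function(sampleA, sampleB, nBoot = 1e5, seed = 1L,
                                 statistic = c("median", "mean")) {
  if (!length(sampleA) || !length(sampleB)) stop("samples must be non-empty")
  if (nBoot < 1) stop("nBoot must be at least 1")
  statistic <- match.arg(statistic)
  statFun <- if (statistic == "median") median else mean
  nA <- length(sampleA); nB <- length(sampleB)
  .withSeed(seed, {
    drawRatios <- function(k) {
      a <- matrix(sample(sampleA, k * nA, replace = TRUE), nrow = k)
      b <- matrix(sample(sampleB, k * nB, replace = TRUE), nrow = k)
      apply(a, 1, statFun) / apply(b, 1, statFun)
    }
    ratios <- drawRatios(nBoot)
    nRedrawn <- 0L
    while (any(bad <- !is.finite(ratios))) {
      nRedrawn <- nRedrawn + sum(bad)
      ratios[bad] <- drawRatios(sum(bad))
    }
    q <- quantile(ratios, c(0.16, 0.5, 0.84), type = 7, names = FALSE)
    list(median = q[2], interval68 = c(q[1], q[3]), nBoot = nBoot,
         nRedrawn = nRedrawn)
  })
}
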