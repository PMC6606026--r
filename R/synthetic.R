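## Seeded synthetic-data generators. Every generator draws its noise inside
## a private RNG substream derived from (seed, entity index), so adding one
## more cell/replicate never shifts the noise of the others, and identical
## seed + parameters give byte-identical output.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## deterministic per-entity substream seed, kept below 2^31 - 1
.entitySeed <- function(seed, index, stream = 0L) {
  ((as.double(seed) %% 1e6) * 1009 + stream * 524287 + index) %% 2147483629
}

#' Ground-truth parameter bundles for the synthetic generators
#'
#' Constructors for the generating truths consumed by
#' [simulateFcsMeasurement()], [simulateFrapExperiment()],
#' [simulateSrmTable()] and [simulatePeakSet()]. Each validates its
#' invariants and returns a classed list; downstream parameter-recovery tests
#' compare estimates against these values.
#'
#' @param nParticles mean particle number in the focal volume (> 0).
#' @param tau1,tau2 diffusion times (ms).
#' @param frac1 fraction of component 1 in `[0, 1]`.
#' @param structureParam focal volume axial/lateral ratio kappa (> 1).
#' @param offset ACF baseline.
#' @param cpm counts per molecule (kHz).
#' @param noiseSdScale relative amplitude of the additive Gaussian ACF noise;
#'   the per-lag SD is `noiseSdScale * (G(tau) + 1/N)`, a simple stand-in for
#'   photon statistics. 0 gives noiseless curves.
#' @param seed integer seed.
#' @return `fcsTruth()`: an object of class `FcsTruth`.
#' @examples
#' tr <- fcsTruth(nParticles = 10, tau1 = 0.5, tau2 = 50, frac1 = 0.6)
#' rec <- simulateFcsMeasurement(tr)
#' @export
fcsTruth <- function(nParticles, tau1 = 0.5, tau2 = 50, frac1 = 0.8,
                     structureParam = 5, offset = 0, cpm = 10,
                     noiseSdScale = 0, seed = 1L) {
  stopifnot(nParticles > 0, tau1 > 0, tau2 > 0, frac1 >= 0, frac1 <= 1,
            structureParam > 1, cpm > 0, noiseSdScale >= 0)
  structure(list(nParticles = nParticles, tau1 = tau1, tau2 = tau2,
                 frac1 = frac1, structureParam = structureParam,
                 offset = offset, cpm = cpm, noiseSdScale = noiseSdScale,
                 seed = as.integer(seed)),
            class = "FcsTruth")
}

#' @rdname fcsTruth
#' @param solubleFrac soluble (unbound) fraction of the nuclear pool.
#' @param stableFracOfBound stable fraction of the chromatin-bound pool
#'   (`1 - a` of the double exponential).
#' @param kOffDynamic,kOffStable dissociation rate constants (1/min).
#' @param noiseSd absolute Gaussian noise SD on the normalized signal.
#' @param nCells number of cells to simulate.
#' @param times sampling grid (min), strictly increasing from 0.
#' @param bleachedVolumeFraction fraction of the nuclear volume photobleached
#'   (default 0.5: half the nucleus).
#' @param condition `"G1"` or `"G2"`, recorded in each curve.
#' @return `frapTruth()`: an object of class `FrapTruth`.
#' @export
frapTruth <- function(solubleFrac = 0.365, stableFracOfBound = 0,
                      kOffDynamic = 1 / 13.7, kOffStable = 1 / (8.6 * 60),
                      noiseSd = 0.03, nCells = 19L, times = 0:40,
                      bleachedVolumeFraction = 0.5,
                      condition = if (stableFracOfBound > 0) "G2" else "G1",
                      seed = 1L) {
  stopifnot(solubleFrac >= 0, solubleFrac <= 1,
            stableFracOfBound >= 0, stableFracOfBound <= 1,
            kOffDynamic > 0, kOffStable > 0, noiseSd >= 0, nCells >= 1,
            bleachedVolumeFraction > 0, bleachedVolumeFraction < 1)
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing and start at 0")
  structure(list(solubleFrac = solubleFrac,
                 stableFracOfBound = stableFracOfBound,
                 kOffDynamic = kOffDynamic, kOffStable = kOffStable,
                 noiseSd = noiseSd, nCells = as.integer(nCells),
                 times = times,
                 bleachedVolumeFraction = bleachedVolumeFraction,
                 condition = condition, seed = as.integer(seed)),
            class = "FrapTruth")
}

#' @rdname fcsTruth
#' @param protein,peptide character vectors (recycled against each other)
#'   naming the peptides quantified per protein.
#' @param trueFmol true light-peptide amount per peptide (fmol).
#' @param spikeFmol heavy reference spike per peptide (fmol).
#' @param nCellsPerAliquot cells contributing to each aliquot.
#' @param cv relative multiplicative noise (SD of the log-ratio).
#' @param nBioReps,nTechReps biological and technical replicate counts.
#' @param fraction `"soluble"` or `"chromatin"`.
#' @return `srmTruth()`: an object of class `SrmTruth`.
#' @export
srmTruth <- function(protein, peptide = paste0(protein, "_pep"),
                     trueFmol, spikeFmol = 10, nCellsPerAliquot = 62500L,
                     cv = 0.1, nBioReps = 2L, nTechReps = 2L,
                     condition = "G1", fraction = "chromatin", seed = 1L) {
  n <- max(length(protein), length(peptide), length(trueFmol),
           length(spikeFmol))
  pep <- data.frame(protein = rep_len(protein, n),
                    peptide = rep_len(peptide, n),
                    trueFmol = rep_len(trueFmol, n),
                    spikeFmol = rep_len(spikeFmol, n))
  stopifnot(all(pep$trueFmol > 0), all(pep$spikeFmol > 0),
            nCellsPerAliquot > 0, cv >= 0, nBioReps >= 1, nTechReps >= 1,
            !anyDuplicated(pep$peptide))
  structure(list(peptides = pep,
                 nCellsPerAliquot = as.integer(nCellsPerAliquot), cv = cv,
                 nBioReps = as.integer(nBioReps),
                 nTechReps = as.integer(nTechReps), condition = condition,
                 fraction = fraction, seed = as.integer(seed)),
            class = "SrmTruth")
}

#' @rdname fcsTruth
#' @param distribution inter-peak spacing distribution: `"exponential"`,
#'   `"constant"` or `"lognormal"`. Spacings are midpoint-to-midpoint
#'   distances between consecutive peaks (bp).
#' @param parameters named list of distribution parameters: `mean` for
#'   exponential, `value` for constant, `meanlog`/`sdlog` for lognormal.
#' @param peakWidth peak width (bp, > 0); spacings below `peakWidth` are
#'   redrawn so peaks never overlap.
#' @param chromSizes named numeric vector, chromosome -> length (bp).
#' @return `spacingModel()`: an object of class `SpacingModel`.
#' @export
spacingModel <- function(distribution = c("exponential", "constant",
                                          "lognormal"),
                         parameters = list(mean = 67500),
                         peakWidth = 1000,
                         chromSizes = c(chr1 = 50e6)) {
  distribution <- match.arg(distribution)
  stopifnot(peakWidth > 0, length(chromSizes) >= 1, all(chromSizes > 0),
            !is.null(names(chromSizes)))
  ok <- switch(distribution,
    exponential = is.numeric(parameters$mean) && parameters$mean > 0,
    constant = is.numeric(parameters$value) && parameters$value >= 0,
    lognormal = is.numeric(parameters$meanlog) &&
      is.numeric(parameters$sdlog) && parameters$sdlog >= 0)
  if (!ok) stop("missing or invalid parameters for distribution '",
                distribution, "'")
  structure(list(distribution = distribution, parameters = parameters,
                 peakWidth = peakWidth, chromSizes = chromSizes),
            class = "SpacingModel")
}

#' Simulate one FCS measurement from a known generating truth
#'
#' Evaluates the two-component diffusion ACF (see [acfDiffusionModel()]) on a
#' lag grid and adds seeded Gaussian noise with per-lag SD
#' `noiseSdScale * (G(tau) + 1/N)`. With `noiseSdScale = 0` the curve is the
#' noiseless closed form.
#'
#' @param truth an `FcsTruth` from [fcsTruth()].
#' @param lagGrid strictly increasing positive lag times (ms); default a
#'   multiple-tau ladder from 1 us to 1 s.
#' @param cellId,compartment,condition metadata for the record.
#' @return an [AcfRecord-class] with `meanIntensity = cpm * N`.
#' @examples
#' rec <- simulateFcsMeasurement(fcsTruth(nParticles = 10, noiseSdScale = 0.02))
#' @export
simulateFcsMeasurement <- function(truth, lagGrid = multipleTauGrid(),
                                   cellId = "cell_1",
                                   compartment = "nucleus_chromatin",
                                   condition = "G1") {
  stopifnot(inherits(truth, "FcsTruth"))
  if (any(lagGrid <= 0)) stop("lag times must be positive")
  if (any(diff(lagGrid) <= 0)) stop("lag grid must be strictly increasing")
  g <- acfDiffusionModel(lagGrid, truth$nParticles, truth$tau1, truth$tau2,
                         truth$frac1, truth$structureParam, truth$offset)
  if (truth$noiseSdScale > 0) {
    sdv <- truth$noiseSdScale * (g + 1 / truth$nParticles)
    g <- g + .withSeed(truth$seed, rnorm(length(g), 0, sdv))
  }
  new("AcfRecord", cellId = cellId, compartment = compartment,
      condition = condition, lags = lagGrid, acf = g,
      meanIntensity = truth$cpm * truth$nParticles, duration = 30)
}

#' Simulate an inverse-FRAP experiment
#'
#' Generates `nCells` [FrapCurve-class] objects whose noiseless normalized
#' difference signal follows
#' `f(t) = a exp(-kOffDynamic t) + (1-a) exp(-kOffStable t)` with
#' `a = 1 - stableFracOfBound`, so `f(0) = 1`. Each curve also carries the
#' pre/post-bleach unbleached-region intensity pair implied by
#' `solubleFrac` and the bleached volume fraction, from which
#' [solubleFraction()] recovers the generating soluble fraction.
#'
#' @param truth a `FrapTruth` from [frapTruth()].
#' @return list of [FrapCurve-class] objects, one per cell.
#' @examples
#' curves <- simulateFrapExperiment(frapTruth(nCells = 3, noiseSd = 0))
#' normalizeIfrap(curves[[1]])
#' @export
simulateFrapExperiment <- function(truth) {
  stopifnot(inherits(truth, "FrapTruth"))
  if (!length(truth$times)) stop("empty time grid")
  a <- 1 - truth$stableFracOfBound
  f <- a * exp(-truth$kOffDynamic * truth$times) +
    (1 - a) * exp(-truth$kOffStable * truth$times)
  pre <- 100                             # arbitrary intensity units
  postLevel <- 1 - truth$solubleFrac * truth$bleachedVolumeFraction
  lapply(seq_len(truth$nCells), function(i) {
    eps <- if (truth$noiseSd > 0) {
      .withSeed(.entitySeed(truth$seed, i, 1L),
                rnorm(2 * length(f), 0, truth$noiseSd * pre / sqrt(2)))
    } else rep(0, 2 * length(f))
    nf <- length(f)
    unbleached <- pre * (postLevel / 2 + f / 2) + eps[seq_len(nf)]
    bleached <- pre * (postLevel / 2 - f / 2) + eps[nf + seq_len(nf)]
    new("FrapCurve", cellId = sprintf("cell_%03d", i),
        condition = truth$condition, times = truth$times,
        bleached = bleached, unbleached = unbleached, prebleachMean = pre,
        prebleachUnbleached = pre,
        postbleachUnbleached = pre * postLevel)
  })
}

#' Simulate an SRM transition table
#'
#' Emits a Skyline-style long table with three transitions per peptide and
#' one row per transition x biological replicate x technical replicate.
#' Heavy apex heights are per-transition response factors (fixed given the
#' seed); light heights are `heavy * (trueFmol/spikeFmol) * e`, where `e` is
#' mean-one log-normal noise with log-SD `cv`, so the light/heavy ratio has
#' expectation `trueFmol / spikeFmol` exactly and `cv = 0` gives exact
#' ratios.
#'
#' @param truth an `SrmTruth` from [srmTruth()].
#' @return data.frame with columns `protein`, `peptide`, `transition_id`,
#'   `replicate_bio`, `replicate_tech`, `condition`, `fraction`,
#'   `light_apex_height`, `heavy_apex_height`, `spike_fmol`, `n_cells`,
#'   `retained`.
#' @examples
#' simulateSrmTable(srmTruth("SCC1", trueFmol = 10, cv = 0))[1:3, ]
#' @export
simulateSrmTable <- function(truth) {
  stopifnot(inherits(truth, "SrmTruth"))
  pep <- truth$peptides
  nTrans <- 3L
  rows <- expand.grid(transition = seq_len(nTrans),
                      pepIdx = seq_len(nrow(pep)),
                      tech = seq_len(truth$nTechReps),
                      bio = seq_len(truth$nBioReps))
  ## fixed per-transition heavy response factors
  nTransTotal <- nrow(pep) * nTrans
  heavyBase <- .withSeed(.entitySeed(truth$seed, 0L, 2L),
                         1000 * rlnorm(nTransTotal, 0, 0.3))
  transKey <- (rows$pepIdx - 1L) * nTrans + rows$transition
  ratioTrue <- pep$trueFmol[rows$pepIdx] / pep$spikeFmol[rows$pepIdx]
  noise <- if (truth$cv > 0) {
    .withSeed(.entitySeed(truth$seed, 1L, 2L),
              exp(rnorm(nrow(rows), -truth$cv^2 / 2, truth$cv)))
  } else rep(1, nrow(rows))
  heavy <- heavyBase[transKey]
  data.frame(
    protein = pep$protein[rows$pepIdx],
    peptide = pep$peptide[rows$pepIdx],
    transition_id = sprintf("%s_t%d", pep$peptide[rows$pepIdx],
                            rows$transition),
    replicate_bio = rows$bio,
    replicate_tech = rows$tech,
    condition = truth$condition,
    fraction = truth$fraction,
    light_apex_height = heavy * ratioTrue * noise,
    heavy_apex_height = heavy,
    spike_fmol = pep$spikeFmol[rows$pepIdx],
    n_cells = truth$nCellsPerAliquot,
    retained = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Simulate a ChIP-seq peak set with a known spacing distribution
#'
#' Places non-overlapping fixed-width peaks along each chromosome with
#' midpoint-to-midpoint spacings drawn from the model distribution.
#' Spacings smaller than the peak width are redrawn (truncation, negligible
#' for widths well below the mean spacing). Peaks extending beyond the
#' chromosome end are clipped and flagged in the `clipped` metadata column.
#'
#' @param model a `SpacingModel` from [spacingModel()].
#' @param seed integer seed.
#' @param name set name stored in the metadata.
#' @return a [GenomicRanges::GRanges] (0-based half-open when exported as
#'   BED) sorted with non-overlapping ranges and `seqlengths` set.
#' @examples
#' gr <- simulatePeakSet(spacingModel(parameters = list(mean = 67500)), 1)
#' @export
simulatePeakSet <- function(model, seed = 1L, name = "peaks") {
  stopifnot(inherits(model, "SpacingModel"))
  w <- model$peakWidth
  drawGaps <- function(n) {
    switch(model$distribution,
      exponential = rexp(n, 1 / model$parameters$mean),
      constant = rep(model$parameters$value, n),
      lognormal = rlnorm(n, model$parameters$meanlog,
                         model$parameters$sdlog))
  }
  perChrom <- lapply(seq_along(model$chromSizes), function(ci) {
    len <- model$chromSizes[ci]
    .withSeed(.entitySeed(seed, ci, 3L), {
      mids <- numeric(0)
      pos <- w / 2 + drawGaps(1)
      while (pos + w / 2 <= len + w) {   # allow one clipped final peak
        mids <- c(mids, pos)
        repeat {
          gap <- drawGaps(1)
          if (gap >= w) break            # redraw: peaks must not overlap
          if (model$distribution == "constant")
            stop("constant spacing below peak width")
        }
        pos <- pos + gap
      }
      mids
    })
  })
  starts <- ends <- chroms <- list()
  for (ci in seq_along(perChrom)) {
    mids <- perChrom[[ci]]
    if (!length(mids)) next
    s <- pmax(1, round(mids - w / 2))
    e <- pmin(model$chromSizes[ci], round(mids + w / 2) - 1)
    keep <- s <= e
    starts[[ci]] <- s[keep]; ends[[ci]] <- e[keep]
    chroms[[ci]] <- rep(names(model$chromSizes)[ci], sum(keep))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = unlist(chroms),
    ranges = IRanges::IRanges(start = unlist(starts), end = unlist(ends)),
    seqlengths = model$chromSizes)
  gr$clipped <- GenomicRanges::width(gr) < w
  gr <- GenomicRanges::sort(gr)
  S4Vectors::metadata(gr)$name <- name
  gr
}
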