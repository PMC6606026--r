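## Orchestration: the end-to-end reproduction pipeline. Synthetic stages
## exercise the estimators against known ground truth; the arithmetic stages
## recompute the derived quantities from the packaged reference tables.

#' Default configuration for [runPipeline()]
#'
#' Problem sizes are kept modest so the full pipeline runs in seconds; the
#' acceptance-scale checks live in the test suite.
#'
#' @param seed master seed; every stage derives its substreams from it.
#' @param nFcsCurves synthetic ACF curves for the FCS recovery stage.
#' @param fcsNoise relative ACF noise (see [fcsTruth()]).
#' @param nFrapCells cells per condition for the FRAP recovery stage.
#' @param frapNoise absolute noise SD on the normalized FRAP signal.
#' @param srmCv relative noise of the synthetic SRM stage.
#' @param paths optional named list of external input tables (`acf`, `frap`,
#'   `srm`: paths to files written by [writeAcfTable()] and friends). When
#'   given, they replace the corresponding synthetic stage's input and must
#'   exist at validation time.
#' @param verbose emit one log line per stage.
#' @return a classed list (`RunConfig`).
#' @export
defaultRunConfig <- function(seed = 1L, nFcsCurves = 40L, fcsNoise = 0.02,
                             nFrapCells = 8L, frapNoise = 0.03,
                             srmCv = 0.1, paths = list(), verbose = FALSE) {
  structure(list(seed = as.integer(seed), nFcsCurves = as.integer(nFcsCurves),
                 fcsNoise = fcsNoise, nFrapCells = as.integer(nFrapCells),
                 frapNoise = frapNoise, srmCv = srmCv, paths = paths,
                 verbose = isTRUE(verbose)),
            class = "RunConfig")
}

.validateRunConfig <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  for (nm in names(config$paths)) {
    p <- config$paths[[nm]]
    if (!file.exists(p))
      stop("configured input table '", nm, "' not found: ", p)
  }
  invisible(config)
}

.stageLog <- function(config, stage, ...) {
  if (config$verbose)
    message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the end-to-end reproduction pipeline
#'
#' Executes the stages in dependency order -- synthetic-data generation,
#' FCS fitting + QC + copy-number conversion, iFRAP fitting + population
#' partition, SRM quantification, equilibrium-model prediction and genomic
#' occupancy arithmetic -- and compiles a reproduction report comparing each
#' derived quantity against its published value (recomputed from the
#' packaged reference tables, never hard-coded into the comparison). The
#' run is deterministic given `config$seed`.
#'
#' @param config a `RunConfig` from [defaultRunConfig()].
#' @return list with `report` (data.frame: `quantity`, `computed`,
#'   `reference`, `rounding`, `pass`) and `stages` (per-stage intermediate
#'   results).
#' @examples
#' \donttest{
#' res <- runPipeline(defaultRunConfig(seed = 1))
#' res$report
#' }
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  .validateRunConfig(config)
  const <- referenceConstants()
  lcms <- referenceLcmsCopyNumbers()
  fcsTab <- referenceFcsCopyNumbers()
  fracTab <- referenceFrapFractions()
  partTab <- referenceFrapPartition()
  stages <- list()

  ## --- FCS stage: synthetic parameter recovery --------------------------
  dyeN <- 12
  dyeFit <- fitAcf(simulateFcsMeasurement(
    fcsTruth(nParticles = dyeN, tau1 = 0.03, tau2 = 0.03, frac1 = 1,
             noiseSdScale = 0, seed = config$seed),
    cellId = "dye"))
  cal <- calibrateConfocalVolume(dyeFit, 50)
  targetConc <- 330                      # nM, nuclear SCC1-scale truth
  targetN <- targetConc * 1e-9 * cal@effectiveVolume * AVOGADRO
  records <- if (!is.null(config$paths$acf)) {
    readAcfTable(config$paths$acf)
  } else {
    lapply(seq_len(config$nFcsCurves), function(i) {
      simulateFcsMeasurement(
        fcsTruth(nParticles = targetN, tau1 = 0.5, tau2 = 30, frac1 = 0.4,
                 cpm = 10, noiseSdScale = config$fcsNoise,
                 seed = .entitySeed(config$seed, i, 10L)),
        cellId = sprintf("fcs_%03d", i))
    })
  }
  fits <- lapply(records, fitAcf)
  qc <- qcFilter(fits, megfpMeanCpm = 10)
  concs <- vapply(qc$retained, concentrationFromFit, numeric(1),
                  calibration = cal)
  fcsStage <- list(nCurves = length(records), qcReport = qc$report,
                   medianConcentration = median(concs),
                   truthConcentration = targetConc)
  .stageLog(config, "fcs", "%d curves in, %d retained, median %.1f nM",
            length(records), qc$report$nRetained, median(concs))
  stages$fcs <- fcsStage

  ## --- FRAP stage: synthetic recovery + partition -----------------------
  frapG1 <- if (!is.null(config$paths$frap)) readFrapTable(config$paths$frap)
    else simulateFrapExperiment(frapTruth(
      solubleFrac = 0.365, stableFracOfBound = 0, kOffDynamic = 1 / 13.7,
      noiseSd = config$frapNoise, nCells = config$nFrapCells,
      times = 0:40, seed = .entitySeed(config$seed, 1L, 20L)))
  g1Fits <- lapply(frapG1, function(cur) {
    d <- normalizeIfrap(cur)
    selectModel(fitSingleExponential(d), fitDoubleExponential(d))
  })
  g1Residence <- mean(vapply(g1Fits, residenceDynamic, numeric(1)))
  stages$frap <- list(nCells = length(frapG1),
                      meanResidenceDynamic = g1Residence,
                      truthResidence = 13.7)
  .stageLog(config, "frap", "%d cells, mean dynamic residence %.2f min",
            length(frapG1), g1Residence)

  ## --- SRM stage: synthetic recovery ------------------------------------
  srmTab <- if (!is.null(config$paths$srm)) readSrmTable(config$paths$srm)
    else simulateSrmTable(srmTruth(
      protein = rep(c("SCC1", "SMC3"), each = 3),
      peptide = paste0(rep(c("SCC1", "SMC3"), each = 3), "_p", 1:3),
      trueFmol = rep(c(7.2, 6.9), each = 3), spikeFmol = 10,
      cv = config$srmCv, seed = .entitySeed(config$seed, 1L, 30L)))
  srmQuant <- srmProteinQuant(srmTab)
  stages$srm <- list(nRows = nrow(srmTab), quant = srmQuant)
  .stageLog(config, "srm", "%d transition rows -> %d protein rows",
            nrow(srmTab), nrow(srmQuant))

  ## --- equilibrium model -------------------------------------------------
  eq <- const$equilibrium
  params <- calibrateFromG1(eq$bound_fraction_g1)
  bTpred <- boundFraction(eq$stable_fraction_g2, params)
  cmp <- comparePrediction(eq$observed_bound_fraction_g2, bTpred)
  stages$equilibrium <- list(params = params, predicted = bTpred,
                             comparison = cmp)
  .stageLog(config, "model", "bT(s=%.3f) = %.3f vs observed %.3f",
            eq$stable_fraction_g2, bTpred, eq$observed_bound_fraction_g2)

  ## --- genome occupancy arithmetic ---------------------------------------
  gn <- const$genome
  cohesinSites <- scaleToGenome(const$sites$cohesin_generic,
                                gn$mappable_genome_bp, gn$hela_genome_bp)
  ctcfSites <- scaleToGenome(const$sites$ctcf, gn$mappable_genome_bp,
                             gn$hela_genome_bp)
  spacing <- expectedSpacing(gn$mappable_genome_bp,
                             const$sites$cohesin_generic)
  ctcfOcc <- occupancyRatio(const$copies$ctcf_nuclear_g1,
                            ctcfSites$rounded)
  centromeric <- perChromosomeCopies(
    const$copies$prometaphase_chromatin_cohesin, gn$n_chromosomes)
  extrusion <- extrusionRate(const$loops$median_tad_kb,
                             const$kinetics$residence_dynamic_g1_min)
  stages$genome <- list(cohesinSites = cohesinSites, ctcfSites = ctcfSites,
                        spacing = spacing, ctcfOccupancy = ctcfOcc,
                        centromeric = centromeric, extrusion = extrusion)
  .stageLog(config, "genome", "%d cohesin sites, %d CTCF sites",
            cohesinSites$rounded, ctcfSites$rounded)

  ## --- cross-table arithmetic --------------------------------------------
  stagRatioG2 <- .lcmsValue("STAG2", "G2", "chromatin", lcms) /
    .lcmsValue("STAG1", "G2", "chromatin", lcms)
  stagRatioPro <- .lcmsValue("STAG2", "prometaphase", "chromatin", lcms) /
    .lcmsValue("STAG1", "prometaphase", "chromatin", lcms)
  partitions <- lapply(c(G1 = "G1", G2 = "G2"), function(cond) {
    fr <- fracTab[fracTab$condition == cond, ]
    copyNumberPartition(
      .fcsValue("SCC1", cond, tab = fcsTab),
      populationFractions(fr$soluble, fr$dynamic, fr$stable,
                          fr$solubleSd, fr$dynamicSd, fr$stableSd))
  })
  boundOf <- function(p) sum(p$copies[p$population %in%
                                        c("dynamic", "stable")])
  methodRatioG1 <- boundOf(partitions$G1) /
    .lcmsValue("SCC1", "G1", "chromatin", lcms)
  methodRatioG2 <- boundOf(partitions$G2) /
    .lcmsValue("SCC1", "G2", "chromatin", lcms)
  g2BoundTotal <- boundOf(partitions$G2)
  ## bound share of the nuclear pool, from the published partition table
  ## (its entries carry more precision than the rounded printed fractions)
  g1Part <- partTab[partTab$condition == "G1", ]
  g1BoundPct <- 100 *
    sum(g1Part$copies[g1Part$population %in% c("dynamic", "stable")]) /
    g1Part$copies[g1Part$population == "total"]
  ## Table-3 reproduction error (worst relative deviation, non-zero rows)
  tab3err <- max(unlist(lapply(c("G1", "G2"), function(cond) {
    ref <- partTab[partTab$condition == cond, ]
    comp <- partitions[[cond]]
    m <- merge(ref, comp, by = "population")
    ok <- m$copies.x > 0
    abs(m$copies.y[ok] - m$copies.x[ok]) / m$copies.x[ok]
  })))
  stages$crossTable <- list(partitions = partitions, table3MaxRelErr = tab3err)

  report <- rbind(
    data.frame(quantity = "bound_fraction_g2_predicted",
               computed = round(bTpred, 3), reference = 0.769,
               rounding = "3 decimals"),
    data.frame(quantity = "bound_fraction_g2_discrepancy",
               computed = round(cmp$absoluteDifference, 3),
               reference = 0.041, rounding = "3 decimals"),
    data.frame(quantity = "cohesin_sites_per_cell",
               computed = cohesinSites$rounded, reference = 117000,
               rounding = "thousand"),
    data.frame(quantity = "ctcf_sites_per_cell",
               computed = ctcfSites$rounded, reference = 120000,
               rounding = "thousand"),
    data.frame(quantity = "expected_site_spacing_bp",
               computed = spacing, reference = 67500, rounding = "none"),
    data.frame(quantity = "ctcf_bound_fraction_for_full_occupancy",
               computed = round(ctcfOcc$boundFractionForFullOccupancy, 2),
               reference = 0.67, rounding = "2 decimals"),
    data.frame(quantity = "centromeric_cohesin_per_chromosome",
               computed = centromeric$rounded, reference = 200,
               rounding = "hundred"),
    data.frame(quantity = "extrusion_rate_tad_kb_per_min",
               computed = extrusion$rounded, reference = 14,
               rounding = "integer"),
    data.frame(quantity = "stag2_stag1_chromatin_ratio_g2",
               computed = round(stagRatioG2, 1), reference = 4.6,
               rounding = "1 decimal"),
    data.frame(quantity = "stag2_stag1_chromatin_ratio_prometaphase",
               computed = round(stagRatioPro, 1), reference = 2.9,
               rounding = "1 decimal"),
    data.frame(quantity = "fcs_frap_vs_lcms_bound_scc1_g1",
               computed = round(methodRatioG1, 1), reference = 2.3,
               rounding = "1 decimal"),
    data.frame(quantity = "fcs_frap_vs_lcms_bound_scc1_g2",
               computed = round(methodRatioG2, 1), reference = 1.4,
               rounding = "1 decimal"),
    data.frame(quantity = "g2_chromatin_bound_total",
               computed = roundPaperStyle(g2BoundTotal, "thousand"),
               reference = 213000, rounding = "thousand"),
    data.frame(quantity = "g1_chromatin_bound_percent",
               computed = roundPaperStyle(g1BoundPct, "integer"),
               reference = 64, rounding = "integer"),
    data.frame(quantity = "partition_table_max_rel_err",
               computed = tab3err, reference = 0.01,
               rounding = "upper bound"),
    data.frame(quantity = "fcs_median_concentration_rel_err",
               computed = abs(fcsStage$medianConcentration - targetConc) /
                 targetConc,
               reference = 0.05, rounding = "upper bound"),
    data.frame(quantity = "frap_g1_residence_rel_err",
               computed = abs(g1Residence - 13.7) / 13.7,
               reference = 0.10, rounding = "upper bound"),
    data.frame(quantity = "srm_copy_recovery_rel_err",
               computed = max(abs(srmQuant$mean -
                 copiesPerCell(rep(c(7.2, 6.9), 1), 62500)[
                   match(srmQuant$protein, c("SCC1", "SMC3"))]) /
                 copiesPerCell(rep(c(7.2, 6.9), 1), 62500)[
                   match(srmQuant$protein, c("SCC1", "SMC3"))]),
               reference = 0.05, rounding = "upper bound")
  )
  report$pass <- ifelse(report$rounding == "upper bound",
                        report$computed <= report$reference,
                        report$computed == report$reference)
  list(report = report, stages = stages)
}
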