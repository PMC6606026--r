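## Packaged reference tables: the published copy-number tables and derived
## constants, shipped as plain CSV/YAML under inst/extdata and used by the
## reproduction pipeline and the cross-table arithmetic.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "cohesinCensus",
                      mustWork = FALSE)
  if (!nzchar(path)) stop("packaged file not found: ", file)
  path
}

#' Packaged reference tables and constants
#'
#' Loaders for the published quantification tables shipped with the
#' package:
#' \itemize{
#'   \item `referenceLcmsCopyNumbers()`: LC-MS/SRM copies per cell of the
#'     cohesin subunits per condition and fraction, as mean with
#'     `[mean - sd, mean + sd]` interval (`lo`, `hi`); missing
#'     quantifications (soluble SMC1) are `NA`, never zero.
#'   \item `referenceFcsCopyNumbers()`: FCS-derived copy numbers per
#'     protein, condition and compartment, as median with central 68%
#'     interval.
#'   \item `referenceFrapFractions()`: iFRAP-derived soluble/dynamic/stable
#'     fractions (mean and across-cell SD) per condition.
#'   \item `referenceFrapPartition()`: the published soluble/dynamic/stable
#'     nuclear copy numbers obtained by multiplying the FCS nuclear medians
#'     by the iFRAP fractions.
#'   \item `referenceConstants()`: genome sizes, site counts, QC thresholds
#'     and kinetic constants (nested list from YAML).
#' }
#'
#' @return a data.frame (or nested list for `referenceConstants()`).
#' @examples
#' head(referenceLcmsCopyNumbers())
#' referenceConstants()$genome$mappable_genome_bp
#' @export
referenceLcmsCopyNumbers <- function() {
  utils::read.csv(.extdata("lcms_copy_numbers.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname referenceLcmsCopyNumbers
#' @export
referenceFcsCopyNumbers <- function() {
  utils::read.csv(.extdata("fcs_copy_numbers.csv"), stringsAsFactors = FALSE)
}

#' @rdname referenceLcmsCopyNumbers
#' @export
referenceFrapFractions <- function() {
  utils::read.csv(.extdata("frap_fractions.csv"), stringsAsFactors = FALSE)
}

#' @rdname referenceLcmsCopyNumbers
#' @export
referenceFrapPartition <- function() {
  utils::read.csv(.extdata("frap_partition_copy_numbers.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname referenceLcmsCopyNumbers
#' @export
referenceConstants <- function() {
  yaml::read_yaml(.extdata("constants.yaml"))
}

.lcmsValue <- function(protein, condition, fraction,
                       tab = referenceLcmsCopyNumbers()) {
  row <- tab[tab$protein == protein & tab$condition == condition &
               tab$fraction == fraction, ]
  if (nrow(row) != 1) stop("no unique row for ", protein)
  row$mean
}

.fcsValue <- function(protein, condition,
                      compartment = "nucleus_chromatin",
                      tab = referenceFcsCopyNumbers()) {
  row <- tab[tab$protein == protein & tab$condition == condition &
               tab$compartment == compartment, ]
  if (nrow(row) != 1) stop("no unique row for ", protein)
  row$median
}

#' Table I/O for measurement records
#'
#' Long-format TSV readers/writers for ACF curves (one row per lag per
#' measurement) and iFRAP curves (one row per frame per cell), plus CSV I/O
#' for SRM transition tables. Columns are documented in the file headers.
#'
#' @param records list of [AcfRecord-class] (`writeAcfTable`) or of
#'   [FrapCurve-class] (`writeFrapTable`).
#' @param path file path.
#' @return readers return lists of records/curves or a data.frame; writers
#'   return `path` invisibly.
#' @export
writeAcfTable <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(r) {
    data.frame(cell_id = r@cellId, compartment = r@compartment,
               condition = r@condition, lag_ms = r@lags, acf = r@acf,
               mean_intensity_khz = r@meanIntensity, duration_s = r@duration)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeAcfTable
#' @export
readAcfTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$lag_ms), ]
    new("AcfRecord", cellId = d$cell_id[1], compartment = d$compartment[1],
        condition = d$condition[1], lags = d$lag_ms, acf = d$acf,
        meanIntensity = d$mean_intensity_khz[1], duration = d$duration_s[1])
  })
}

#' @rdname writeAcfTable
#' @export
writeFrapTable <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(r) {
    data.frame(cell_id = r@cellId, condition = r@condition,
               time_min = r@times, bleached = r@bleached,
               unbleached = r@unbleached, prebleach_mean = r@prebleachMean,
               prebleach_unbleached = r@prebleachUnbleached,
               postbleach_unbleached = r@postbleachUnbleached)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeAcfTable
#' @export
readFrapTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$time_min), ]
    new("FrapCurve", cellId = d$cell_id[1], condition = d$condition[1],
        times = d$time_min, bleached = d$bleached,
        unbleached = d$unbleached, prebleachMean = d$prebleach_mean[1],
        prebleachUnbleached = d$prebleach_unbleached[1],
        postbleachUnbleached = d$postbleach_unbleached[1])
  })
}

#' @rdname writeAcfTable
#' @param table SRM transition data.frame.
#' @export
writeSrmTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAcfTable
#' @export
readSrmTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
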