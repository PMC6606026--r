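## Genomic occupancy arithmetic over ChIP-seq peak sets.

#' @importFrom GenomicRanges GRanges reduce findOverlaps seqnames start end
#'   width sort
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits metadata
NULL

#' Read a peak set from a BED file
#'
#' Imports a (minimum 3-column) BED file, sorts it and merges overlapping
#' intervals, so the returned set satisfies the per-chromosome
#' sorted/non-overlapping invariant.
#'
#' @param path BED file path (0-based half-open intervals).
#' @param name set name stored in the metadata.
#' @return a sorted, reduced `GRanges`.
#' @export
readPeakBed <- function(path, name = basename(path)) {
  gr <- rtracklayer::import(path, format = "BED")
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  S4Vectors::metadata(gr)$name <- name
  gr
}

#' Write a peak set as 3-column BED
#'
#' @param peaks a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePeakBed <- function(peaks, path) {
  rtracklayer::export(peaks, path, format = "BED")
  invisible(path)
}

#' Scale a mappable-genome site count to the whole genome
#'
#' Extrapolates the number of enrichment sites called in the mappable
#' (non-repetitive) genome to the full genome assuming equal site density:
#' `sitesTotal = mappableSites / mappableGenome * totalGenome`. For the HeLa
#' genome (7.9 Gb) versus the mappable human genome (2.7 Gb), ~40,000 sites
#' scale to ~117,000.
#'
#' @param mappableSites site count in the mappable genome.
#' @param mappableGenome mappable genome size (bp, > 0).
#' @param totalGenome total genome size (bp).
#' @return list with `raw` (exact value) and `rounded` (nearest thousand,
#'   the convention used when quoting such extrapolations).
#' @examples
#' scaleToGenome(40000, 2.7e9, 7.9e9)
#' @export
scaleToGenome <- function(mappableSites, mappableGenome, totalGenome) {
  if (mappableGenome <= 0) stop("mappableGenome must be positive")
  if (totalGenome < mappableGenome)
    stop("totalGenome must be at least mappableGenome")
  raw <- mappableSites / mappableGenome * totalGenome
  list(raw = raw, rounded = roundPaperStyle(raw, "thousand"))
}

#' Expected uniform spacing between sites
#'
#' `mappableGenome / nSites`: the mean inter-site distance if sites were
#' equally spaced within the mappable genome (2.7 Gb / 40,000 = 67.5 kb).
#'
#' @param mappableGenome genome size (bp).
#' @param nSites number of sites (> 0).
#' @return expected spacing (bp).
#' @examples
#' expectedSpacing(2.7e9, 40000)
#' @export
expectedSpacing <- function(mappableGenome, nSites) {
  if (nSites <= 0) stop("nSites must be positive")
  mappableGenome / nSites
}

#' Distances between consecutive peaks and their category fractions
#'
#' Computes midpoint-to-midpoint distances between consecutive peaks on the
#' same chromosome (never across chromosomes; chromosomes with a single
#' peak contribute no distances) and bins them into distance categories.
#' The default edges span 10 kb to 2 Mb. `anchor = "edge"` switches
#' the distance definition to gap (end-to-start) distances.
#'
#' @param peaks a `GRanges` (sorted, non-overlapping; see [readPeakBed()]).
#' @param categoryEdges increasing breakpoints (bp) between categories; the
#'   outer bins are open-ended.
#' @param anchor `"midpoint"` (default) or `"edge"`.
#' @return list with `distances` (numeric, bp), `fractions` (named per
#'   category), `counts`, and `nSinglePeakChromosomes`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(1, 50001, 120001), width = 1000))
#' spacingDistribution(gr)
#' @export
spacingDistribution <- function(peaks,
                                categoryEdges = c(1e4, 5e4, 1e5, 5e5, 1e6,
                                                  2e6),
                                anchor = c("midpoint", "edge")) {
  anchor <- match.arg(anchor)
  if (length(peaks) < 2) stop("need at least 2 peaks")
  stopifnot(all(diff(categoryEdges) > 0))
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  perChrom <- split(seq_along(peaks), chrom)
  nSingle <- sum(vapply(perChrom, length, integer(1)) < 2)
  dists <- unlist(lapply(perChrom, function(idx) {
    if (length(idx) < 2) return(numeric(0))
    s <- GenomicRanges::start(peaks)[idx]
    e <- GenomicRanges::end(peaks)[idx]
    o <- order(s)
    s <- s[o]; e <- e[o]
    if (anchor == "midpoint") diff((s + e) / 2)
    else s[-1] - e[-length(e)]
  }), use.names = FALSE)
  breaks <- c(-Inf, categoryEdges, Inf)
  labs <- c(paste0("<", format(categoryEdges[1], scientific = FALSE,
                               big.mark = "")),
            paste(head(categoryEdges, -1), categoryEdges[-1], sep = "-"),
            paste0(">", format(categoryEdges[length(categoryEdges)],
                               scientific = FALSE, big.mark = "")))
  counts <- table(cut(dists, breaks = breaks, labels = labs, right = FALSE))
  fractions <- setNames(as.numeric(counts) / length(dists), names(counts))
  list(distances = dists, fractions = fractions, counts = counts,
       nSinglePeakChromosomes = nSingle)
}

#' Count connected genomic sites across peak sets
#'
#' Builds the connected components of mutually overlapping intervals pooled
#' across all input sets; each component is a single "connected genomic
#' site", counted once and labelled by the input sets contributing to it.
#' When one peak in set A spans two peaks in set B, the three intervals form
#' one component counted as a single A+B entry, so per-set component totals
#' are at most the raw per-set peak counts.
#'
#' @param sets named list of `GRanges` (at least 2).
#' @return list with `components` (a reduced `GRanges` of connected sites
#'   with a `sets` character column), `countsByCombination` (table of
#'   component counts per contributing-set combination, names like
#'   `"A+B"`), and `perSetTotal` (components touched by each set).
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 100), width = 50))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10, 120))
#' connectedOverlap(list(A = a, B = b))
#' @export
connectedOverlap <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 peak sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("set", seq_along(sets))
  ## min.gapwidth = 0: abutting half-open intervals share no base and must
  ## not be connected
  ## sets legitimately cover different chromosomes; silence the seqlevel
  ## mismatch notice when pooling
  pooled <- suppressWarnings(GenomicRanges::reduce(
    do.call(c, unname(lapply(sets, function(gr) {
      GenomicRanges::granges(gr)
    }))),
    min.gapwidth = 0L))
  membership <- vapply(sets, function(gr) {
    GenomicRanges::countOverlaps(pooled, gr) > 0
  }, logical(length(pooled)))
  if (length(pooled) == 1) membership <- matrix(membership, nrow = 1,
                                                dimnames = list(NULL,
                                                                names(sets)))
  labels <- apply(membership, 1, function(m)
    paste(names(sets)[m], collapse = "+"))
  pooled$sets <- labels
  list(components = pooled,
       countsByCombination = table(labels),
       perSetTotal = colSums(membership))
}

#' Occupancy ratio of bound copies to genomic sites
#'
#' @param boundCopies chromatin-bound copy number.
#' @param sitesTotal number of genomic sites (> 0).
#' @return list with `copiesPerSite`, `sitesPerCopy` and
#'   `boundFractionForFullOccupancy` (= sites/copies: the chromatin-bound
#'   fraction below which not all sites can be occupied simultaneously).
#' @examples
#' occupancyRatio(180000, 120000)
#' @export
occupancyRatio <- function(boundCopies, sitesTotal) {
  if (sitesTotal <= 0) stop("sitesTotal must be positive")
  list(copiesPerSite = boundCopies / sitesTotal,
       sitesPerCopy = sitesTotal / boundCopies,
       boundFractionForFullOccupancy = sitesTotal / boundCopies)
}

#' Loop-extrusion rate needed to form a loop within a residence time
#'
#' `rate = loopSize / residence`: the extrusion speed a dynamically bound
#' complex needs to extrude a loop of the given size within its chromatin
#' residence time (e.g. 185 kb / 13.7 min ~ 14 kb/min).
#'
#' @param loopSizeKb loop size (kb).
#' @param residenceMin residence time (min, > 0).
#' @return list with `raw` (kb/min) and `rounded` (nearest integer).
#' @examples
#' extrusionRate(185, 13.7)
#' @export
extrusionRate <- function(loopSizeKb, residenceMin) {
  if (residenceMin <= 0) stop("residence must be positive")
  raw <- loopSizeKb / residenceMin
  list(raw = raw, rounded = roundPaperStyle(raw, "integer"))
}

#' Average copies per chromosome
#'
#' @param totalCopies total copy number.
#' @param nChromosomes number of chromosomes (> 0); HeLa cells carry ~64.
#' @return list with `raw` and `rounded` (nearest hundred).
#' @examples
#' perChromosomeCopies(14000, 64)
#' @export
perChromosomeCopies <- function(totalCopies, nChromosomes) {
  if (nChromosomes <= 0) stop("nChromosomes must be positive")
  raw <- totalCopies / nChromosomes
  list(raw = raw, rounded = roundPaperStyle(raw, "hundred"))
}

#' Report-layer rounding
#'
#' Rounding used when quoting derived quantities (nearest thousand, hundred,
#' integer, or a number of decimals); raw values are always kept alongside.
#'
#' @param x numeric.
#' @param rule `"thousand"`, `"hundred"`, `"integer"`, or a non-negative
#'   integer number of decimals.
#' @return rounded numeric.
#' @examples
#' roundPaperStyle(117037, "thousand")
#' @export
roundPaperStyle <- function(x, rule = "integer") {
  if (is.numeric(rule)) return(round(x, rule))
  switch(match.arg(rule, c("thousand", "hundred", "integer")),
         thousand = round(x / 1000) * 1000,
         hundred = round(x / 100) * 100,
         integer = round(x))
}
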