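## Genomic occupancy arithmetic: scaling, spacing, connected overlaps.

grFrom <- function(df) GenomicRanges::GRanges(df$chrom,
                                              IRanges::IRanges(df$start,
                                                               df$end))

test_that("genome scaling extrapolates site counts linearly", {
  s1 <- scaleToGenome(40000, 2.7e9, 7.9e9)
  expect_equal(round(s1$raw), 117037)
  expect_equal(s1$rounded, 117000)
  s2 <- scaleToGenome(41000, 2.7e9, 7.9e9)
  expect_equal(round(s2$raw), 119963)
  expect_equal(s2$rounded, 120000)
  ## identity and linearity
  expect_equal(scaleToGenome(1234, 2.7e9, 2.7e9)$raw, 1234)
  expect_equal(scaleToGenome(80000, 2.7e9, 7.9e9)$raw, 2 * s1$raw)
  expect_error(scaleToGenome(10, 0, 1), "positive")
})

test_that("expected spacing is the uniform-coverage distance", {
  expect_equal(expectedSpacing(2.7e9, 40000), 67500)
  expect_equal(expectedSpacing(2.7e9, 1), 2.7e9)
  expect_equal(expectedSpacing(2.7e9, 80000), 67500 / 2)
})

test_that("spacing distribution matches brute-force consecutive distances", {
  df <- data.frame(chrom = "chr1",
                   start = c(1, 50001, 120001), end = c(1000, 51000,
                                                        121000))
  sp <- spacingDistribution(grFrom(df))
  expect_equal(sort(sp$distances), c(50000, 70000))
  expect_equal(sum(sp$distances < 1e5) / length(sp$distances), 1)

  ## one peak per chromosome: no distances
  dfSingle <- data.frame(chrom = c("chr1", "chr2"), start = c(1, 1),
                         end = c(100, 100))
  spSingle <- spacingDistribution(grFrom(dfSingle))
  expect_length(spSingle$distances, 0)
  expect_equal(spSingle$nSinglePeakChromosomes, 2)

  ## agreement with the O(n^2) nearest-successor oracle on random sets
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    start <- sort(sample.int(5e6, n))
    df2 <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                      start = start, end = start + 99)
    gr <- GenomicRanges::reduce(grFrom(df2))   # enforce non-overlap
    red <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr))
    expect_equal(sort(spacingDistribution(gr)$distances),
                 sort(bruteConsecutiveDistances(red)))
  }

  ## exponential spacings: fraction below 100 kb near the analytic CDF
  m <- spacingModel(parameters = list(mean = 67500), peakWidth = 1000,
                    chromSizes = c(chr1 = 80e6, chr2 = 80e6))
  sp2 <- spacingDistribution(simulatePeakSet(m, seed = 2))
  frac <- sum(sp2$distances < 1e5) / length(sp2$distances)
  expect_lt(abs(frac - (1 - exp(-100 / 67.5))), 0.04)
})

test_that("connected-overlap counting matches the interval-graph oracle", {
  ## identical sets: every component is shared
  a <- grFrom(data.frame(chrom = "chr1", start = c(1, 200, 400),
                         end = c(100, 300, 500)))
  ovAA <- connectedOverlap(list(A = a, B = a))
  expect_equal(length(ovAA$components), 3)
  expect_true(all(ovAA$components$sets == "A+B"))

  ## one A peak spanning two B peaks: a single connected entry
  aSpan <- grFrom(data.frame(chrom = "chr1", start = 10, end = 500))
  bTwo <- grFrom(data.frame(chrom = "chr1", start = c(20, 400),
                            end = c(120, 450)))
  ovSpan <- connectedOverlap(list(A = aSpan, B = bTwo))
  expect_equal(length(ovSpan$components), 1)
  expect_equal(unname(ovSpan$countsByCombination["A+B"]), 1L)
  expect_equal(unname(ovSpan$perSetTotal), c(1, 1))

  ## disjoint sets: additive counts, no shared label
  b <- grFrom(data.frame(chrom = "chr2", start = c(1, 200), end = c(50,
                                                                    250)))
  ovDisj <- connectedOverlap(list(A = a, B = b))
  expect_equal(length(ovDisj$components), 5)
  expect_equal(sort(unique(ovDisj$components$sets)), c("A", "B"))

  ## symmetry and idempotence
  sets <- asGRangesList(randomIntervalSets(3, seed = 99))
  o1 <- connectedOverlap(sets)
  o2 <- connectedOverlap(rev(sets))
  expect_equal(length(o1$components), length(o2$components))
  expect_equal(sort(unname(o1$perSetTotal)), sort(unname(o2$perSetTotal)))
  merged <- GenomicRanges::reduce(sets[[1]], min.gapwidth = 0L)
  oSelf <- connectedOverlap(list(X = merged, Y = merged))
  expect_equal(length(oSelf$components), length(merged))
  expect_true(all(oSelf$components$sets == "X+Y"))

  ## 100 random instances against the brute-force oracle
  for (seed in 1:100) {
    nSets <- 2 + seed %% 2
    dfs <- randomIntervalSets(nSets, seed = 1000 + seed)
    ov <- connectedOverlap(asGRangesList(dfs))
    pooledDf <- do.call(rbind, lapply(names(dfs), function(nm) {
      cbind(dfs[[nm]], set = nm)
    }))
    oracle <- bruteConnectedComponents(pooledDf)
    expect_equal(length(ov$components), oracle$nComponents)
    expect_equal(sort(unname(ov$components$sets)), oracle$combos)
  }
})

test_that("occupancy, extrusion-rate and per-chromosome arithmetic", {
  occ <- occupancyRatio(180000, 120000)
  expect_equal(round(occ$boundFractionForFullOccupancy, 2), 0.67)
  expect_equal(round(occupancyRatio(159437, 117037)$copiesPerSite, 2), 1.36)
  expect_equal(occupancyRatio(5, 5)$copiesPerSite, 1)

  ex <- extrusionRate(185, 13.7)
  expect_equal(round(ex$raw, 1), 13.5)
  expect_equal(ex$rounded, 14)
  expect_equal(round(extrusionRate(100, 13.7)$raw, 1), 7.3)
  expect_equal(extrusionRate(0, 10)$raw, 0)

  pc <- perChromosomeCopies(14000, 64)
  expect_equal(pc$raw, 218.75)
  expect_equal(pc$rounded, 200)
  expect_equal(perChromosomeCopies(64, 64)$raw, 1)
  expect_equal(round(perChromosomeCopies(14165, 64)$raw, 1), 221.3)
})

test_that("BED round trip preserves peaks and merges on load", {
  m <- spacingModel(parameters = list(mean = 50000), peakWidth = 800,
                    chromSizes = c(chr1 = 20e6))
  gr <- simulatePeakSet(m, seed = 3)
  f <- tempfile(fileext = ".bed")
  writePeakBed(gr, f)
  back <- readPeakBed(f)
  expect_equal(length(back), length(gr))
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
})
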