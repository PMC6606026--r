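## Independent brute-force oracles used across the test files. These stay
## deliberately naive (O(n^2), explicit loops) and share no code with the
## implementation they check.

## direct autocovariance G(k) = mean(dI_t dI_{t+k}) / mean(I)^2
bruteAutocorrelation <- function(trace, lagBins) {
  mu <- mean(trace)
  dI <- trace - mu
  n <- length(trace)
  vapply(lagBins, function(k) {
    acc <- 0
    for (t in seq_len(n - k)) acc <- acc + dI[t] * dI[t + k]
    acc / (n - k) / mu^2
  }, numeric(1))
}

## connected components of the interval-overlap graph.
## df: data.frame(chrom, start, end, set) in 1-based closed coordinates.
## Returns list(nComponents, combos = sorted character vector, one entry per
## component, sets joined by "+").
bruteConnectedComponents <- function(df) {
  n <- nrow(df)
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && df$chrom[i] == df$chrom[j] &&
        df$start[i] <= df$end[j] && df$start[j] <= df$end[i]) {
      ri <- findRoot(i); rj <- findRoot(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  combos <- vapply(split(df$set, roots), function(s)
    paste(sort(unique(s)), collapse = "+"), character(1))
  list(nComponents = length(unique(roots)),
       combos = sort(unname(combos)))
}

## consecutive nearest-successor midpoint distances per chromosome (O(n^2))
bruteConsecutiveDistances <- function(df) {
  out <- numeric(0)
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(sub) < 2) next
    mids <- (sub$start + sub$end) / 2
    for (i in seq_along(mids)) {
      larger <- mids[mids > mids[i]]
      if (length(larger)) out <- c(out, min(larger) - mids[i])
    }
  }
  out
}

## linear-interpolation percentile (type-7) computed from first principles
brutePercentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

## random peak-set instance for overlap tests (1-based closed coords)
randomIntervalSets <- function(nSets, seed) {
  set.seed(seed)
  sets <- lapply(seq_len(nSets), function(si) {
    n <- sample(4:25, 1)
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    start <- sample.int(5000, n, replace = TRUE)
    width <- sample.int(300, n, replace = TRUE)
    data.frame(chrom = chrom, start = start, end = start + width - 1)
  })
  names(sets) <- LETTERS[seq_len(nSets)]
  sets
}

asGRangesList <- function(sets) {
  lapply(sets, function(df)
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(df$start, df$end)))
}
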