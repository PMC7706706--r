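# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately avoid the vectorized code paths of the
# package (rle/cumsum/FFT) so that agreement is informative.

# Brute-force hot-spot caller: per-base state-machine scan for runs strictly
# above threshold, repeated pairwise merging until stable, then filtering.
# Consumes an already-smoothed vector; smoothing is tested separately against
# direct evaluation of the weight vector.
oracle_call_hotspots <- function(values, smoothed, threshold,
                                 merge_gap, min_width, min_total) {
  n <- length(smoothed)
  starts <- integer(0); ends <- integer(0)
  run_start <- NA_integer_
  for (i in seq_len(n)) {
    if (smoothed[i] > threshold) {
      if (is.na(run_start)) run_start <- i
      if (i == n) { starts <- c(starts, run_start); ends <- c(ends, i) }
    } else if (!is.na(run_start)) {
      starts <- c(starts, run_start); ends <- c(ends, i - 1L)
      run_start <- NA_integer_
    }
  }
  # pairwise merge until no adjacent pair is mergeable (=> transitive)
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(starts)) {
      if (starts[i + 1L] - ends[i] - 1L <= merge_gap) {
        ends[i] <- ends[i + 1L]
        starts <- starts[-(i + 1L)]
        ends <- ends[-(i + 1L)]
        merged <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!merged) break
  }
  keep <- logical(length(starts))
  totals <- numeric(length(starts))
  for (i in seq_along(starts)) {
    totals[i] <- 0
    for (p in starts[i]:ends[i]) totals[i] <- totals[i] + values[p]
    keep[i] <- (ends[i] - starts[i] + 1L >= min_width) &&
      (totals[i] >= min_total)
  }
  data.frame(start = starts[keep], end = ends[keep],
             total_signal = totals[keep])
}

# Direct (non-FFT) evaluation of truncated, renormalized Hann smoothing.
oracle_hann_smooth <- function(x, w) {
  wt <- (1 - cos(2 * pi * (seq_len(w) - 1) / (w - 1))) / 2
  wt <- wt / sum(wt)
  h <- (w - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    k <- seq.int(i - h, i + h)
    ok <- k >= 1 & k <= n
    sum(wt[ok] * x[k[ok]]) / sum(wt[ok])
  }, numeric(1))
}

# One-chromosome assembly without the ceremony.
mini_assembly <- function(len = 100000L, rdna = NULL, cen = NULL,
                          copy_number = 2L) {
  if (is.null(rdna)) rdna <- list(chrom = "chrT", start = 1, end = 1)
  if (is.null(cen)) cen <- round(len / 2)
  genome_assembly("chrT", len, cen, copy_number, rdna = rdna)
}

# Map with a single chromosome holding the given values.
mini_map <- function(values, assembly = mini_assembly(length(values)),
                     state = "RPM") {
  signal_map(list(chrT = values), assembly, state = state)
}

# Random spiky map fixture on one chromosome: scattered hot blocks over a low
# background, in raw count units.
random_spiky_values <- function(len, n_blocks = 15) {
  v <- rpois(len, 0.02)
  for (b in seq_len(n_blocks)) {
    w <- sample(10:400, 1)
    s <- sample.int(len - w, 1)
    v[s:(s + w - 1)] <- v[s:(s + w - 1)] + rpois(w, runif(1, 0.5, 8))
  }
  as.numeric(v)
}
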