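#' Hann-window smoothing of a per-base signal
#'
#' Convolves the signal with a normalized Hann (raised-cosine) window of odd
#' width `window_bp`. At chromosome ends the window is truncated and
#' re-normalized over the in-bounds positions, so a constant signal is exactly
#' preserved everywhere.
#'
#' @param values numeric per-base vector.
#' @param window_bp odd window width in bp (>= 3).
#' @return numeric vector of smoothed per-base density, same length.
#' @export
hann_smooth <- function(values, window_bp = 201L) {
  w <- as.integer(window_bp)
  if (w %% 2L == 0L || w < 3L)
    stop("window_bp must be odd and >= 3")
  n <- length(values)
  if (n == 0) return(numeric(0))
  wt <- hann_window(w)
  h <- (w - 1L) %/% 2L
  if (n == 1) return(values)
  # numerator: full linear convolution via FFT (window is symmetric)
  m <- stats::nextn(n + w - 1L)
  fx <- stats::fft(c(values, numeric(m - n)))
  fw <- stats::fft(c(wt, numeric(m - w)))
  conv <- Re(stats::fft(fx * fw, inverse = TRUE)) / m
  num <- conv[h + seq_len(n)]
  # denominator: in-bounds weight mass, exact via cumulative sums
  cw <- c(0, cumsum(wt))
  hi <- pmin(w, n - seq_len(n) + 1L + h)
  lo <- pmax(0L, h - seq_len(n) + 1L)
  den <- cw[hi + 1L] - cw[lo + 1L]
  num / den
}

hann_window <- function(w) {
  k <- seq_len(w) - 1L
  wt <- (1 - cos(2 * pi * k / (w - 1))) / 2
  wt / sum(wt)
}

#' Hot-spot calling parameters
#'
#' Defaults follow the standard Spo11-oligo hot-spot definition: smooth with a
#' 201-bp Hann window, call bases whose smoothed density is strictly greater
#' than 2.3-fold the genome-average density (or a fixed absolute threshold in
#' RPM/bp when supplied), merge calls separated by <= 200 bp, then drop calls
#' that are < 25 bp wide or contain < 10 RPM total.
#'
#' @param window_bp odd smoothing window (default 201).
#' @param fold_over_mean threshold as fold over the map's genome-average
#'   density (default 2.3).
#' @param fixed_threshold absolute density threshold in RPM/bp; overrides
#'   `fold_over_mean` when non-`NULL` (0.193 gives parity with published
#'   sacCer2 calls).
#' @param merge_gap_bp maximum gap merged (default 200).
#' @param min_width_bp minimum retained width (default 25).
#' @param min_total minimum retained total signal (default 10).
#' @return An object of class `hotspot_params`.
#' @export
hotspot_params <- function(window_bp = 201L, fold_over_mean = 2.3,
                           fixed_threshold = NULL, merge_gap_bp = 200L,
                           min_width_bp = 25L, min_total = 10) {
  stopifnot(window_bp > 0, fold_over_mean > 0, merge_gap_bp >= 0,
            min_width_bp > 0, min_total > 0)
  if (as.integer(window_bp) %% 2L == 0L)
    stop("window_bp must be odd")
  if (!is.null(fixed_threshold) && fixed_threshold <= 0)
    stop("fixed_threshold must be > 0")
  structure(list(window_bp = as.integer(window_bp),
                 fold_over_mean = fold_over_mean,
                 fixed_threshold = fixed_threshold,
                 merge_gap_bp = as.integer(merge_gap_bp),
                 min_width_bp = as.integer(min_width_bp),
                 min_total = min_total),
            class = "hotspot_params")
}

new_hotspot_set <- function(df, params = NULL, threshold = NA_real_) {
  rownames(df) <- NULL
  structure(df, params = params, threshold = threshold,
            class = c("hotspot_set", "data.frame"))
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("Hot-spot set: %d hot spots on %d chromosome(s)",
              nrow(x), length(unique(x$chrom))))
  if (!is.na(attr(x, "threshold")))
    cat(sprintf(" (threshold %.4g per bp)", attr(x, "threshold")))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Call DSB hot spots on a normalized map
#'
#' Candidate hot spots are maximal runs of bases whose Hann-smoothed density
#' strictly exceeds the threshold; candidates separated by at most
#' `merge_gap_bp` are merged (transitively), then candidates narrower than
#' `min_width_bp` or containing less than `min_total` summed raw signal are
#' removed. The reported `total_signal` sums the raw (unsmoothed) map inside
#' each interval; `peak_smoothed` is the maximum smoothed density inside.
#'
#' @param map a [signal_map()] in `RPM` or `NRPM` state.
#' @param assembly defaults to the map's own assembly.
#' @param params a [hotspot_params()].
#' @return A `hotspot_set`: data frame with columns `chrom`, `start`, `end`
#'   (1-based closed), `width`, `total_signal`, `peak_smoothed`, sorted and
#'   non-overlapping, with the calling parameters and realized threshold as
#'   attributes. An empty map yields an empty set.
#' @export
call_hotspots <- function(map, assembly = map$assembly,
                          params = hotspot_params()) {
  if (map$state == "RAW")
    stop("call_hotspots expects a normalized (RPM/NRPM) map")
  threshold <- params$fixed_threshold
  if (is.null(threshold))
    threshold <- params$fold_over_mean *
      map_total(map, mask_rdna = TRUE) / included_genome_length(assembly)
  res <- lapply(assembly$chroms$chrom, function(ch) {
    v <- map$values[[ch]]
    sm <- hann_smooth(v, params$window_bp)
    runs <- runs_above(sm, threshold)
    if (nrow(runs) == 0) return(NULL)
    merged <- merge_runs(runs, params$merge_gap_bp)
    cs <- c(0, cumsum(v))
    total <- cs[merged$end + 1] - cs[merged$start]
    width <- merged$end - merged$start + 1L
    keep <- width >= params$min_width_bp & total >= params$min_total
    if (!any(keep)) return(NULL)
    merged <- merged[keep, , drop = FALSE]
    peak <- vapply(seq_len(nrow(merged)), function(i)
      max(sm[merged$start[i]:merged$end[i]]), numeric(1))
    data.frame(chrom = ch, start = merged$start, end = merged$end,
               width = width[keep], total_signal = total[keep],
               peak_smoothed = peak, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, res)
  if (is.null(df))
    df <- data.frame(chrom = character(), start = integer(), end = integer(),
                     width = integer(), total_signal = numeric(),
                     peak_smoothed = numeric(), stringsAsFactors = FALSE)
  new_hotspot_set(df, params = params, threshold = threshold)
}

# maximal runs with value strictly greater than threshold
runs_above <- function(x, threshold) {
  above <- x > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# transitively merge runs whose gap (bases strictly between) <= gap_bp
merge_runs <- function(runs, gap_bp) {
  if (nrow(runs) <= 1) return(runs)
  gap <- runs$start[-1] - runs$end[-nrow(runs)] - 1L
  grp <- cumsum(c(0L, as.integer(gap > gap_bp)))
  data.frame(start = as.integer(tapply(runs$start, grp, min)),
             end = as.integer(tapply(runs$end, grp, max)))
}

#' Compare two hot-spot sets
#'
#' Two hot spots are shared when their intervals intersect by at least 1 bp.
#' Counts are reported from both directions (a hot spot in one set can
#' overlap several in the other).
#'
#' @param set_a,set_b `hotspot_set` objects on the same assembly.
#' @return list with `n_shared_a` (a-hotspots overlapping any b),
#'   `n_shared_b`, `n_only_a`, `n_only_b`, and `pairing`, a data frame of
#'   overlapping index pairs (`ia`, `ib`).
#' @export
compare_hotspot_sets <- function(set_a, set_b) {
  na <- nrow(set_a); nb <- nrow(set_b)
  hit_a <- logical(na); hit_b <- logical(nb)
  pairs <- list()
  for (ch in unique(c(set_a$chrom, set_b$chrom))) {
    ia <- which(set_a$chrom == ch)
    ib <- which(set_b$chrom == ch)
    if (!length(ia) || !length(ib)) next
    for (i in ia) {
      j <- ib[set_b$start[ib] <= set_a$end[i] &
              set_b$end[ib] >= set_a$start[i]]
      if (length(j)) {
        hit_a[i] <- TRUE
        hit_b[j] <- TRUE
        pairs[[length(pairs) + 1L]] <- data.frame(ia = i, ib = j)
      }
    }
  }
  pairing <- if (length(pairs)) do.call(rbind, pairs)
             else data.frame(ia = integer(), ib = integer())
  list(n_shared_a = sum(hit_a), n_shared_b = sum(hit_b),
       n_only_a = na - sum(hit_a), n_only_b = nb - sum(hit_b),
       pairing = pairing)
}

#' Per-hotspot fold change between two maps
#'
#' Sums each map inside every hot spot and reports the ratio
#' numerator/denominator together with the hot-spot midpoint, plus a
#' tricube-weighted local-regression (loess) trend over midpoints per
#' chromosome. Hot spots with zero denominator signal are flagged and
#' excluded from the trend, never silently dropped. Maps must already be
#' comparably scaled ([cross_scale()] and/or [apply_global_scale()]).
#'
#' @param hotspots a `hotspot_set`.
#' @param map_num,map_den numerator and denominator [signal_map()]s.
#' @param span loess span (default 0.5).
#' @return data frame with columns `chrom`, `midpoint`, `ratio`,
#'   `num_total`, `den_total`, `flagged`, `trend`.
#' @export
hotspot_fold_change <- function(hotspots, map_num, map_den, span = 0.5) {
  if (nrow(hotspots) == 0)
    return(data.frame(chrom = character(), midpoint = numeric(),
                      ratio = numeric(), num_total = numeric(),
                      den_total = numeric(), flagged = logical(),
                      trend = numeric()))
  sum_in <- function(map, ch, s, e) sum(map$values[[ch]][s:e])
  num <- mapply(sum_in, ch = hotspots$chrom, s = hotspots$start,
                e = hotspots$end, MoreArgs = list(map = map_num))
  den <- mapply(sum_in, ch = hotspots$chrom, s = hotspots$start,
                e = hotspots$end, MoreArgs = list(map = map_den))
  flagged <- den == 0
  ratio <- ifelse(flagged, NA_real_, num / den)
  mid <- floor((hotspots$start + hotspots$end) / 2)
  out <- data.frame(chrom = hotspots$chrom, midpoint = mid, ratio = ratio,
                    num_total = num, den_total = den, flagged = flagged,
                    trend = NA_real_, stringsAsFactors = FALSE)
  for (ch in unique(out$chrom)) {
    i <- which(out$chrom == ch & !out$flagged)
    # a loess fit needs appreciably more points than its local df; fall
    # back to the group mean on very sparse chromosomes
    if (length(i) >= max(10, ceiling(4 / span))) {
      fit <- tryCatch(
        stats::loess(ratio ~ midpoint, data = out[i, ], span = span,
                     degree = 2, family = "gaussian"),
        error = function(e) NULL)
      if (!is.null(fit))
        out$trend[i] <- stats::predict(fit, newdata = out[i, ])
    } else if (length(i) > 0) {
      out$trend[i] <- mean(out$ratio[i])
    }
  }
  rownames(out) <- NULL
  out
}

#' Write a hot-spot set as BED
#'
#' Internal 1-based closed intervals are converted to BED 0-based half-open
#' (`start - 1`, `end`). Column 5 carries the BED-convention integer score
#' (total signal scaled to 0-1000 over the set); the exact `total_signal` is
#' preserved at full precision in column 6.
#'
#' @param set a `hotspot_set`, sorted and non-overlapping per chromosome.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hotspots <- function(set, path) {
  for (ch in unique(set$chrom)) {
    i <- which(set$chrom == ch)
    if (is.unsorted(set$start[i]))
      stop("hot spots must be sorted per chromosome")
    if (length(i) > 1 &&
        any(set$start[i][-1] <= set$end[i][-length(i)]))
      stop("integrity error: overlapping hot spots on ", ch)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("track name=hotspots description=\"DSB hot spots\"", con)
  if (nrow(set)) {
    smax <- max(set$total_signal)
    score <- if (smax > 0) as.integer(round(1000 * set$total_signal / smax))
             else rep(0L, nrow(set))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%.17g",
                       set$chrom, as.integer(set$start) - 1L,
                       as.integer(set$end),
                       sprintf("hs_%s_%d", set$chrom,
                               stats::ave(seq_len(nrow(set)), set$chrom,
                                          FUN = seq_along)),
                       score, set$total_signal), con)
  }
  invisible(path)
}

#' Read a hot-spot BED file written by [write_hotspots()]
#'
#' @param path BED file path.
#' @return A `hotspot_set` with internal 1-based closed coordinates and the
#'   exact total signal recovered from column 6.
#' @export
read_hotspots <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#|browser)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(new_hotspot_set(data.frame(
      chrom = character(), start = integer(), end = integer(),
      width = integer(), total_signal = numeric(),
      peak_smoothed = numeric(), stringsAsFactors = FALSE)))
  f <- strsplit(lines, "\t")
  if (any(lengths(f) < 6))
    stop("format error: hotspot BED lines need 6 fields")
  start <- as.integer(vapply(f, `[`, character(1), 2)) + 1L
  end <- as.integer(vapply(f, `[`, character(1), 3))
  new_hotspot_set(data.frame(
    chrom = vapply(f, `[`, character(1), 1),
    start = start, end = end, width = end - start + 1L,
    total_signal = as.numeric(vapply(f, `[`, character(1), 6)),
    peak_smoothed = NA_real_, stringsAsFactors = FALSE))
}
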