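#' Sub-chromosomal domain classification
#'
#' Classifies an interval by its midpoint into one of the canonical domains of
#' the meiotic DSB landscape. Two schemes:
#'
#' * `"fig_domains"` (`TEL`/`CEN`/`RDNA`/`INTERSTITIAL`): `TEL` within 20 kb
#'   of a telomere, `CEN` within 10 kb of a centromere midpoint, `RDNA` from
#'   60 kb left of the rDNA interval to 30 kb right of it (rDNA chromosome
#'   only), everything else `INTERSTITIAL`.
#' * `"ear"`: additionally labels `EAR` (end-adjacent region) for midpoints
#'   more than 20 kb and at most 110 kb from the nearer telomere, applied
#'   after `TEL` (so the 20-kb boundary itself belongs to `TEL`).
#'
#' Precedence is TEL > (EAR) > CEN > RDNA > INTERSTITIAL, so classification
#' is total: every in-bounds interval gets exactly one label.
#'
#' @param chrom,start,end interval (1-based closed); vectors recycle.
#' @param assembly a [genome_assembly()].
#' @param scheme `"fig_domains"` or `"ear"`.
#' @return character vector of domain labels.
#' @export
classify_interval <- function(chrom, start, end, assembly,
                              scheme = c("fig_domains", "ear")) {
  scheme <- match.arg(scheme)
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  i <- chrom_index(assembly, chrom)
  L <- assembly$chroms$length[i]
  cen <- assembly$chroms$cen_mid[i]
  if (any(start < 1 | end > L | start > end))
    stop("interval outside chromosome bounds")
  mid <- floor((start + end) / 2)
  tel_dist <- pmin(mid, L - mid + 1)
  rd <- assembly$rdna
  in_rdna <- chrom == rd$chrom &
    mid >= (rd$start - 60e3) & mid <= (rd$end + 30e3)
  out <- rep("INTERSTITIAL", n)
  out[in_rdna] <- "RDNA"
  out[abs(mid - cen) <= 10e3] <- "CEN"
  if (scheme == "ear")
    out[tel_dist > 20e3 & tel_dist <= 110e3] <- "EAR"
  out[tel_dist <= 20e3] <- "TEL"
  out
}

#' Domain-wise distribution of per-hotspot fold changes
#'
#' Groups [hotspot_fold_change()] ratios by domain class and summarizes each
#' class with the median, interquartile range and Tukey whiskers (most
#' extreme points within 1.5 x IQR of the box); points beyond the whiskers
#' are outliers. Empty domains are reported with count 0.
#'
#' @param hotspots a `hotspot_set`.
#' @param map_num,map_den comparably scaled [signal_map()]s.
#' @param assembly defaults to the numerator map's assembly.
#' @param scheme passed to [classify_interval()].
#' @param span loess span for the underlying fold-change trend.
#' @return list with `per_hotspot` (fold-change table plus `domain` column)
#'   and `summary` (one row per domain: `n`, `median`, `q1`, `q3`, `iqr`,
#'   `whisker_lo`, `whisker_hi`, `n_outliers`).
#' @export
domain_fold_change <- function(hotspots, map_num, map_den,
                               assembly = map_num$assembly,
                               scheme = "fig_domains", span = 0.5) {
  fc <- hotspot_fold_change(hotspots, map_num, map_den, span = span)
  fc$domain <- if (nrow(fc)) classify_interval(hotspots$chrom,
                                               hotspots$start, hotspots$end,
                                               assembly, scheme)
               else character(0)
  classes <- c("TEL", if (scheme == "ear") "EAR", "CEN", "RDNA",
               "INTERSTITIAL")
  summ <- do.call(rbind, lapply(classes, function(cl) {
    r <- fc$ratio[fc$domain == cl & !fc$flagged]
    r <- r[!is.na(r)]
    if (!length(r))
      return(data.frame(domain = cl, n = 0L, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_, iqr = NA_real_,
                        whisker_lo = NA_real_, whisker_hi = NA_real_,
                        n_outliers = 0L, stringsAsFactors = FALSE))
    q <- stats::quantile(r, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    data.frame(domain = cl, n = length(r), median = q[2], q1 = q[1],
               q3 = q[3], iqr = iqr,
               whisker_lo = min(r[r >= lo_fence]),
               whisker_hi = max(r[r <= hi_fence]),
               n_outliers = sum(r < lo_fence | r > hi_fence),
               stringsAsFactors = FALSE)
  }))
  list(per_hotspot = fc, summary = summ)
}

#' Correlation between chromosome length and DSB density
#'
#' Pearson product-moment correlation between chromosome length and
#' per-chromosome signal density, the classic negative size-vs-density
#' relation of the wild-type DSB landscape. Named chromosomes can be excluded
#' (e.g. a focal aneuploid chromosome).
#'
#' @param summaries per-chromosome table from [per_chromosome_totals()]
#'   (needs columns `chrom`, `length`, `density`).
#' @param exclude chromosome names to drop before correlating.
#' @return Pearson's r (numeric scalar).
#' @export
size_density_correlation <- function(summaries, exclude = NULL) {
  tab <- summaries[!summaries$chrom %in% exclude, ]
  if (nrow(tab) < 3)
    stop("need at least 3 chromosomes to correlate")
  if (stats::sd(tab$length) == 0 || stats::sd(tab$density) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(tab$length, tab$density, method = "pearson")
}
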