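#' Simulation scenarios
#'
#' A `sim_scenario` bundles everything the synthetic-data generator needs to
#' emulate hot-spot-structured Spo11-oligo count maps: the assembly (with
#' per-chromosome copy numbers), hot-spot density and heavy-tailed intensity
#' law, background fraction, a focal chromosome whose DSB output follows a
#' time-indexed fold-boost schedule (modeling time-dependent overrepresentation
#' on engagement-defective chromosomes), optional domain modulation, and the
#' sequencing depth per time point.
#'
#' @param assembly a [genome_assembly()]; its `copy_number` column multiplies
#'   expected chromosome weight (diploid baseline 2).
#' @param focal_chrom chromosome carrying the fold-boost schedule, or `NULL`.
#' @param fold_schedule named numeric vector, names = time points in hours,
#'   values = multiplicative boosts of the focal chromosome (all > 0).
#' @param hotspot_density_per_kb expected hot spots per kb (default 0.3,
#'   about 3,600 genome-wide on a 12-Mb genome, the scale seen in yeast
#'   Spo11-oligo maps).
#' @param intensity_shape,intensity_scale gamma law of hot-spot intensities;
#'   the default shape 0.6 gives the heavy-tailed strength spectrum of real
#'   hot-spot maps.
#' @param background_fraction fraction of reads falling uniformly outside
#'   hot spots (default 0.15).
#' @param width_range hot-spot width law, uniform on this bp range.
#' @param reads_per_timepoint sequencing depth per simulated map.
#' @param domain_factors optional named multipliers per domain class
#'   (`TEL`, `EAR`, `CEN`, `RDNA`, `INTERSTITIAL`) applied to hot-spot
#'   weights, classified under the `"ear"` scheme.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(assembly,
                         focal_chrom = NULL,
                         fold_schedule = c("4" = 1),
                         hotspot_density_per_kb = 0.3,
                         intensity_shape = 0.6,
                         intensity_scale = 1,
                         background_fraction = 0.15,
                         width_range = c(50, 500),
                         reads_per_timepoint = 1e6,
                         domain_factors = NULL) {
  stopifnot(hotspot_density_per_kb >= 0, intensity_shape > 0,
            intensity_scale > 0,
            background_fraction >= 0, background_fraction < 1,
            length(width_range) == 2, width_range[1] >= 1,
            width_range[1] <= width_range[2],
            reads_per_timepoint >= 1)
  if (any(fold_schedule <= 0))
    stop("fold schedule must be positive")
  if (!is.null(focal_chrom)) chrom_index(assembly, focal_chrom)
  if (!is.null(domain_factors) && any(domain_factors < 0))
    stop("domain factors must be >= 0")
  structure(list(assembly = assembly, focal_chrom = focal_chrom,
                 fold_schedule = fold_schedule,
                 hotspot_density_per_kb = hotspot_density_per_kb,
                 intensity_shape = intensity_shape,
                 intensity_scale = intensity_scale,
                 background_fraction = background_fraction,
                 width_range = width_range,
                 reads_per_timepoint = reads_per_timepoint,
                 domain_factors = domain_factors),
            class = "sim_scenario")
}

# evaluate code with a local, restored RNG stream
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (is.null(old)) {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    } else {
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

schedule_fold <- function(scenario, time_point) {
  if (is.null(scenario$focal_chrom)) return(1)
  sched <- scenario$fold_schedule
  i <- match(as.character(time_point), names(sched))
  if (is.na(i))
    stop("time point ", time_point, " not in the fold schedule")
  unname(sched[i])
}

#' Draw a ground-truth hot-spot set
#'
#' Places non-overlapping hot spots (uniform widths in the scenario's range)
#' along every chromosome at the scenario's density and draws i.i.d. gamma
#' intensities. The construction distributes the free (non-hot-spot) bases as
#' random gaps, so placement cannot overlap by construction and fails with an
#' explicit error when the density is too high to fit.
#'
#' @param scenario a [sim_scenario()].
#' @param seed mandatory integer seed.
#' @return data frame of class `hotspot_truth` with columns `chrom`, `start`,
#'   `end`, `width`, `intensity`.
#' @export
simulate_truth <- function(scenario, seed) {
  stopifnot(!missing(seed))
  asm <- scenario$assembly
  with_local_seed(seed, {
    res <- lapply(seq_len(nrow(asm$chroms)), function(i) {
      ch <- asm$chroms$chrom[i]
      L <- asm$chroms$length[i]
      n <- round(scenario$hotspot_density_per_kb * L / 1000)
      if (n == 0)
        return(NULL)
      widths <- scenario$width_range[1] - 1L +
        sample.int(scenario$width_range[2] - scenario$width_range[1] + 1L,
                   n, replace = TRUE)
      free <- L - sum(widths)
      if (free < 0)
        stop("hot-spot density too high to place without overlap on ", ch)
      cuts <- sort(sample.int(free + 1, n, replace = TRUE)) - 1L
      starts <- cuts + cumsum(c(0L, widths[-n])) + 1L
      data.frame(chrom = ch, start = starts, end = starts + widths - 1L,
                 width = widths,
                 intensity = stats::rgamma(n, shape = scenario$intensity_shape,
                                           scale = scenario$intensity_scale),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, res)
    if (is.null(df))
      df <- data.frame(chrom = character(), start = integer(),
                       end = integer(), width = integer(),
                       intensity = numeric(), stringsAsFactors = FALSE)
    rownames(df) <- NULL
    structure(df, class = c("hotspot_truth", "data.frame"))
  })
}

#' Simulate a raw Spo11-oligo count map
#'
#' Allocates the scenario's read budget multinomially over the truth hot
#' spots plus a uniform per-chromosome background. Expected hot-spot weight is
#' intensity x (copy number / 2) x focal fold at `time_point` x optional
#' domain factor; within a hot spot reads follow a triangular (center-peaked)
#' profile. Background weight is proportional to chromosome length with the
#' same copy-number/focal multipliers, and carries `background_fraction` of
#' the total expected mass.
#'
#' @param truth output of [simulate_truth()].
#' @param scenario the same [sim_scenario()].
#' @param time_point hours; must appear in the fold schedule (ignored when
#'   there is no focal chromosome).
#' @param seed mandatory integer seed.
#' @return A [signal_map()] in `RAW` state.
#' @export
simulate_map <- function(truth, scenario, time_point, seed) {
  stopifnot(!missing(seed))
  asm <- scenario$assembly
  fold <- schedule_fold(scenario, time_point)
  chroms <- asm$chroms$chrom
  cw <- asm$chroms$copy_number / 2
  names(cw) <- chroms
  focal_mult <- function(ch) {
    if (is.null(scenario$focal_chrom)) return(rep(1, length(ch)))
    ifelse(ch == scenario$focal_chrom, fold, 1)
  }
  hs_w <- numeric(0)
  if (nrow(truth)) {
    hs_w <- truth$intensity * cw[truth$chrom] * focal_mult(truth$chrom)
    if (!is.null(scenario$domain_factors)) {
      dom <- classify_interval(truth$chrom, truth$start, truth$end, asm,
                               scheme = "ear")
      f <- scenario$domain_factors[dom]
      f[is.na(f)] <- 1
      hs_w <- hs_w * f
    }
  }
  bg_w <- asm$chroms$length * cw * focal_mult(chroms)
  tot_hs <- sum(hs_w)
  bf <- scenario$background_fraction
  bg_mass <- if (tot_hs > 0) bf / (1 - bf) * tot_hs else sum(bg_w)
  bg_w <- if (sum(bg_w) > 0) bg_w / sum(bg_w) * bg_mass else bg_w
  wts <- c(hs_w, bg_w)
  if (sum(wts) <= 0)
    stop("zero total weight: nothing to simulate")
  with_local_seed(seed, {
    counts <- stats::rmultinom(1, size = scenario$reads_per_timepoint,
                               prob = wts)[, 1]
    nh <- length(hs_w)
    pos_by_chrom <- lapply(chroms, function(ch) integer(0))
    names(pos_by_chrom) <- chroms
    if (nh) {
      for (i in seq_len(nh)) {
        ni <- counts[i]
        if (ni == 0) next
        w <- truth$width[i]
        prof <- pmin(seq_len(w), w + 1L - seq_len(w))
        off <- sample.int(w, ni, replace = TRUE, prob = prof)
        ch <- truth$chrom[i]
        pos_by_chrom[[ch]] <- c(pos_by_chrom[[ch]],
                                truth$start[i] + off - 1L)
      }
    }
    for (j in seq_along(chroms)) {
      nb <- counts[nh + j]
      if (nb == 0) next
      ch <- chroms[j]
      pos_by_chrom[[ch]] <- c(pos_by_chrom[[ch]],
                              sample.int(asm$chroms$length[j], nb,
                                         replace = TRUE))
    }
    values <- lapply(chroms, function(ch)
      as.numeric(tabulate(pos_by_chrom[[ch]],
                          nbins = chrom_length(asm, ch))))
    names(values) <- chroms
    signal_map(values, asm, state = "RAW")
  })
}

#' Simulate a PFGE DSB-frequency time course
#'
#' Evaluates the log-normal DSB-timing curve at the grid and adds Gaussian
#' noise (clamped at zero, since measured fractions are non-negative).
#'
#' @param a,b,c,d log-normal curve parameters (`d > 0`).
#' @param sigma Gaussian noise SD (0 reproduces the model exactly).
#' @param grid time grid in hours.
#' @param seed integer seed (required when `sigma > 0`).
#' @param label series label.
#' @return A [time_course()].
#' @export
simulate_pfge_timecourse <- function(a, b, c, d, sigma = 0,
                                     grid = c(0, 1, 2, 2.5, 3, 3.5, 4, 4.5,
                                              5, 5.5, 6, 7),
                                     seed = NULL, label = "sim_pfge") {
  stopifnot(d > 0, sigma >= 0)
  if (sigma > 0 && is.null(seed))
    stop("a seed is required for noisy simulation")
  y <- lognormal_peak(grid, a, b, c, d)
  with_local_seed(seed, {
    if (sigma > 0) y <- y + stats::rnorm(length(grid), 0, sigma)
    time_course(grid, pmax(y, 0), label = label)
  })
}

#' Simulate a ChIP-qPCR binding time course
#'
#' Rise-plateau-fall profile built as the product of an increasing and a
#' decreasing logistic: `L * plogis(k_rise (t - t_assoc)) *
#' plogis(-k_fall (t - t_dissoc))`, plus Gaussian noise clamped at zero.
#'
#' @param t_assoc,t_dissoc association/dissociation times in hours
#'   (`t_assoc < t_dissoc`).
#' @param L plateau amplitude (percent of input).
#' @param k_rise,k_fall logistic steepness of the two slopes (per hour).
#' @param sigma Gaussian noise SD.
#' @param grid time grid in hours (default: the 12-point ChIP sampling grid).
#' @param seed integer seed (required when `sigma > 0`).
#' @param label series label.
#' @return A [time_course()].
#' @export
simulate_chip_timecourse <- function(t_assoc, t_dissoc, L = 2,
                                     k_rise = 4, k_fall = 4, sigma = 0,
                                     grid = c(0, 1, 2, 2.5, 3, 3.5, 4, 4.5,
                                              5, 5.5, 6, 7),
                                     seed = NULL, label = "sim_chip") {
  stopifnot(t_assoc < t_dissoc, L > 0, k_rise > 0, k_fall > 0, sigma >= 0)
  if (sigma > 0 && is.null(seed))
    stop("a seed is required for noisy simulation")
  y <- L * stats::plogis(k_rise * (grid - t_assoc)) *
    stats::plogis(-k_fall * (grid - t_dissoc))
  with_local_seed(seed, {
    if (sigma > 0) y <- y + stats::rnorm(length(grid), 0, sigma)
    time_course(grid, pmax(y, 0), label = label)
  })
}
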