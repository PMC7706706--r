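#' Reads-per-million normalization with rDNA masking
#'
#' Scales a raw count map so that the total over nuclear chromosomes, with the
#' rDNA interval zeroed, equals one million (RPM). The rDNA interval is zeroed
#' in the output, so the plain map total equals 1e6 as well; relative per-base
#' proportions outside the masked region are preserved. Reads on excluded
#' sequences (mitochondrial DNA, 2-micron plasmid) never enter a `signal_map`
#' and so are excluded by construction.
#'
#' @param map a [signal_map()] in `RAW` state.
#' @param assembly assembly to normalize against; defaults to the map's own.
#' @return A [signal_map()] in `RPM` state.
#' @export
rpm_normalize <- function(map, assembly = map$assembly) {
  if (map$state != "RAW")
    stop("rpm_normalize expects a RAW map, got ", map$state)
  total <- map_total(map, mask_rdna = TRUE)
  if (total <= 0)
    stop("empty map: no included signal to normalize")
  out <- mask_rdna(map)
  out$values <- lapply(out$values, function(v) v * (1e6 / total))
  out$state <- "RPM"
  out
}

#' Copy-number correction schemes
#'
#' Describes how to correct a map for chromosome copy number. Two modes:
#' multiplicative `factor` mode (e.g. a trisomic chromosome in a diploid
#' baseline gets factor 2/3; a single-copy chromosome gets factor 2), and
#' `sum` mode for a homeologous pair, where the partner chromosome's reads
#' (mapped to its own sequence, supplied as `partner_map` to
#' [correct_copy_number()]) are added to the native copy's total.
#'
#' @param factors named numeric vector of per-chromosome multiplicative
#'   factors (chromosomes not named get factor 1). All factors must be > 0.
#' @param sum_chrom chromosome whose total should absorb the partner map's
#'   reads (`sum` mode); `NULL` for pure factor mode.
#' @return An object of class `copy_scheme`.
#' @seealso [copy_factors()] to derive factors from assembly copy numbers.
#' @export
copy_scheme <- function(factors = numeric(), sum_chrom = NULL) {
  factors <- unlist(factors)
  if (length(factors) && (is.null(names(factors)) || any(!nzchar(names(factors)))))
    stop("factors must be a named vector (chromosome = factor)")
  if (any(factors <= 0))
    stop("copy-correction factors must be > 0")
  structure(list(factors = factors, sum_chrom = sum_chrom),
            class = "copy_scheme")
}

#' Derive copy-correction factors from assembly copy numbers
#'
#' With a diploid baseline, a chromosome present in `k` copies gets the
#' multiplicative factor `2/k` (trisomic: 2/3; monosomic: 2).
#'
#' @param assembly a [genome_assembly()].
#' @return A [copy_scheme()] with factors for every non-disomic chromosome.
#' @export
copy_factors <- function(assembly) {
  cn <- assembly$chroms$copy_number
  odd <- which(cn != 2L)
  f <- 2 / cn[odd]
  names(f) <- assembly$chroms$chrom[odd]
  copy_scheme(factors = f)
}

#' Correct a normalized map for chromosome copy number
#'
#' In factor mode, per-base values of each named chromosome are multiplied by
#' its factor (all other chromosomes untouched). In sum mode, the focal
#' chromosome is rescaled so that its total equals the sum of its own and the
#' partner map's total, emulating the summing of reads from a homeologous
#' pair while keeping the single-track map structure.
#'
#' @param map a [signal_map()] in `RPM` (or `NRPM`) state.
#' @param scheme a [copy_scheme()].
#' @param partner_map map of the partner chromosome(s), required in sum mode.
#' @return A [signal_map()] in `NRPM` state.
#' @export
correct_copy_number <- function(map, scheme, partner_map = NULL) {
  if (!inherits(scheme, "copy_scheme"))
    stop("scheme must be a copy_scheme")
  if (map$state == "RAW")
    stop("correct_copy_number expects a normalized (RPM/NRPM) map")
  for (ch in names(scheme$factors)) {
    i <- chrom_index(map$assembly, ch)   # validates name
    map$values[[ch]] <- map$values[[ch]] * scheme$factors[[ch]]
  }
  if (!is.null(scheme$sum_chrom)) {
    ch <- scheme$sum_chrom
    chrom_index(map$assembly, ch)
    if (is.null(partner_map))
      stop("sum mode requires partner_map")
    own <- sum(map$values[[ch]])
    if (own <= 0)
      stop("sum mode: focal chromosome has zero signal")
    partner_total <- map_total(partner_map, mask_rdna = FALSE)
    map$values[[ch]] <- map$values[[ch]] * ((own + partner_total) / own)
  }
  map$state <- "NRPM"
  map
}

#' Place two maps on a common scale using non-focal chromosomes
#'
#' Computes each map's total excluding the focal chromosome, averages the two
#' to a standard total, and multiplies each whole map by
#' `standard / its own non-focal total`. After scaling both non-focal totals
#' equal the standard, so focal-chromosome differences can be read directly.
#'
#' @param map_a,map_b [signal_map()]s in `RPM` or `NRPM` state on the same
#'   assembly.
#' @param focal_chrom chromosome left out of the scaling totals.
#' @return list with elements `a`, `b` (scaled maps, state `NRPM`) and
#'   `standard_total`.
#' @export
cross_scale <- function(map_a, map_b, focal_chrom) {
  if (map_a$state == "RAW" || map_b$state == "RAW")
    stop("cross_scale expects normalized maps")
  chrom_index(map_a$assembly, focal_chrom)
  # sum the non-focal chromosomes directly (not total-minus-focal, which is
  # subject to cancellation error when the non-focal signal is zero)
  nf <- function(m) {
    others <- setdiff(names(m$values), focal_chrom)
    tot <- sum(vapply(m$values[others], sum, numeric(1)))
    rd <- m$assembly$rdna
    if (rd$chrom != focal_chrom)
      tot <- tot - sum(m$values[[rd$chrom]][rd$start:rd$end])
    tot
  }
  nfa <- nf(map_a)
  nfb <- nf(map_b)
  if (nfa <= 0 || nfb <= 0)
    stop("non-focal total is zero; cannot cross-scale")
  standard <- (nfa + nfb) / 2
  scale_map <- function(m, f) {
    m$values <- lapply(m$values, `*`, f)
    m$state <- "NRPM"
    m
  }
  list(a = scale_map(map_a, standard / nfa),
       b = scale_map(map_b, standard / nfb),
       standard_total = standard)
}

#' Per-chromosome totals and densities
#'
#' @param map a [signal_map()] in any state.
#' @param assembly defaults to the map's own assembly.
#' @return data frame with columns `chrom`, `length`, `total`, `density`
#'   (total/length) and `kRPM` (total/1000, for axis parity with map figures).
#' @export
per_chromosome_totals <- function(map, assembly = map$assembly) {
  tot <- chromosome_totals_vec(map)
  data.frame(
    chrom = assembly$chroms$chrom,
    length = assembly$chroms$length,
    total = as.numeric(tot),
    density = as.numeric(tot) / assembly$chroms$length,
    kRPM = as.numeric(tot) / 1000,
    stringsAsFactors = FALSE
  )
}

#' Apply a global scaling factor to a map
#'
#' Used to place mutant maps on an absolute-DSB scale when an independent
#' quantification of total break activity is available (e.g. 1.8-fold for a
#' zip3-deletion map, 1.7-fold for ecm11-deletion).
#'
#' @param map a [signal_map()].
#' @param factor positive scalar.
#' @return The scaled map (state unchanged except `RPM` becomes `NRPM`,
#'   since the 1e6 total no longer holds).
#' @export
apply_global_scale <- function(map, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor <= 0)
    stop("scaling factor must be a positive number")
  map$values <- lapply(map$values, `*`, factor)
  if (map$state == "RPM" && factor != 1) map$state <- "NRPM"
  map
}
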