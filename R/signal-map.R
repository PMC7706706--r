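#' Per-base signal maps
#'
#' A `signal_map` stores strand-collapsed, non-negative per-base coverage for
#' every chromosome of an assembly, together with its normalization state:
#' `RAW` (counts), `RPM` (reads per million mapped, rDNA masked) or `NRPM`
#' (RPM after copy-number correction and/or cross-map scaling).
#'
#' @param values named list of numeric vectors, one per chromosome, each of
#'   the chromosome's full length. Chromosomes absent from the list are
#'   all-zero.
#' @param assembly a [genome_assembly()].
#' @param state one of `"RAW"`, `"RPM"`, `"NRPM"`.
#' @return An object of class `signal_map`: list with elements `values`
#'   (named list, one numeric vector per chromosome), `assembly`, `state`.
#' @export
signal_map <- function(values, assembly, state = c("RAW", "RPM", "NRPM")) {
  state <- match.arg(state)
  chroms <- assembly$chroms$chrom
  out <- vector("list", length(chroms))
  names(out) <- chroms
  unknown <- setdiff(names(values), chroms)
  if (length(unknown))
    stop("unknown chromosome name: ", paste(unknown, collapse = ", "))
  for (ch in chroms) {
    v <- values[[ch]]
    L <- chrom_length(assembly, ch)
    if (is.null(v)) v <- numeric(L)
    if (length(v) != L)
      stop(sprintf("values for %s have length %d, expected %d",
                   ch, length(v), L))
    if (anyNA(v) || any(v < 0))
      stop("signal values must be finite and >= 0 (", ch, ")")
    out[[ch]] <- as.numeric(v)
  }
  structure(list(values = out, assembly = assembly, state = state),
            class = "signal_map")
}

#' @export
print.signal_map <- function(x, ...) {
  cat(sprintf("Spo11-oligo signal map [%s], %d chromosomes\n",
              x$state, length(x$values)))
  cat(sprintf("  included total: %.4g (rDNA masked)\n", map_total(x)))
  invisible(x)
}

mask_rdna <- function(map) {
  rd <- map$assembly$rdna
  map$values[[rd$chrom]][rd$start:rd$end] <- 0
  map
}

#' Total included signal of a map
#'
#' Sum of per-base values over nuclear chromosomes with the rDNA interval
#' masked (zeroed) before totaling. For a map in `RPM` state this is 1e6.
#'
#' @param map a [signal_map()].
#' @param mask_rdna mask the rDNA interval before summing (default `TRUE`).
#' @return numeric total.
#' @export
map_total <- function(map, mask_rdna = TRUE) {
  tot <- sum(vapply(map$values, sum, numeric(1)))
  if (mask_rdna) {
    rd <- map$assembly$rdna
    tot <- tot - sum(map$values[[rd$chrom]][rd$start:rd$end])
  }
  tot
}

chromosome_totals_vec <- function(map) {
  vapply(map$values, sum, numeric(1))
}

parse_kv <- function(fields) {
  kv <- strsplit(fields, "=", fixed = TRUE)
  out <- vapply(kv, function(p) if (length(p) == 2) p[2] else NA_character_,
                character(1))
  names(out) <- vapply(kv, `[`, character(1), 1)
  out[!is.na(out)]
}

#' Read a per-base coverage map (wiggle or bedGraph)
#'
#' Accepts the two common wiggle dialects (`variableStep` with any span,
#' `fixedStep`) and 4-column bedGraph. Unlisted positions are zero. The file
#' may carry a `track` line; a `dsbscape_state=RPM|NRPM` attribute on it (or a
#' `#dsbscape state=...` comment) marks prior normalization, otherwise the map
#' is returned in `RAW` state. Coverage on the assembly's excluded sequences
#' (mitochondrial, 2-micron) is ignored.
#'
#' @param path file path.
#' @param assembly a [genome_assembly()].
#' @param format `"auto"` (sniff step headers), `"wig"` or `"bedGraph"`.
#' @return A [signal_map()].
#' @export
read_signal_map <- function(path, assembly,
                            format = c("auto", "wig", "bedGraph")) {
  format <- match.arg(format)
  lines <- readLines(path)
  state <- "RAW"
  for (ln in grep("^#", lines, value = TRUE)) {
    f <- strsplit(trimws(sub("^#", "", ln)), "[ \t]+")[[1]]
    if (length(f) >= 2 && f[1] == "dsbscape") {
      kv <- parse_kv(f[-1])
      if ("state" %in% names(kv)) state <- kv[["state"]]
    }
  }
  lines <- lines[!grepl("^(#|browser)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  track <- grep("^track", lines)
  if (length(track)) {
    f <- strsplit(lines[track[1]], "[ \t]+")[[1]]
    kv <- parse_kv(f[-1])
    if ("dsbscape_state" %in% names(kv)) state <- kv[["dsbscape_state"]]
    lines <- lines[-track]
  }
  if (!state %in% c("RAW", "RPM", "NRPM"))
    stop("unrecognized map state in header: ", state)
  chroms <- assembly$chroms$chrom
  values <- lapply(chrom_length(assembly, chroms), numeric)
  names(values) <- chroms
  if (length(lines) == 0)
    return(signal_map(values, assembly, state))
  # occupancy mask per chromosome, to detect overlapping/duplicate records
  seen <- lapply(chrom_length(assembly, chroms),
                 function(L) raw(L))
  names(seen) <- chroms

  is_step <- grepl("^(variableStep|fixedStep)", lines)
  if (format == "auto")
    format <- if (any(is_step)) "wig" else "bedGraph"

  check_chrom <- function(ch) {
    if (ch %in% assembly$excluded) return(FALSE)
    if (!ch %in% chroms)
      stop("format error: unknown chromosome name '", ch, "'")
    TRUE
  }
  add_run <- function(ch, start, end, val) {
    L <- length(values[[ch]])
    if (any(start < 1) || any(end > L))
      stop(sprintf("format error: position outside %s bounds (1-%d)", ch, L))
    for (i in seq_along(start)) {
      idx <- start[i]:end[i]
      if (any(seen[[ch]][idx] != as.raw(0)))
        stop("format error: overlapping intervals on ", ch)
      seen[[ch]][idx] <<- as.raw(1)
      values[[ch]][idx] <<- val[i]
    }
  }

  if (format == "bedGraph") {
    f <- strsplit(lines, "[ \t]+")
    if (any(lengths(f) < 4))
      stop("format error: bedGraph lines need 4 fields")
    ch <- vapply(f, `[`, character(1), 1)
    s0 <- as.numeric(vapply(f, `[`, character(1), 2))
    e0 <- as.numeric(vapply(f, `[`, character(1), 3))
    v <- as.numeric(vapply(f, `[`, character(1), 4))
    if (anyNA(s0) || anyNA(e0) || anyNA(v))
      stop("format error: non-numeric bedGraph fields")
    for (cc in unique(ch)) {
      if (!check_chrom(cc)) next
      j <- which(ch == cc)
      add_run(cc, s0[j] + 1, e0[j], v[j])   # 0-based half-open -> 1-based
    }
  } else {
    hdr <- grep("^(variableStep|fixedStep)", lines)
    if (length(hdr) == 0 || hdr[1] != 1)
      stop("format error: wiggle data before any step header")
    block_end <- c(hdr[-1] - 1, length(lines))
    for (b in seq_along(hdr)) {
      f <- strsplit(lines[hdr[b]], "[ \t]+")[[1]]
      mode <- f[1]
      kv <- parse_kv(f[-1])
      ch <- kv[["chrom"]]
      span <- if ("span" %in% names(kv)) as.numeric(kv[["span"]]) else 1
      body <- lines[seq(hdr[b] + 1, length.out = block_end[b] - hdr[b])]
      keep <- check_chrom(ch)
      if (length(body) == 0) next
      bf <- strsplit(body, "[ \t]+")
      if (mode == "variableStep") {
        if (any(lengths(bf) < 2))
          stop("format error: variableStep lines need 2 fields")
        pos <- as.numeric(vapply(bf, `[`, character(1), 1))
        val <- as.numeric(vapply(bf, `[`, character(1), 2))
        if (anyNA(pos) || anyNA(val))
          stop("format error: non-numeric variableStep fields")
        if (keep) add_run(ch, pos, pos + span - 1, val)
      } else {
        start <- as.numeric(kv[["start"]])
        step <- if ("step" %in% names(kv)) as.numeric(kv[["step"]]) else 1
        val <- as.numeric(vapply(bf, `[`, character(1), 1))
        if (anyNA(val))
          stop("format error: non-numeric fixedStep fields")
        pos <- start + step * (seq_along(val) - 1)
        if (keep) add_run(ch, pos, pos + span - 1, val)
      }
    }
  }
  signal_map(values, assembly, state)
}

#' Write a signal map as wiggle
#'
#' Emits `variableStep span=1` records for non-zero positions, preceded by a
#' track line carrying the map's normalization state. Values are printed at
#' full double precision so that write/read round-trips are bit-exact.
#'
#' @param map a [signal_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signal_map <- function(map, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf(
    "track type=wiggle_0 name=dsbscape dsbscape_state=%s", map$state), con)
  for (ch in names(map$values)) {
    v <- map$values[[ch]]
    nz <- which(v != 0)
    if (length(nz) == 0) next
    writeLines(sprintf("variableStep chrom=%s span=1", ch), con)
    writeLines(paste(nz, sprintf("%.17g", v[nz])), con)
  }
  invisible(path)
}
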