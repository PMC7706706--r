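#' Kinetic time courses
#'
#' A `time_course` is a (time in hours, measurement) series for a PFGE
#' broken-fraction or ChIP-qPCR percent-of-input assay, tagged with the locus
#' or probe label. Times are stored sorted and must be unique; values must be
#' finite and non-negative.
#'
#' @param time_h numeric times in hours.
#' @param value numeric measurements (percent broken DNA, percent of input).
#' @param label locus/probe identifier.
#' @return An object of class `time_course`: data frame with columns
#'   `time_h`, `value` and attribute `label`.
#' @export
time_course <- function(time_h, value, label = NA_character_) {
  stopifnot(length(time_h) == length(value))
  o <- order(time_h)
  time_h <- as.numeric(time_h)[o]
  value <- as.numeric(value)[o]
  if (anyDuplicated(time_h))
    stop("duplicate time points in series '", label, "'")
  if (anyNA(value) || any(!is.finite(value)))
    stop("time-course values must be finite")
  if (any(value < 0))
    stop("time-course values must be >= 0")
  structure(data.frame(time_h = time_h, value = value),
            label = as.character(label),
            class = c("time_course", "data.frame"))
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Time course '%s': %d points, %g-%g h\n",
              attr(x, "label"), nrow(x), min(x$time_h), max(x$time_h)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read kinetic time courses from a TSV file
#'
#' Expects columns `time_h`, `value`, `label`; returns one sorted
#' [time_course()] per label. Duplicate (label, time) pairs and negative
#' values are errors.
#'
#' @param path TSV file path.
#' @return Named list of [time_course()] objects, one per label.
#' @export
read_timecourse <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("time_h", "value", "label")
  if (!all(need %in% names(tab)))
    stop("time-course table must have columns: ",
         paste(need, collapse = ", "))
  if (anyDuplicated(tab[c("label", "time_h")]))
    stop("duplicate (label, time) pair in time-course table")
  if (any(tab$value < 0))
    stop("time-course values must be >= 0")
  labs <- unique(tab$label)
  out <- lapply(labs, function(l) {
    sub <- tab[tab$label == l, ]
    time_course(sub$time_h, sub$value, label = l)
  })
  names(out) <- labs
  out
}

#' Write time courses to a TSV file
#'
#' @param tcs a [time_course()] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tcs, path) {
  if (inherits(tcs, "time_course")) tcs <- list(tcs)
  tab <- do.call(rbind, lapply(tcs, function(tc) {
    data.frame(time_h = tc$time_h, value = tc$value,
               label = attr(tc, "label"), stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
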