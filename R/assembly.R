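#' Genome assembly model
#'
#' A `genome_assembly` holds the coordinate frame every other operation in the
#' package works in: ordered nuclear chromosome names and lengths, centromere
#' midpoints, the rDNA interval (masked during normalization), the names of
#' non-nuclear sequences that are excluded from read totals, and per-chromosome
#' copy numbers (diploid baseline 2).
#'
#' Coordinates are 1-based closed intervals throughout (SGD convention); BED
#' output converts to 0-based half-open on write.
#'
#' @param chrom character vector of chromosome names, in karyotype order.
#' @param length integer chromosome lengths in bp.
#' @param cen_mid integer centromere midpoint per chromosome (bp).
#' @param copy_number integer copies per chromosome; default 2 (diploid).
#' @param rdna list or vector `(chrom, start, end)` of the rDNA interval.
#' @param excluded character names of non-nuclear sequences (e.g. `chrM`,
#'   `2micron`); coverage on these is ignored on read.
#' @param genome optional assembly label.
#'
#' @return An object of class `genome_assembly`: a list with elements
#'   `chroms` (data frame `chrom`, `length`, `cen_mid`, `copy_number`),
#'   `rdna`, `excluded`, and `genome`.
#' @export
#' @examples
#' asm <- genome_assembly(c("chrA", "chrB"), c(200000L, 100000L),
#'                        c(60000L, 30000L),
#'                        rdna = list(chrom = "chrA", start = 150000,
#'                                    end = 155000))
genome_assembly <- function(chrom, length, cen_mid,
                            copy_number = rep(2L, base::length(chrom)),
                            rdna,
                            excluded = character(),
                            genome = NA_character_) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  cen_mid <- as.numeric(cen_mid)
  copy_number <- as.integer(copy_number)
  n <- base::length(chrom)
  stopifnot(base::length(length) == n, base::length(cen_mid) == n,
            base::length(copy_number) == n)
  if (anyDuplicated(chrom))
    stop("duplicated chromosome names in assembly")
  if (any(length < 1))
    stop("chromosome lengths must be positive")
  if (any(cen_mid < 1 | cen_mid > length))
    stop("centromere midpoint outside chromosome bounds")
  if (any(copy_number < 1L))
    stop("copy_number must be >= 1 for every chromosome")
  rdna <- as.list(rdna)
  names(rdna) <- c("chrom", "start", "end")[seq_along(rdna)]
  rdna$chrom <- as.character(rdna$chrom)
  rdna$start <- as.numeric(rdna$start)
  rdna$end <- as.numeric(rdna$end)
  if (!rdna$chrom %in% chrom)
    stop("rDNA interval on unknown chromosome: ", rdna$chrom)
  L <- length[match(rdna$chrom, chrom)]
  if (rdna$start < 1 || rdna$end > L || rdna$start > rdna$end)
    stop("rDNA interval outside chromosome bounds")
  structure(
    list(
      chroms = data.frame(chrom = chrom, length = length, cen_mid = cen_mid,
                          copy_number = copy_number,
                          stringsAsFactors = FALSE),
      rdna = rdna,
      excluded = as.character(excluded),
      genome = genome
    ),
    class = "genome_assembly"
  )
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("Genome assembly", if (!is.na(x$genome)) paste0("'", x$genome, "'"),
      "\n", sep = " ")
  cat(sprintf("  %d chromosomes, %.2f Mb total\n",
              nrow(x$chroms), sum(x$chroms$length) / 1e6))
  cat(sprintf("  rDNA: %s:%d-%d\n", x$rdna$chrom, x$rdna$start, x$rdna$end))
  if (length(x$excluded))
    cat("  excluded sequences:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Read a genome assembly table
#'
#' Parses the tab-separated assembly format shipped in `inst/extdata`:
#' a header data table with columns `chrom`, `length`, `cen_mid`,
#' `copy_number`, preceded by optional directive comment lines
#' `#rdna <chrom> <start> <end>` and `#excluded <name> ...`.
#'
#' @param path path to the TSV file.
#' @param genome optional assembly label.
#' @return A [genome_assembly()].
#' @export
read_assembly <- function(path, genome = NA_character_) {
  lines <- readLines(path)
  rdna <- NULL
  excluded <- character()
  for (ln in grep("^#", lines, value = TRUE)) {
    f <- strsplit(trimws(sub("^#", "", ln)), "[ \t]+")[[1]]
    if (length(f) == 0) next
    if (f[1] == "rdna") rdna <- list(chrom = f[2], start = as.numeric(f[3]),
                                     end = as.numeric(f[4]))
    if (f[1] == "excluded") excluded <- f[-1]
  }
  if (is.null(rdna))
    stop("assembly table lacks an '#rdna' directive")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "length", "cen_mid")
  if (!all(need %in% names(tab)))
    stop("assembly table must have columns: ", paste(need, collapse = ", "))
  if (is.null(tab$copy_number)) tab$copy_number <- 2L
  genome_assembly(tab$chrom, tab$length, tab$cen_mid, tab$copy_number,
                  rdna = rdna, excluded = excluded, genome = genome)
}

#' The packaged sacCer2 assembly
#'
#' Chromosome lengths, centromere midpoints and the chrXII rDNA (RDN1)
#' interval of the S. cerevisiae sacCer2 assembly, shipped with the package so
#' that no download is needed. Mitochondrial DNA and the 2-micron plasmid are
#' excluded sequences.
#'
#' @return A [genome_assembly()] of the 16 nuclear chromosomes.
#' @export
saccer2_assembly <- function() {
  read_assembly(system.file("extdata", "sacCer2_assembly.tsv",
                            package = "dsbscape"),
                genome = "sacCer2")
}

#' A small toy assembly for simulation and tests
#'
#' Four chromosomes spanning 200-1,500 kb, centromeres placed off-center, and
#' a short rDNA-like interval on the largest chromosome. Copy numbers can be
#' set to emulate aneuploidy.
#'
#' @param lengths chromosome lengths in bp.
#' @param copy_number per-chromosome copies (recycled).
#' @return A [genome_assembly()].
#' @export
toy_assembly <- function(lengths = c(1500e3, 1100e3, 700e3, 200e3),
                         copy_number = 2L) {
  n <- length(lengths)
  chrom <- paste0("chr", utils::as.roman(seq_len(n)))
  genome_assembly(
    chrom = chrom,
    length = lengths,
    cen_mid = round(lengths * 0.4),
    copy_number = rep_len(as.integer(copy_number), n),
    rdna = list(chrom = chrom[1],
                start = round(lengths[1] * 0.6),
                end = round(lengths[1] * 0.6) + 9999),
    excluded = c("chrM", "2micron"),
    genome = "toy"
  )
}

chrom_index <- function(assembly, chrom) {
  i <- match(chrom, assembly$chroms$chrom)
  if (anyNA(i))
    stop("unknown chromosome name: ",
         paste(chrom[is.na(i)], collapse = ", "))
  i
}

chrom_length <- function(assembly, chrom) {
  assembly$chroms$length[chrom_index(assembly, chrom)]
}

#' Total nuclear genome length included in density calculations
#'
#' Sum of chromosome lengths minus the width of the masked rDNA interval.
#'
#' @param assembly a [genome_assembly()].
#' @return numeric length in bp.
#' @export
included_genome_length <- function(assembly) {
  sum(assembly$chroms$length) - (assembly$rdna$end - assembly$rdna$start + 1)
}
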