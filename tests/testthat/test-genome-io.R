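test_that("assembly invariants are enforced and the packaged table loads", {
  asm <- saccer2_assembly()
  expect_equal(nrow(asm$chroms), 16)
  expect_true(all(asm$chroms$cen_mid >= 1 &
                    asm$chroms$cen_mid <= asm$chroms$length))
  expect_identical(asm$rdna$chrom, "chrXII")
  expect_true(asm$rdna$start >= 1 &&
                asm$rdna$end <= dsbscape:::chrom_length(asm, "chrXII"))
  expect_true(all(asm$chroms$copy_number >= 1))
  expect_error(genome_assembly("c1", 100, 200,
                               rdna = list("c1", 1, 10)),
               "centromere")
  expect_error(genome_assembly("c1", 100, 50,
                               rdna = list("c1", 90, 120)),
               "rDNA")
  expect_error(genome_assembly("c1", 100, 50, copy_number = 0L,
                               rdna = list("c1", 10, 20)),
               "copy_number")
})

test_that("single-record and empty wiggle files read as specified", {
  asm <- genome_assembly(c("chrV", "chrX"), c(5000, 2000), c(2500, 1000),
                         rdna = list("chrX", 1, 10))
  f <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("variableStep chrom=chrV span=1", "1000 3.0"), f)
  m <- read_signal_map(f, asm)
  expect_identical(m$state, "RAW")
  expect_equal(m$values$chrV[1000], 3.0)
  expect_equal(sum(m$values$chrV), 3.0)
  expect_equal(sum(m$values$chrX), 0)

  writeLines(character(0), f)
  m0 <- read_signal_map(f, asm)
  expect_equal(map_total(m0), 0)
})

test_that("both wiggle dialects, spans, and bedGraph are accepted", {
  asm <- mini_assembly(1000L)
  f <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chrT start=11 step=1", "1", "2", "3",
               "variableStep chrom=chrT span=3", "101 5"), f)
  m <- read_signal_map(f, asm)
  expect_equal(m$values$chrT[11:13], c(1, 2, 3))
  expect_equal(m$values$chrT[101:103], c(5, 5, 5))

  g <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chrT\t0\t3\t2.5", "chrT\t10\t12\t1"), g)
  mb <- read_signal_map(g, asm)
  expect_equal(mb$values$chrT[1:3], rep(2.5, 3))
  expect_equal(mb$values$chrT[11:12], c(1, 1))
  expect_equal(sum(mb$values$chrT), 9.5)
})

test_that("format errors name the offender", {
  asm <- mini_assembly(1000L)
  f <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("variableStep chrom=chrBogus span=1", "10 1"), f)
  expect_error(read_signal_map(f, asm), "chrBogus")
  writeLines(c("variableStep chrom=chrT span=1", "2000 1"), f)
  expect_error(read_signal_map(f, asm), "bounds")
  g <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chrT\t0\t10\t1", "chrT\t5\t15\t2"), g)
  expect_error(read_signal_map(g, asm), "overlap")
  # excluded sequences are ignored, not errors
  writeLines(c("variableStep chrom=chrM span=1", "10 4",
               "variableStep chrom=chrT span=1", "10 4"), f)
  asm2 <- genome_assembly("chrT", 1000, 500, rdna = list("chrT", 1, 1),
                          excluded = "chrM")
  m <- read_signal_map(f, asm2)
  expect_equal(sum(m$values$chrT), 4)
})

test_that("write/read round-trip is bit-exact and preserves state", {
  asm <- genome_assembly(c("cA", "cB"), c(3000, 1500), c(1000, 700),
                         rdna = list("cB", 100, 150))
  withr::with_seed(71, {
    for (rep in 1:5) {
      vals <- list(cA = numeric(3000), cB = numeric(1500))
      nz <- sample.int(3000, 200)
      vals$cA[nz] <- rexp(200) * 100
      vals$cB[sample.int(1500, 80)] <- rpois(80, 4) + 0.5
      m <- signal_map(vals, asm, state = "NRPM")
      f <- withr::local_tempfile(fileext = ".wig")
      write_signal_map(m, f)
      m2 <- read_signal_map(f, asm)
      expect_identical(m2$state, "NRPM")
      expect_identical(m2$values$cA, m$values$cA)
      expect_identical(m2$values$cB, m$values$cB)
    }
  })
})

test_that("wiggle parser agrees with rtracklayer on a shared fixture", {
  skip_if_not_installed("rtracklayer")
  asm <- mini_assembly(5000L)
  f <- withr::local_tempfile(fileext = ".wig")
  withr::with_seed(5, {
    pos <- sort(sample.int(5000, 150))
    val <- round(rexp(150) * 10, 6)
  })
  writeLines(c("variableStep chrom=chrT span=1",
               paste(pos, val)), f)
  m <- read_signal_map(f, asm)
  gr <- rtracklayer::import(f, format = "wig")
  expect_equal(sum(m$values$chrT), sum(gr$score))
  expect_equal(m$values$chrT[pos], gr$score[order(BiocGenerics::start(gr))])
})

test_that("hotspot BED output follows 0-based half-open convention and round-trips", {
  hs <- dsbscape:::new_hotspot_set(data.frame(
    chrom = c("chrI", "chrI", "chrII"),
    start = c(101L, 500L, 7L), end = c(200L, 620L, 31L),
    width = c(100L, 121L, 25L),
    total_signal = c(55.25, 10 + 1e-9, 12.125),
    peak_smoothed = c(1, 2, 3), stringsAsFactors = FALSE))
  f <- withr::local_tempfile(fileext = ".bed")
  write_hotspots(hs, f)
  lines <- readLines(f)
  expect_match(lines[1], "^track")
  expect_identical(strsplit(lines[2], "\t")[[1]][2:3], c("100", "200"))
  back <- read_hotspots(f)
  expect_identical(back$start, hs$start)
  expect_identical(back$end, hs$end)
  expect_identical(back$total_signal, hs$total_signal)

  # empty set -> header-only file
  write_hotspots(hs[0, ], f)
  expect_identical(length(readLines(f)), 1L)
  expect_equal(nrow(read_hotspots(f)), 0)

  # overlapping hotspots are an integrity error
  bad <- hs
  bad$start[2] <- 150L
  expect_error(write_hotspots(bad, f), "overlap")
})

test_that("random hotspot sets round-trip through BED with identical coordinates", {
  withr::with_seed(909, {
    for (rep in 1:5) {
      # gaps of at least 301 bp between starts, widths below 300:
      # disjoint by construction
      s <- cumsum(sample(301:700, 40, replace = TRUE))
      e <- s + sample.int(299, 40)
      hs <- dsbscape:::new_hotspot_set(data.frame(
        chrom = "chrZ", start = s, end = e, width = e - s + 1L,
        total_signal = rexp(40) * 50,
        peak_smoothed = NA_real_, stringsAsFactors = FALSE))
      f <- withr::local_tempfile(fileext = ".bed")
      write_hotspots(hs, f)
      back <- read_hotspots(f)
      expect_identical(back$start, hs$start)
      expect_identical(back$end, hs$end)
      expect_identical(back$total_signal, hs$total_signal)
    }
  })
})

test_that("time-course reader groups by label, sorts, and validates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time_h\tvalue\tlabel",
               "2\t5.5\tP1", "0\t0.4\tP1", "4\t8.1\tP1"), f)
  tcs <- read_timecourse(f)
  expect_length(tcs, 1)
  expect_equal(tcs$P1$time_h, c(0, 2, 4))
  expect_equal(tcs$P1$value, c(0.4, 5.5, 8.1))

  # the 12-point ChIP sampling grid, two probes
  grid <- c(0, 1, 2, 2.5, 3, 3.5, 4, 4.5, 5, 5.5, 6, 7)
  tab <- data.frame(time_h = rep(grid, 2),
                    value = seq_len(24) / 10,
                    label = rep(c("P1", "P2"), each = 12))
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  tcs2 <- read_timecourse(f)
  expect_length(tcs2, 2)
  expect_equal(tcs2$P2$time_h, grid)

  writeLines(c("time_h\tvalue\tlabel", "1\t2\tA", "1\t3\tA"), f)
  expect_error(read_timecourse(f), "duplicate")
  writeLines(c("time_h\tvalue\tlabel", "1\t-2\tA"), f)
  expect_error(read_timecourse(f), ">= 0")
})
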