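Package: dsbscape
Title: Meiotic DSB Landscape Analysis from Spo11-Oligo Coverage Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide meiotic double-strand break
    (DSB) landscapes measured by Spo11-oligo sequencing in budding yeast.
    Reads per-base coverage maps (wiggle/bedGraph), performs reads-per-million
    normalization with rDNA masking, corrects chromosome copy number for
    aneuploid and homeologous karyotypes, and places pairs of maps on a common
    scale using non-focal chromosomes. Calls DSB hot spots by thresholding a
    Hann-window-smoothed map, compares hot-spot sets, and summarizes fold
    changes along chromosomes and within sub-chromosomal domains (telomeric,
    pericentromeric, rDNA-flanking, end-adjacent regions). Fits log-normal
    DSB-timing curves to pulsed-field gel time courses with Poisson correction
    for multiple breaks, estimates protein association/dissociation times from
    ChIP-qPCR time courses via logistic fits, and compares whole maps by
    covariance PCA and Ward-D2 hierarchical clustering. A seeded synthetic-data
    generator emulates hot-spot-structured count maps and noisy kinetic time
    courses so the full pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    BiocGenerics,
    minpack.lm
Config/testthat/edition: 3
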