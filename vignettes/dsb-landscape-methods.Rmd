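---
title: "Methods: quantifying meiotic DSB landscapes with dsbscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying meiotic DSB landscapes with dsbscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbscape)
```

`dsbscape` analyzes genome-wide meiotic double-strand break (DSB) maps built
from Spo11-oligo sequencing, together with the two kinetic assays that
usually accompany them (PFGE broken-fraction time courses and ChIP-qPCR
binding profiles). This vignette is the package's account of the underlying
models, the tunable parameters and their defaults, the numerical choices,
and the limits of what the synthetic-data generator can establish.

## Coordinate model and map representation

All internal coordinates are 1-based closed intervals, the SGD convention in
which yeast genome annotations are published; BED export converts to 0-based
half-open on write and back on read, so interval round-trips are the
identity. A `signal_map` stores a full-length numeric vector per chromosome
(strand-collapsed per-base coverage) plus a normalization state: `RAW`
counts, `RPM`, or `NRPM` (copy-corrected and/or rescaled RPM). The wiggle
reader accepts `variableStep` (any span) and `fixedStep` dialects as well as
bedGraph, because public Spo11-oligo depositions use the wiggle family
loosely; the writer emits `variableStep span=1` with values printed at full
double precision (`%.17g`), which makes write/read round-trips bit-exact —
a property the test suite checks against random maps and cross-checks
against an independent wiggle parser.

Non-nuclear sequences (mitochondrial DNA, the 2-micron plasmid) are excluded
sequences of the assembly: coverage on them is ignored at read time rather
than carried around and repeatedly masked.

## Normalization

**RPM.** Each map is scaled so the total over nuclear chromosomes equals one
million, excluding the rDNA interval, whose repeat structure makes its
apparent coverage an artifact of mapping. Masking zeroes the annotated rDNA
interval (chrXII in sacCer2) before totaling, and the normalized map keeps
those bases at zero so the plain map total equals 1e6 exactly. We mask the
interval rather than dropping chrXII entirely, so the rest of chrXII remains
usable. Chromosome *densities* divide by the full assembly length; the few
masked kilobases are a negligible fraction of chrXII and this keeps lengths
interpretable.

**Copy number.** RPM is a *relative* measure, so chromosomes present in
abnormal copy number must be corrected before per-chromosome comparison.
With a diploid baseline the factor is `2 / copy number`: a trisomic
chromosome is multiplied by 2/3, a chromosome whose partner is absent from
the reference (e.g. the native copy of a homeologous pair, when the partner
maps to its own sequence) by 2. For per-chromosome totals of a homeolog pair
the package can instead *sum* the partner map's reads into the focal
chromosome (`copy_scheme(sum_chrom = ...)`); summing is preferred for totals
because it uses all reads, while doubling is the only option for per-base
profiles along the native copy, where the partner's coordinates do not
align. Both modes are exposed; the choice belongs to the analysis, not the
package.

**Cross-map scaling.** If the focal chromosome genuinely makes more DSBs,
RPM normalization deflates every other chromosome. Two maps are therefore
placed on a common scale by equalizing their totals over the *non-focal*
chromosomes: both totals are averaged to a standard, and each map is
multiplied by `standard / own non-focal total`. The non-focal totals are
computed by summing the non-focal chromosomes directly rather than
subtracting the focal total from the grand total, which avoids catastrophic
cancellation when a map is degenerate. After scaling, the focal-chromosome
ratio between the maps is the quantity of interest; everything else sits on
the diagonal by construction.

**Global scale factors.** Comparisons against mutants with globally elevated
DSB numbers can apply a single externally measured factor (e.g. 1.8 for a
ZMM-deletion map, 1.7 for an SC-central-element deletion, from Spo11-oligo
complex quantification) to place a map on an absolute scale. The package
treats the factor as an input, not something it estimates.

## Hot-spot calling

The smoothing kernel is a Hann (raised-cosine) window, width 201 bp by
default, normalized to sum 1; at chromosome ends the window is truncated and
renormalized over in-bounds positions, so a constant map is a fixed point of
smoothing everywhere. The smoothed density is compared **strictly** against
a threshold: by default 2.3-fold the map's genome-average density (total
included signal over included genome length), with a fixed absolute
threshold (0.193 RPM/bp) available for parity with published sacCer2 calls —
the effective genome length behind that published constant is not exactly
recoverable, which is why the fold-over-mean form is the default. Candidate
runs separated by ≤ 200 bp are merged *transitively* (a chain of small gaps
merges into one hot spot; the merge is a single grouping pass, and a
repeat-until-stable pairwise merge provably gives the same result — the test
oracle uses the latter). Finally, candidates narrower than 25 bp **or**
containing less than 10 units of summed raw signal are removed; this is the
stricter reading of the published "and/or" filter and removes every listed
defect. Hot-spot strength (`total_signal`) sums the *raw* map inside the
interval, not the smoothed one, matching how hot-spot strengths are reported
in the field.

The numerator of the smoother is computed by FFT convolution (the window is
symmetric) and the edge-renormalization denominator by exact cumulative
sums. FFT round-off is at the level of 1e-15 relative and is far from any
calling decision in practice; the caller's correctness surface is an exact
equivalence against a brute-force per-base oracle over a thousand random
maps.

Two hot spots in different sets are "shared" when their intervals intersect
by at least one base pair; because a hot spot may overlap several in the
other set, shared counts are reported from both directions. Per-hotspot fold
changes between comparably scaled maps are summarized with a tricube local
regression (loess, span 0.5 by default, degree 2) over hot-spot midpoints
per chromosome; the span is a display choice, not an inference. Hot spots
with zero denominator signal are flagged and excluded from the trend but
never dropped from the table. Chromosomes with fewer than about ten usable
hot spots get the group mean as their trend, since a loess fit with fewer
points than local degrees of freedom is meaningless.

## Sub-chromosomal domains

Hot spots are classified by their midpoint — hot spots are tens to hundreds
of bp, domains are tens of kb, so boundary straddling is immaterial — into
telomeric (≤ 20 kb from a chromosome end), pericentromeric (≤ 10 kb from the
centromere midpoint), rDNA-flanking (60 kb left to 30 kb right of the
annotated rDNA interval, its own chromosome only), and interstitial
(everything else), with precedence TEL > CEN > RDNA; telomere and centromere
windows can only collide on very short arms, and the precedence is
configurable in the sense that the distance computations are exposed. The
end-adjacent-region scheme adds EAR for midpoints more than 20 kb and at
most 110 kb from the nearer telomere, applied after TEL, so the 20-kb
boundary itself is telomeric and TEL and EAR are disjoint by construction.
Per-domain fold-change distributions are summarized with type-7 quartiles
and Tukey whiskers (most extreme points within 1.5 × IQR of the box),
reproducing the standard box-plot convention exactly.

The chromosome-size relation is plain Pearson correlation between
chromosome length and per-chromosome density, with optional exclusion of
named chromosomes (a focal aneuploid chromosome distorts the relation for
reasons unrelated to size regulation).

## Kinetics

**PFGE.** The broken fraction is `broken / (parental + broken)` per lane.
Because a gel scores a chromatid with several breaks only once, observed
fractions are converted to mean breaks per chromatid with the Poisson
zero-class correction `λ = −ln(1 − f)`; the cited literature does not
restate the formula, but this is the standard zero-truncation correction
consistent with correcting for multiple breaks, it is exactly inverse to
`f = 1 − e^{−λ}`, and `λ ≥ f` always with equality in the small-f limit.

**DSB timing.** The timing curve is log-normal in shifted time:
`y = a + b·exp{−[log(x + 1) − c]² / d²}` with natural log (the convention of
the R fitting environment in which this curve family is used). The
background `a` is pinned to the observed 0-h value — it is a property of the
assay, not a free parameter — and `(b, c, d)` minimize the residual sum of
squares. The curve's analytic maximum is at `x = e^c − 1`, reported as the
peak time. Optimization is bounded multi-start local search: L-BFGS-B from a
deterministic grid (`b₀ = max − a`, `c₀ = log(argmax + 1)`,
`d₀ ∈ {0.3, 0.6, 1.2}` plus one shifted start), followed by a Nelder-Mead
polish of the winner, because L-BFGS-B line searches can end abnormally on
nearly flat residual surfaces without being wrong. No randomness is
involved. On noiseless model data the fit recovers `(b, c, d)` to well under
1%; under Gaussian noise of SD 0.3 on a peak of height 8, the median
peak-time error over 200 replicates stays under 0.15 h — the package's
resolution target, chosen because reproducible timing shifts of ~15 min are
the effect size this assay is asked to resolve.

**Time-averaged DSBs.** The area under the observed points by the
trapezoidal rule, in %·h, with optional 0-h background subtraction (both
conventions appear in practice, so both are offered; the default integrates
the observed values as plotted).

**ChIP binding windows.** Binding profiles rise to a plateau and fall. The
peak is located by fitting the same log-normal family as above (the only
peak-shaped curve this package defines; the originally cited "modified
Gaussian" is not specified precisely in the literature, so this stand-in is
a documented choice). A 3-parameter logistic `L / (1 + exp(−k(t − t₀)))` is
then least-squares fitted to the observed points at `t ≤ peak`, and a
decreasing logistic to `t ≥ peak`; the association and dissociation times
are the half-maximum times (`t₀`) of the two fits and the binding duration
is their difference. The plateau `L` is a free parameter rather than the
observed maximum, which makes the times invariant under amplitude scaling.
No pseudo-point is injected at the fitted peak: anchoring the slope fits to
a model-interpolated peak value measurably biases both half-maximum times
toward the peak (about 0.04 h per side on noiseless product-of-logistics
truth), so each slope is fit only to its own observations. Each slope must
contain at least three samples; the error message names the offending
slope. Estimated association times are clipped to not exceed the peak time
(and dissociation times to not precede it), so the window invariant
`t_assoc ≤ peak ≤ t_dissoc` holds by construction.

## Multivariate map comparison

Whole maps are compared through their 16 per-chromosome RPM totals. PCA is
covariance PCA — column-centered, not variance-scaled — computed by SVD of
the centered matrix; this matches the default of the classical analysis
environment for this data type, and the choice matters (correlation PCA
would change the variance fractions, since chromosome totals differ in
scale). The implementation deliberately avoids `princomp()`'s requirement of
more rows than columns, which small map collections violate; a test
cross-checks scores and variance fractions against `prcomp`. Component signs
are fixed by making each component's largest-magnitude loading positive.
Hierarchical clustering uses Euclidean distances and Ward's D2 criterion via
`hclust`, whose merge order is deterministic for a given matrix; trees
export to Newick through `ape`.

Whether to center columns (chromosomes as variables) or rows was an open
choice; columns are centered, treating each chromosome as a variable
measured across maps, which is the orientation in which "per-chromosome
counts of 20 data sets" is a standard multivariate sample.

## The synthetic-data generator

The generator exists so that every stage of the pipeline can be exercised,
end to end, without sequencing data. It emulates:

* hot-spot-structured maps: non-overlapping hot spots placed by a
  stars-and-bars construction (uniform widths 50–500 bp), i.i.d.
  gamma-distributed intensities with shape 0.6 by default — the heavy tail
  reproduces the orders-of-magnitude spread of real hot-spot strengths —
  at 0.3 hot spots per kb (roughly 3,600 on a 12-Mb genome, the scale of
  yeast Spo11 maps);
* multinomial read allocation (1e6 reads per time point by default) over
  hot spots plus 15% uniform background, with triangular within-hotspot
  profiles so smoothing and calling see realistic sub-structure;
* chromosome copy number as a multiplicative weight (diploid baseline),
  and a time-indexed fold boost on one focal chromosome — the signature of
  an engagement-defective chromosome that keeps breaking after the rest of
  the genome has stopped (1.4-fold at 4 h, 2.0-fold at 5 h in the package's
  standard scenario);
* optional per-domain modulation factors (telomere/centromere/rDNA
  suppression, EAR persistence);
* kinetic time courses drawn from the exact fitted model families plus
  Gaussian noise, clamped at zero because the assays report non-negative
  quantities.

Every generator is a pure function of its scenario and a mandatory seed, and
restores the caller's RNG stream. The fold boost is a multiplicative weight,
not a mechanistic break-accrual process: the pipeline measures relative
maps, so simulating absolute accrual would add machinery without adding
test power.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: mappability artifacts and multi-mapping
loss, GC or chromatin covariates of Spo11 cleavage, sequence-motif
preferences within hot spots, biological covariance between hot-spot
strength and domain context, library-preparation biases, and the real
genome's size-vs-density anticorrelation (which the generator only produces
if asked). Agreement between caller and oracle, and recovery of planted
folds, validate the *computations*, not the biology.

### Problem sizes used in the shipped checks

The test suite and acceptance script run the caller-vs-oracle equivalence on
1,000 random maps of 2–30 kb, kinetic Monte-Carlo recoveries with 200
replicates each, and the end-to-end aneuploidy experiment on a 3.5-Mb
four-chromosome toy genome at 1e6 reads per map. These sizes were chosen so
the full suite exercises every code path in about a minute while keeping
every statistical check comfortably powered (the fold-recovery check, for
instance, resolves its target to ±1% at three multinomial standard errors).

## Known limitations

* The reader materializes full per-base vectors; a full eukaryotic genome at
  per-base resolution is memory-hungry compared to run-length encodings.
  For the 12-Mb yeast genome this is irrelevant.
* The fixed 0.193 RPM/bp threshold reproduces published calls only on maps
  normalized exactly as published; the fold-over-mean default is
  self-consistent on any map.
* `fit_chip_kinetics` assumes a unimodal profile; bimodal binding
  trajectories will be summarized misleadingly.
* Domain classification is midpoint-based; an interval straddling a domain
  boundary is assigned wholly to its midpoint's domain.
* Sum-mode copy correction rescales the focal chromosome uniformly; it
  preserves totals, not the partner chromosome's spatial profile.
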