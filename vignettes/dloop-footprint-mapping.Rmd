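---
title: "Mapping D-loop footprints from non-denaturing bisulfite long reads"
author: "dloopmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping D-loop footprints from non-denaturing bisulfite long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dloopmapr)
```

## The measurement model

A D-loop on a double-stranded donor exposes one strand — the displaced
strand — as single-stranded DNA. Non-denaturing bisulfite deaminates
cytosines only where DNA is single-stranded, so after PCR and long-read
amplicon sequencing the displaced strand carries a patch of C→T
conversions whose extent marks one D-loop on one molecule. Three signals
structure everything this package does:

1. **Conversion density.** A spiked fully single-stranded control
   converts at about 58 % per cytosine under the assay's room-temperature
   conditions; duplex DNA converts only sporadically, through transient
   "breathing" of the helix. A footprint is therefore a *density* signal
   over consecutive cytosines, not the presence of individual
   conversions.
2. **Strand identity.** Each read derives from one strand of one
   molecule. Conversions on the displaced (top) strand appear as C→T in
   reference orientation; conversions on the complementary strand appear
   as G→A. Predominance of one over the other assigns the read's strand.
3. **Topology.** On a covalently closed negatively supercoiled donor,
   every 10.4 bp of heteroduplex absorbs one negative supercoil, so the
   donor's supercoiling density σ caps footprint length at
   |σ|·L — about 210 nt for σ = −0.07 on a 3 kb plasmid
   (`supercoil_capacity()`). Linear donors are capped only by the
   homology length.

## The pipeline and its parameters

### Conversion tracks (`call_conversions`)

For every reference cytosine covered by a read, the status is
`converted` (read shows T), `unconverted` (C), or `masked` — and
symmetrically G→A for the bottom-strand candidate. Mismatches to any
other base are masked rather than counted as unconverted: they are
sequencing errors and carry no conversion information. Long-read indels
are the dominant artifact, so every reference position within 5 nt of an
indel (insertions mask around their anchor base) is masked; masked
cytosines are excluded from all tallies and from window denominators.
Conversion counts are computed after masking.

Reads shorter than 50 % of the expected amplicon length are discarded
(boundary inclusive: exactly half is kept). Strand assignment then uses
two rules: if both the C→T and G→A counts are below 6 the read is
`unknown` (too little signal); if the two counts are within 10 % of the
larger one the read is `unknown` (ambiguous); otherwise the larger count
wins. The 10 %-of-the-larger formalization was chosen because it is
scale-free and symmetric under swapping strands.

### Peak calling (`call_peaks`)

The footprint caller slides a window of `w` consecutive *unmasked*
cytosines across the whole read, one cytosine at a time — windows are
defined in cytosine counts rather than nucleotides so that C-poor
stretches do not dilute the statistic, and the scan is not restricted to
the homology window so that genuine background patches can be seen and
quantified. A window is positive when its converted fraction is at least
`t` (ties pass: 20/50 meets t40w50). Maximal runs of *consecutive*
positive windows merge into one peak; a failing window terminates the
run, so two positive runs separated by a failing window yield two
footprints even if their spans overlap. Peak boundaries are trimmed to
the outermost converted cytosines within the run's coverage — extension
beyond the homology can only ever be driven by converted cytosines, and
unconverted tails are never included. Footprint length is `end − start`,
the 3′ boundary minus the 5′ boundary in nt.

The default threshold `t40w50` sits below the 58 % single-strand
conversion efficiency (so true footprints are rarely rejected) and far
above what duplex breathing can assemble over 50 consecutive cytosines.
`threshold_grid()` reproduces the threshold-selection workflow:
sensitivity falls and specificity rises monotonically with `t`, and the
cytosine coverage of peaks at a higher `t` is nested inside the coverage
at a lower `t` at fixed `w`.

The window also sets a detection floor. `min_detectable_length()`
reports the range of genomic spans a single window of `w` cytosines can
occupy on a given reference: with ~20 % cytosine density, w50 cannot see
footprints much shorter than ~120–200 nt, and a 43-cytosine homology
(the 197 nt substrate) cannot host a w50 window at all — such substrates
are analyzed with smaller windows at the cost of more background.

### Profiling

`percent_peak()` divides footprint-containing reads by total reads per
strand (a multi-footprint read counts once; each footprint still enters
the length and position statistics). Position distributions bin each
footprint's closed interval into 100-nt bins tiling the homology window
*non-exclusively* — a footprint contributes to every bin it overlaps by
at least 1 nt, and bin values are normalized by the total footprint
count, so they do not sum to 1. Bins anchor at the homology start and
the final partial bin is kept, because the 3′ edge is exactly where the
position signal concentrates. Footprint maps cluster reads 5′→3′ by
(first footprint start, end, read id) and encode each cytosine as
unconverted / converted / in-footprint / masked; the text matrix parses
back to the per-read union of footprint intervals exactly.

## The synthetic-data generator

`simulate_dataset()` emulates the features of the real data that the
pipeline's decisions rest on, with per-molecule ground truth:

* D-loop incidence per molecule (default 0.15, between the ~13 %
  measured from footprints and the ~22 % measured on gels — footprint
  detection loses some nicked top strands).
* Position law: the 3′ edge of the D-loop is drawn with a linearly
  increasing weight toward the homology 3′ end (`three_prime_biased`),
  reproducing the observed 3′ enrichment; a `uniform` law is available.
  The exact in vivo law is unknown, which is why it is a parameter and
  not an assertion.
* Length law: truncated normal (mean 210, sd 50) capped by
  `supercoil_capacity()` for supercoiled donors; `length_uniform()`
  reproduces the broad range seen on linear donors; `length_fixed()`
  for exact tests. Draws never exceed the topology or homology cap.
* Conversion: each displaced-strand cytosine inside the D-loop converts
  with probability 0.58; *every* duplex cytosine (both strands, and
  top-strand cytosines outside the D-loop) converts with the breathing
  rate. Breathing is modeled i.i.d. per cytosine — the simplest null
  consistent with threshold-based filtering; real breathing may be
  weakly clustered, which would only make the window threshold more,
  not less, necessary.
* The breathing default is 0.02 per cytosine. This is the operating
  point consistent with the observed read pools: an unconverted duplex
  read has several hundred scorable cytosines, and fewer than ~5 % of
  reads fall below the 6-conversion strand-assignment floor only if the
  background contributes on the order of ten conversions per read. At
  0.02 a positive t40w50 window would require a ~20-sigma breathing
  excursion, so specificity is unaffected.
* Read sampling: bottom:top ratio 2 (nicking of the uracil-containing
  displaced strand depletes top amplicons), 1-nt indels at 0.001/base,
  and 1 % of reads truncated below half length to exercise the length
  filter. Reads are emitted pre-aligned (position 1, CIGAR carrying the
  indels): read mapping itself is upstream of this package's scope.

`simulate_ssdna_control()` reproduces the spiked single-stranded
control used to measure conversion efficiency (every cytosine converts
at the configured efficiency, no strand logic).

What passing tests on this generator do *not* show: robustness to
mapping errors, chimeric or duplicate reads, PCR bias beyond the strand
ratio, clustered breathing, RPA-occlusion patterns within D-loops, or
branch migration during treatment. Those enter upstream of the modeled
interface or are summarized by the two net-effect knobs (conversion
efficiency, strand ratio).

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; human-readable TSVs add
  1-based inclusive columns, and BED output is standard 0-based
  half-open (`[start, end + 1)` around the closed cytosine interval).
* Window positivity uses `fraction >= t` with a 1e-9 slack so that exact
  ties (20/50 at t40) pass regardless of floating-point representation.
* The topology cap is computed as a real number and rounded only for
  display; the simulator floors it before drawing integer lengths.
* Reads with fewer unmasked cytosines than `w` yield no footprints;
  empty tracks, zero-molecule simulations and zero-footprint summaries
  return empty (not zero-filled) structures, except `percent_peak(0, n)
  = 0` and `percent_peak(n, 0)` which is an error, not 0.
* Sample SD of a single footprint length is reported as `NA`, not 0.
* Strand-ambiguous (`unknown`) reads pass through track construction but
  are excluded from peak calling and summaries; the pipeline logs the
  full accounting (input = kept + length-filtered + unknown).

## Problem sizes

The shipped tests and demo run at desk scale, chosen to keep the whole
suite in a few minutes while leaving the stochastic properties
well-resolved: simulations of 120–2,000 molecules on the 3 kb donor,
500 random tracks of up to 200 cytosines for the caller-vs-oracle
equivalence check, and 1,000 D-loop-bearing reads for the
boundary-recovery property (recovery ≥ 90 % with boundaries within the
local span of 10 cytosines, run at breathing 0.005, within the regime
where that guarantee is claimed). Larger runs only sharpen the same
estimates.

## Known limitations

* Footprint boundaries are conversion-limited: at 58 % efficiency the
  called boundary sits a geometrically distributed few cytosines inside
  the true junction, and a breathing conversion adjacent to a D-loop can
  extend a boundary slightly outward. Near the detection floor, lengths
  are overestimated (a sub-window footprint borrows neighboring
  cytosines or is missed entirely).
* Strand assignment needs background conversions: with no breathing at
  all, duplex-only reads are `unknown` by construction rather than
  assigned to a strand.
* Multi-invasion of several donors by one substrate is invisible by
  design (each donor molecule is one read); two footprints on one read
  are reported but not interpreted.
* The binned position distribution dips in the final ~100 nt of
  homology even under a 3′-biased truth law: a footprint's 3′ boundary
  cannot pass the last cytosine, and the terminal bin overlaps fewer
  footprint intervals. This is an edge effect of the method, shared
  with the assay itself.
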