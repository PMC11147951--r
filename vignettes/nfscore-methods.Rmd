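---
title: "Scoring nucleosome formation from DNA shape power spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring nucleosome formation from DNA shape power spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfscore)
```

## The problem and the model

A nucleosome wraps 147 bp of DNA around a histone octamer, and part of what
decides where nucleosomes sit is encoded in the DNA sequence itself: a ~10-bp
periodic placement of flexible AA/TT dinucleotides eases bending around the
octamer, while stiff poly(dA:dT) tracts resist wrapping. `nfscore` turns that
intuition into a sequence-intrinsic *nucleosome formation (NF) score* in
three stages:

1. **DNA shape.** A 147-bp sequence is translated into four structural
   profiles via a pentamer lookup table: minor groove width (MGW, Å) and
   propeller twist (ProT, °) per base pair, and helix twist (HelT, °) and
   roll (°) per base-pair step. Each pentamer predicts MGW/ProT at its
   centre and the two steps flanking the centre; steps predicted by two
   pentamers are averaged, and the value reported at a position is the mean
   of its flanking steps. The edges lose 4 values per central channel and 2
   per step channel, so a 147-bp sequence carries
   `4 * 147 - 12 = 576` defined shape values.

2. **Power spectra.** Each channel's series is demeaned, tapered with a
   split cosine bell (fraction 0.1 per end), Fourier transformed
   (`power = |DFT|^2 / n`), and smoothed with a modified Daniell kernel of
   total span 10 (11 weights, half-weight endpoints; circular smoothing over
   the two-sided spectrum, which for a real series equals reflection at the
   one-sided boundaries). Keeping frequency bins 1–72 per channel halves the
   576 two-sided coefficients into **288 features** named `MGW_1 … Roll_72`;
   `HelT_5` is the power of the HelT profile at ≈5 cycles per 147 bp. The
   spectrum is what makes the representation tolerant to where along the
   fragment the periodic signal sits — a circular shift moves every raw
   value but barely any power.

3. **Classification.** A random forest (500 trees, `mtry = 16 =
   floor(sqrt(288))`, unlimited depth, no class weights — the defaults of
   the `randomForest` implementation) is trained on labeled 147-bp fragments
   (1 = nucleosomal, 0 = linker). Its per-window vote fraction drives two
   genome tracks: the **low-resolution score** writes each window's binary
   call to its central 50 bp (window offsets 48–97; left-biased by one
   because 147 − 50 is odd), and the **high-resolution score** slides by
   7 bp — a divisor of 147, so every interior base pair sits in exactly
   147/7 = 21 windows — and reports the fraction of covering windows called
   nucleosomal (14 of 21 ⇒ 14/21 = 0.67).

Alongside the score the package carries the interpretation machinery used
with it: strand-aware mean profiles of any per-bp track around interval
anchors (narrowPeak summits, 5′ ends, exon midpoints, intron/exon
junctions), length-quantile stratification, and a multi-sample DNase
accessibility count (the *DHS score*: at each base pair, how many peak files
contain a peak overlapping it — 403 means "all 403 cell lines").

## Numerical choices

**Series length standardization.** The channels carry 143 (MGW/ProT) and
145 (HelT/Roll) defined values; a single even length is needed so that four
72-bin blocks make exactly 288 features. We standardize to 144 by
*duplicating the central (72nd) value* of a 143-series and *dropping the
central (73rd) value* of a 145-series. Both edits are fixed points of
positional reversal, which buys an exact symmetry: with a
reverse-complement-symmetric pentamer table, a sequence and its reverse
complement produce identical feature vectors to machine precision (~1e-15).
Edge-anchored alternatives (replicating the last value, or dropping it)
break that symmetry at the 1e-2 level, because a cosine taper applied after
an asymmetric edit no longer commutes with reversal; a strand-symmetric
featurization was judged the more defensible property, and the central edits
reproduce the 576/288 bookkeeping exactly.

**Spectrum conventions.** The zero-frequency bin is excluded (the series is
demeaned; before smoothing it is replaced by the mean of its neighbours so
it cannot distort bins 1–5) and the Nyquist bin is included — both required
to reach 72 bins per channel. The normalization `|DFT|^2 / n` makes
Parseval's identity exact: untapered and unsmoothed, the two-sided power
sums to the sum of squares of the demeaned series (tested at 1e-6
relative). The whole pipeline reproduces R's classical smoothed periodogram
(`spec.pgram`) bin-for-bin when untapered, and up to that implementation's
constant taper power correction otherwise; the tests use it as an
independent oracle rather than calling it from the package, since the
featurization is the method's core and should be explicit.

**Ties and conventions elsewhere.** A window with vote fraction exactly 0.5
is called nucleosomal (deterministic, documented). Interval arithmetic is
0-based half-open throughout, matching BED bit-for-bit; midpoints floor
(left-biased for even lengths); unstranded intervals profile as `+` with a
logged count; narrowPeak summit offset −1 falls back to the midpoint only on
request. High-resolution edge base pairs keep their true (smaller) coverage
as denominator — the score stays a vote fraction — with `drop_partial` to
trim them instead. Windows containing any non-`ACGT` base are excluded from
both numerator and denominator, never imputed; `compute_shape` itself
refuses ambiguous bases so that masking stays the scanner's explicit job.
The genome grid phase of the sliding windows is configurable (`phase`),
defaulting to 0.

**Cross-validation.** Folds are stratified by class — the benchmark is
near-balanced and stratification stabilizes per-fold metrics — and the
report carries accuracy, sensitivity, specificity, F1, AUC (rank method,
ties one half) and MCC (0 substituted for degenerate denominators), each as
mean ± SD over folds plus the pooled confusion. Whether SDs should be taken
across folds of one split or across repeated splits is a genuinely open
convention; we use one split, recording the seed.

## What the synthetic generators emulate

No external data ships with the package; every fixture is generated in code
under a seed.

* `gen_training_set()` emulates the *shape* of an MNase-derived benchmark:
  147-bp fragments, the nucleosomal class carrying AA/TT dinucleotides
  placed with probability `amplitude = 0.8` on a 10-bp grid whose phase is
  random per sequence (so only a shift-tolerant featurization can recover
  it), the linker class carrying one 20–40-bp poly(dA) or poly(dT) tract on
  a uniform background. The periodicity is a placement *bias*, not a hard
  repeat. Default benchmark size for the package's own evaluation runs is
  150 + 150 — large enough for 10-fold folds with 30 held-out examples,
  small enough for desk-scale runs.
* `gen_toy_pentamer_table()` provides complete 1024-entry tables: constant,
  monotone in A/T content, or random-but-rc-symmetric (values drawn per
  reverse-complement pair with the two step values swapped between
  partners). These are synthetic stand-ins; the loader accepts any table
  exported into the documented TSV dialect, including the published
  pentamer shape table.
* `gen_toy_genome()` builds a genome whose score field is controlled:
  linker-like background (uniform composition with a poly(dA:dT) tract
  about every 150 bp) with nucleosome-favourable islands rewritten from
  scratch (fresh background + periodic signal), plus a truth BED.
* `gen_peak_panel()` writes peak-file panels with an exactly prescribed
  per-bp membership count for DHS score validation.

What passing tests on these fixtures show — and what they do not: the
pipeline recovers a planted, strongly separable periodicity-vs-tract
contrast (CV accuracy ≳0.95, AUC ≈1; a label-permuted control sits at
chance), and all bookkeeping, symmetry and aggregation contracts hold
exactly. Real chromatin benchmarks are far noisier (the published benchmark
sits near 82% accuracy / 0.89 AUC); nothing here estimates that number, and
the synthetic margins say nothing about accuracy on real genomes.

**Resolution agreement.** The claim that averaging many low-resolution
(binary) profiles is practically indistinguishable from averaging
high-resolution (vote-fraction) profiles holds when the score field varies
slowly relative to the 147-bp window — as it does across large panels of
promoters. The fixture therefore uses 2-kb alternating domains on a 240-kb
genome and 6,000 strand-randomized anchors; the two mean profiles agree
within 0.005–0.009, against a stated bound of 0.015. Sharp 147-bp islands
are the deliberate worst case — there the aligned window systematically
outvotes the off-aligned ones and the profiles differ by ~0.07 — which is
why island fixtures validate the *scanner*, and domain fixtures the
*averaging claim*.

## Problem sizes and runtime

The package's own evaluation runs use: 300 training fragments for CV
(≈40 s), a 240-kb genome scanned at both resolutions (≈35 s), 6,000
anchors for profile aggregation, and 403-file peak panels. These sizes were
chosen so the complete evaluation re-runs from scratch in about a minute on
one core while keeping every statistical check comfortably powered.

## Known limitations

* Shape tables are lookup-based; recomputing shape from simulation, and the
  electrostatic-potential channel sometimes listed alongside these four, are
  out of scope (only the four-channel reading reproduces the 576/288
  arithmetic).
* Whether the original pipeline padded series to composite lengths before
  the FFT is not reconstructable; the uniform-144 scheme is this package's
  pinned choice.
* The synthetic MNase emulation ignores digestion bias, GC effects beyond a
  configurable skew, and real linker-length distributions.
* Only single-threaded scanning is implemented; genome-scale application is
  linear in genome length (~7 s per 100 kb at step 7 on one core).
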