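# nfscore

Sequence-intrinsic nucleosome formation (NF) scores from DNA shape power
spectra.

Part of what determines nucleosome positioning is written in the DNA itself:
~10-bp periodic AA/TT dinucleotides ease the bending of the double helix
around the histone octamer, while stiff poly(dA:dT) tracts resist it.
`nfscore` implements a classifier-based score built on that signal, for
researchers in regulatory genomics who want a *sequence-only* estimate of
nucleosome support to compare against measured occupancy and accessibility.

The pipeline:

- **DNA shape.** Each 147-bp fragment is mapped to four structural profiles
  (MGW, ProT, HelT, Roll) via a pentamer lookup table; edge losses leave
  4 × 147 − 12 = 576 defined values.
- **Spectral features.** Each channel is demeaned, cosine-tapered (0.1),
  Fourier-transformed and Daniell-smoothed (span 10); bins 1–72 per channel
  give 288 features (`MGW_1 … Roll_72`), a representation invariant to where
  along the fragment the periodicity sits.
- **Random forest.** 500 trees, `mtry = 16`, Gini importances; evaluated by
  stratified 10-fold cross-validation (accuracy, sensitivity, specificity,
  F1, AUC, MCC; mean ± SD).
- **Genome tracks.** The low-resolution NF score writes each sliding
  window's binary call to its central 50 bp; the high-resolution score steps
  by 7 bp (a divisor of 147) so every interior base pair is the vote
  fraction of exactly 21 windows (14 of 21 ⇒ 0.67).
- **Interpretation tools.** Strand-aware mean profiles around anchors
  (narrowPeak summits, 5′ ends, midpoints, intron/exon junctions),
  length-quantile splits, a multi-sample DNase peak count track (DHS score),
  bedGraph/bigWig export, and seeded synthetic generators for every input
  (training sets, pentamer tables, toy genomes, peak panels).

## Worked example

```r
library(nfscore)

tab   <- gen_toy_pentamer_table("rc_symmetric_random", seed = 7)
train <- gen_training_set(synthetic_spec(n_pos = 150, n_neg = 150, seed = 11))
feats <- featurize_set(train, tab)          # 300 x (id, label, 288 features)

cross_validate(feats, k = 10, seed = 3)
#> <nf_cv> 10 fold cross-validation, 500 trees, seed 3
#>   accuracy     1.0000 (+/- 0.0000)
#>   sensitivity  1.0000 (+/- 0.0000)
#>   specificity  1.0000 (+/- 0.0000)
#>   F1           1.0000 (+/- 0.0000)
#>   AUC          1.0000 (+/- 0.0000)
#>   MCC          1.0000 (+/- 0.0000)
```

The planted periodicity-vs-tract contrast is strongly separable, so the
forest recovers it perfectly; a label-permuted control sits at chance
(~50% accuracy, MCC ≈ 0). Scanning a toy genome with five planted
nucleosome-favourable islands and averaging the high-resolution track over
the island midpoints:

```r
model <- nf_train(feats, n_trees = 500, seed = 2)
g     <- gen_toy_genome(20000, 5, seed = 5)
track <- scan_high_res(g$genome, model, tab, step = 7)
prof  <- mean_profile(track, g$truth, mode = "midpoint", flank = 200)
prof[prof$offset %in% c(-200, -100, 0, 100, 200), ]
#> # A tibble: 5 × 3
#>   offset  mean     n
#>    <int> <dbl> <dbl>
#> 1   -200 0.276     5
#> 2   -100 0.248     5
#> 3      0 0.810     5
#> 4    100 0.571     5
#> 5    200 0.381     5
```

The vote fraction peaks at the island centres (0.81 at offset 0) and decays
into the linker-like background. `autoplot(prof)` draws the profile;
`tidy(model)` returns the 288 Gini importances; `write_track(track,
"nf.bw")` exports bigWig.

A thin command-line wrapper ships in `exec/nf` (installed with the package):
`nf simulate training --seed 1 --out train.fa`, `nf train`, `nf evaluate`,
`nf score --mode high`, `nf profile`, `nf dhs`. See `?nf_main`.

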