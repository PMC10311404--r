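---
title: "Detecting selective sweeps with a convolutional window classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps with a convolutional window classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A hard selective sweep — the fixation of a newly arisen beneficial allele —
drags linked neutral variation along with it. Around the selected site this
leaves three classic signatures: reduced nucleotide diversity, a site
frequency spectrum skewed toward rare and high-frequency derived variants,
and a characteristic linkage-disequilibrium (LD) pattern with high LD on
each flank of the target but low LD across it. Classic neutrality tests
summarize one of these signatures into a statistic; `sweepcnn` instead lets
a convolutional neural network (CNN) learn discriminative patterns directly
from the raw haplotype data, and then scans whole regions by sliding the
classifier along the genome. The confounders that plague summary statistics
— population bottlenecks, migration from an unsampled ("ghost") population,
and recombination hotspots — are part of the training vocabulary rather
than nuisance assumptions.

## From SNP data to images

Input data (Hudson `ms` output, VCF, or aligned FASTA) are reduced to an
`n x T` matrix of per-site states: ancestral, derived, or *other* (missing,
gap, ambiguous). Real data are polarized with the VCF `AA` tag (or REF),
or a FASTA outgroup (or majority allele); monomorphic sites and
infinite-sites violations are removed by `filter_sites()`, mirroring the
preprocessing a practitioner applies to phased panels.

A window of `W = 50` consecutive SNPs and step `S` (1 by default) slides
along the matrix, producing `floor((T - W)/S) + 1` windows that overlap by
`W - S` columns. Placing windows on SNPs rather than on physical
coordinates concentrates resolution where there is information. Each window
becomes an `n x W` grayscale image by multiplying the state code by 127:
ancestral pixels are black (0), derived gray (127), everything else
near-white (254). Before entering the network, gray levels are divided by
254 into `[0, 1]` — standard input conditioning that leaves the file format
untouched.

Because windows are defined in SNPs, the genomic span of a window depends
on SNP density; the coordinate a window's probability is assigned to is the
midpoint of its span (the convention is symmetric; first- or last-SNP
anchoring would bias localization directionally).

## The classifier

The default architecture is three "combined" layers — a 3x3 same-padding
convolution with ReLU activation followed by max-pooling of size 2 along
the SNP axis — with 32 filters each, one dense ReLU layer of 32 units, and
a softmax output over the classes (`neutral`, `selection`). The search
space exposed by `cnn_arch()` covers 2–5 combined layers, filter counts
8–64 in constant/increasing/decreasing form, and 1–2 dense layers of
16–64 units.

Several training details are deliberately conventional and exposed as
arguments rather than hidden constants: cross-entropy loss, the Adam
optimizer at its customary 1e-3 rate, batch size 64, a 10% stratified
validation split, and single-precision arithmetic inside the convolutions
(the norm for CNN frameworks). Training runs for 6 epochs by default and
keeps the weights of the epoch with the highest validation accuracy, ties
resolved to the earliest epoch. Pooling uses "valid" semantics (an odd
trailing column is dropped; ties take the left element), so a width
shrinks as `W -> floor(W/2)` and an architecture that would pool a
dimension below one is rejected with an error naming the layer.

Training images are non-overlapping `W`-SNP windows drawn evenly across
each training replicate, for both classes. Two observations motivate this:
scan-time windows come from everywhere in the region, so the neutral class
must include flanking material; and sweep replicates carry several-fold
fewer SNPs than neutral ones (hitchhiking removes variation), which would
otherwise starve and unbalance the selection class. The classes are
rebalanced by downsampling the larger one. The number of windows kept per
replicate (`train_windows`) is a pipeline parameter.

## From probabilities to a selection profile

Classifying `L` windows yields a `2 x L` column-stochastic matrix. The
"selection" row is averaged into a 1D profile by one of three
configurations: a moving average over `k` consecutive windows (SNP mode,
the default; entries are placed at the midpoint of the covered span), an
average over all windows whose centers fall within a bp span (position
mode), or a grid of evenly spaced positions each averaging a surrounding
bp region (grid mode, the natural choice when comparing against tools that
report grid-based scores; grid cells covering no window are flagged `NA`
rather than 0). Averaging can only interpolate: a profile never leaves the
range of its input probabilities.

The sweep call takes the profile maximum as the reported location
(leftmost on ties, flagged) and reports as the sweep extent the maximal
contiguous run of positions around the peak with probability at or above a
threshold (0.5 by default). The extent definition is an operational choice
— the simplest defensible one — and the threshold is exposed everywhere it
is used.

For genome-scan decisions, the per-replicate score is the profile maximum.
A detection threshold is the nearest-rank 95th percentile of the scores of
neutral calibration replicates (for a 5% false positive rate), and a
replicate is called positive iff its score strictly exceeds it. A
replicate too short to host a single window contributes a score of 0 — no
windows, no evidence — and counts as a localization failure.

## The built-in coalescent simulator

Training and evaluation need labeled data, so the package ships a
self-contained coalescent simulator (C++ core) rather than wrapping
external tools. It implements the ancestral recombination graph with
piecewise-constant population sizes, a two-deme continent–island model
with a ghost continent (island lineages migrate backward at rate
`M / size_ratio` per `4 N0` generations and merge into the continent at the
join time), an msHOT-style recombination map (hotspot intervals multiply
the background rate), and infinite-sites mutation. Identical configuration
and seed give byte-identical `ms` output.

Hard complete sweeps use a structured coalescent conditioned on a
deterministic logistic trajectory of genic selection,
`dx/dt = s x (1 - x)`, discretized on a uniform grid of 1000 points,
running from `1/(2N)` to fixation in `(2/s) log(2N - 1)` generations
(about 1151 generations for `s = 0.02`, `N = 50000`). The trajectory is
anchored so fixation occurs at the configured time before the present.
Within the sweep phase lineages carry the allelic class at the selected
site; coalescence happens only within a class, at a rate inversely
proportional to the class frequency; recombination between a lineage's
ancestral material and the selected site re-draws its background from the
current frequency; and the surviving beneficial-class lineages merge at
the sweep origin. Conversions between coalescent units and generations
assume a present-day diploid size of 50 000, configurable.

Times are in units of `4 N0` generations with `N0` the island (sampled)
population. For the continent–island model the join time is interpreted in
`4 Nc` units (continent-scaled), the reading under which the sweep
completes while the island still exists; the interpretation is switchable
(`join_units`).

The named models `dataset-1` … `dataset-101` cover four families:
bottleneck + sweep (severity 0.005–0.5, onset 0.004–0.1, duration
0.0004–0.002, all in `4 N0` generations — published only as ranges, so these
three values must be supplied per run), migration + sweep (join times
log-spaced 0.003–3, the printed endpoints), neutral hotspots (5 kb, 10 kb,
and three 5-kb hotspots at intensities {2, 3, 5, 10, 20, 50, 100}; the
documented columns 2/10/100 fall at positions 1/4/7), and sweep ± hotspot
(intensities {2, 5, 10, 15, 20}). Hotspot locations are centered (single
hotspot) or at 25/50/75 kb (triple); sweeps sit at 50 kb (inside) or 30 kb
(outside the hotspot).

## What the simulator does and does not emulate

The generator reproduces the genealogical consequences of demography,
migration, recombination-rate variation, and genetic hitchhiking, which is
what the classifier learns from. It does not emulate properties of real
panels: mutation-rate heterogeneity, genotyping and phasing error,
polarization error, gaps and inaccessible regions, or soft/incomplete
sweeps. A green test suite therefore certifies the machinery and its
calibration under the stated models — not performance on any real panel,
which depends on how well those models match the data at hand.

## Problem sizes and numerical choices

The published experiments use `theta = rho = 2000` over 100 kb, 1500 + 1500
training replicates and 100 + 100 test replicates per model. This package's
own runs (test suite and `scripts/acceptance.R`) scale the simulations
down; all scale choices are stated here once.

* Hotspot false-positive experiment: `theta = rho = 200` (10x down). The
  binding constraint is spatial resolution — at this density a 50-SNP
  window spans roughly 7 kb and can still resolve a 5-kb hotspot, while at
  20x down it spans ~14 kb and averages the hotspot's local LD signature
  away. 300 + 300 training replicates, a 500-replicate neutral calibration
  set, 100 replicates per hotspot model. The calibration set is large
  because all nine per-model false positive rates share the one estimated
  95th-percentile threshold: percentile noise moves them coherently and
  dominates the variance of their average, so a bigger calibration set is
  the cheapest honest variance reduction available.
* Migration sensitivity experiment: `theta = rho = 100` (20x down; these
  replicates are SNP-rich because the 20x ghost continent contributes deep
  branches). 300 + 300 training replicates, 100 + 100 test replicates.
* Scans step 10 SNPs with `k = 5` profile smoothing; training takes up to
  10 non-overlapping windows per replicate.

One consequence of scaling down must be kept in mind when comparing
against published full-scale numbers: a full-scale neutral migration
replicate offers on the order of 1e5 windows to the maximum, so the 95th
percentile of neutral profile maxima sits near the top of the probability
scale and suppresses the measured sensitivity. At desk scale a neutral
replicate has a few hundred windows, the neutral maxima are lower, and the
same protocol yields a substantially higher true positive rate on the
migration models. The hotspot experiment measures a false positive rate on
a shared threshold and is much less exposed to this depth effect.

Numerical conventions collected in one place: ms positions are printed
with six decimals and mapped to bp by `ceiling(pos * region_len)` with
upward tie-breaking (strict monotonicity is required downstream); pixel
values are exactly {0, 127, 254}; pooling ties take the left element;
checkpoint ties take the earliest epoch; profile peak ties take the
leftmost position and set a flag; the percentile is nearest-rank and
positives are strict exceedances; the sweep trajectory is clamped to
`[1/(2N), 1 - 1/(2N)]` inside the solver to avoid division by zero at the
endpoints.

## Known limitations

* Hard complete sweeps only; soft and incomplete sweeps are out of scope.
* The simulator supports at most 64 haplotypes per run (descendant sets are
  bit masks) and one contig per run.
* Only the first ALT allele of a VCF record is used; additional alleles
  are coded as "other" and the site is removed as an infinite-sites
  violation.
* The sweep-extent rule (threshold contiguity) is one of several defensible
  operationalizations; extents from different thresholds are not
  comparable.
* Whether real-data runs should polarize with the `AA` tag or treat REF as
  ancestral is data-dependent; both are supported and the choice matters
  for the high-frequency-derived signature.

## A minimal session

```{r example}
library(sweepcnn)

cfg <- preset_config("dataset-61", theta = 100, rho = 100)
train_n <- simulate_ms(cfg$neutral, 300, seed = 1)
train_s <- simulate_ms(cfg$selection, 300, seed = 2)

tr <- sweepcnn:::training_images(list(neutral = train_n,
                                      selection = train_s))
model <- fit_sweep_cnn(tr$images, tr$labels, epochs = 6, seed = 3)

rep <- simulate_ms(cfg$selection, 1, seed = 4)[[1]]
prof <- scan_replicate(model, as_snp_matrix(rep), step = 10, k = 5)
plot(prof)
call_sweep(prof)
```
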