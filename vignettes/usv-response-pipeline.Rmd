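---
title: "Characterizing USV-modulated neural activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing USV-modulated neural activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalmod)
```

## What the package computes

`vocalmod` implements an end-to-end analysis of single-unit activity around
rat ultrasonic vocalizations (USVs): syllable segmentation from ultrasonic
audio, splitting of syllables into first and subsequent calls of a bout,
peri-call responsiveness testing, auROC response normalization, unsupervised
discovery of response types, optogenetic identification of projection
neurons via a spike-latency test, and the group-level contingency and
permutation statistics that compare response types across cortical
subregions. Every stage can be exercised on synthetic sessions with planted
ground truth, which is how the test suite and the `analysis/` drivers
validate the pipeline.

## The synthetic session generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed, not tuning knobs.

**USV streams.** Syllables arrive in bouts. Within a bout, inter-onset
intervals are Gamma-distributed with mean 366 ms and SD 64 ms (Gamma rather
than Normal because intervals must be positive; the two parameterizations
match in mean and SD). Bouts are separated by a silent gap of at least 1 s
plus an exponential excess sized to meet the requested bout rate (default
12 bouts/min). Bout sizes default to a geometric distribution with mean 4,
truncated at 1. Syllable durations are Gamma with mean 50 ms and SD 20 ms;
the field reports no canonical duration or bout-length distributions, so
these are stated defaults, not claims about real data. Flat calls are given
frequency extents below 15 kHz and FM calls above, all within the
20–120 kHz band of the 50-kHz call family.

**Spike trains.** Each unit is an inhomogeneous Poisson process with rate
`baseline_rate × gain(t)`. The gain is a product of piecewise-constant
kernels triggered at first-call and subsequent-call onsets; overlapping
kernels multiply, and gains are non-negative, so the rate never goes
negative. The eight canonical profiles are rectangular caricatures of
empirically observed response families: sustained excitation (E1: gain 3 for
0–0.5 s after first calls, gain 2 after subsequent calls), transient
excitation (E2: gain 3.5 for 0–0.1 s, first calls only), sustained (I1),
transient (I2), anticipatory (I3) and delayed (I4) inhibition, a weak
mixed responder (O: gain 1.4 for 0–0.25 s) and a nonresponder (NR: gain 1).
The real types are defined by their data, not parametrically; these kernels
are a modeling choice that makes ground truth recoverable. Sampling uses
thinning against an exact upper bound on the gain (computed by sliding each
excitatory kernel's length over the onsets), so the simulation is exact, not
discretized.

**Audio.** Syllables are rendered as linear chirps with 2 ms Hann ramps over
white noise, by default at 250 kHz sampling (a desk-scale stand-in for
768 kHz recording rigs; configurable). The default amplitude/noise settings
give a ~23 dB tone-to-noise ratio; validation tests run at 10 dB.

**Tagging sessions.** The light protocol is 10 trains of 10 pulses (10 ms at
5 Hz) with 10 s intertrain gaps. A tagged unit emits one evoked spike per
pulse with probability 0.8 at a latency of 3 ± 1 ms (Normal, truncated at
0.1 ms); untagged units are background-only. Evoked and spontaneous mean
waveforms share one biphasic 4-channel template, with averaging noise scaled
by the number of contributing spikes — so an untagged unit's "evoked"
waveform is noisier but still correlated with its spontaneous one, which is
realistic: the waveform criterion rejects contaminated channels, not
untagged units; specificity comes from the latency test.

What the generator deliberately omits: harmonic stacks and vocal-fold
acoustics, female-stimulus session structure, movement covariates, and
electrode drift. Passing tests therefore demonstrate correctness of the
analysis machinery under idealized Poisson/chirp assumptions, not
performance on real recordings.

## Syllable segmentation

The segmenter is a transparent stand-in for dedicated USV software, using
the standard detection parameters: analysis band 20–120 kHz, minimum
syllable duration 5 ms, minimum inter-syllable gap 20 ms. A frame of the
512-sample, 75%-overlap Hann spectrogram is marked active when any in-band
bin exceeds that bin's noise floor, estimated per frequency bin as the
median plus `threshold_sd` robust (MAD-based) SDs across time. Because a
frame is flagged on *any* of ~200 in-band bins, a 3-SD cut marks most
pure-noise frames; the default is therefore 10 robust SDs, which leaves the
chance of marking a noise frame negligible while tonal syllables at 10 dB
broadband SNR exceed it by roughly an order of magnitude (frame maxima of
~70–90 robust SDs in our fixtures). Active runs are shrunk by
(window − step)/2 per side to undo window smearing — without this a 3 ms
tone smears past the 5 ms minimum — then runs closer than 20 ms are merged
and runs shorter than 5 ms dropped. Merging-then-filtering is idempotent.
Onset accuracy on synthetic 10 dB audio is ~1.5 ms, comfortably within the
5 ms tolerance used by the recovery tests.

Two conventions the field leaves open: a frequency extent of exactly 15 kHz
is classified FM (the flat/FM definitions are stated as `<15` and `>15`,
leaving the boundary undefined), and a syllable whose onset follows the
previous one by exactly 1.0 s is a subsequent call (the bout rule is
strictly "> 1 s"). Manual curation of false positives is replaced by the
SNR threshold; there is no interactive step.

## Responsiveness testing

The baseline period is 1.0 to 0.5 s before each first-call onset. Four
two-sided rank-sum comparisons are made — 0.5 s before and 0.25 s after
first calls, 0.25 s before and after subsequent calls — with Bonferroni
correction (×4), and a unit is responsive when any adjusted p < 0.05.

One numerical choice matters here. Comparing the per-trial *0.5 s* baseline
rate directly against *0.25 s* window rates is anticonservative for
low-rate discrete data: at 5 spikes/s the null probability that the
baseline rate exceeds the window rate is 0.526, not 0.5, because the two
rates live on different lattices (multiples of 2 vs 4 spikes/s). With ~100
and ~300 trials this inflates the family-wise false-positive rate to ~9%.
The package therefore tiles the baseline period into sub-windows matched to
each comparison window's duration (one 0.5 s window, or two 0.25 s windows,
per trial), which makes the null supports identical and restores the
nominal level (measured family-wise rate ~4–5% on 1,000 null units, within
the Bonferroni guarantee). The rank-sum test itself enumerates all rank
splits exactly when both samples have ≤ 8 observations (ties handled
exactly) and otherwise uses the tie-corrected normal approximation with
continuity correction; it matches `wilcox.test` wherever the latter is
exact.

## auROC normalization and the response vector

Per-trial spike counts in 50 ms bins spanning −1 to +1 s around onsets are
converted to rates and smoothed along time with a centered 5-bin moving
average (truncated and renormalized at the edges). For each bin, the auROC
compares the across-trial distribution of smoothed rates with the baseline
sample via the Mann–Whitney identity
auROC = P(bin > baseline) + ½ P(bin = baseline): 0.5 means no modulation,
above 0.5 excitation, below inhibition. Whether smoothing precedes or
follows the ROC computation is ambiguous in the source description; the
package smooths the per-trial rows first, which keeps a full distribution
per bin for the ROC (the alternative order can be had by passing
`smooth_bins = 1` and smoothing the auROC course afterwards). The baseline
sample for the auROC is the per-trial 0.5 s rate.

The response vector concatenates the 15 bins covering −0.5 to +0.25 s
around first calls with the 10 bins covering −0.25 to +0.25 s around
subsequent calls: 25 dimensions.

## Type discovery

Features are the first three principal components of the 25-dim vectors of
all responsive units plus log10 of the baseline rate (floored at
0.01 spikes/s), each z-scored. The 2-D embedding uses exact t-SNE
(perplexity 30, 1,000 iterations, PCA initialization, fixed seed — none of
these are externally specified, so they are package defaults). The embedded
density is histogrammed on a 100 × 100 grid over a *square* bounding box
(both axes use the larger span, padded 5%, so the Gaussian smoothing sigma
of 2 bins has the same data-unit extent in x and y; with per-axis scaling,
elongated embeddings grow spurious basins along the compressed axis),
smoothed, and segmented by a watershed transform with a merge tolerance of
0.2 × the peak density — small enough to keep distinct clusters apart,
large enough to absorb sampling ripples. Units on ridge lines or in basins
containing no units are assigned to the nearest unit-occupied basin
centroid. Clusters are named post hoc: excitatory/inhibitory when the mean
post-onset auROC deviates from 0.5 by more than 0.05, `O` otherwise, with
E/I subtypes numbered by descending response duration. The naming is a
labeling convenience, not a claim of matching any published type
boundaries.

On the default planted population (7 responsive types × 70 units, 600 s
sessions, ~100 first calls), the discovered segmentation reaches an
adjusted Rand index of ~0.8 against the planted labels, with 6–7 basins
across seeds; the sustained and delayed inhibitory types are the pair that
occasionally merges.

## Optogenetic tagging (SALT)

For each pulse, the 150 ms pre-pulse baseline is tiled into fifteen 10 ms
epochs and the 10 ms post-pulse window forms the test epoch; each epoch
records the first-spike latency in 1 ms bins or the absence of a spike.
Histograms are accumulated over all 100 pulses and normalized. The null set
is all 105 pairwise Jensen–Shannon distances among the baseline epochs; the
statistic is the median distance from the test histogram to the baseline
histograms, and p = (#{null ≥ statistic} + 1)/106. The +1 correction avoids
p = 0; the attainable minimum 1/106 ≈ 0.0094 sits just below the 0.01
criterion, which is why the criterion is decidable at all — ranking against
the 15 per-epoch *median* distances instead would floor the p-value at
1/16. Under the null the p-value is conservative (stochastically larger
than uniform). The associated information difference is the excess of the
statistic over the median null distance. A unit is light-responsive when
the test-window rate exceeds the 150 ms pre-pulse rate, SALT p < 0.01, and
the Pearson correlation between evoked and spontaneous mean waveforms
(samples of all four channels concatenated) exceeds 0.9. On the default
protocol, 100% of simulated tagged units (reliability 0.8, 3 ± 1 ms
latency) and 0 of several hundred untagged units pass all three criteria.

## Group statistics

Recording sites are split into anterior and posterior parts at
AP = +1.5 mm, with the boundary itself assigned posterior (the published
split says only "divided at"; the choice is configurable). Counts by
region-part and type feed 2 × 2 contrasts tested with Fisher's exact test;
odds-ratio intervals use the sample OR with the Woolf log-normal CI
(`exp(log OR ± z·√(1/a+1/b+1/c+1/d))`), the method that reproduces all five
published region-contrast CIs from the published count table to the printed
two decimals; an exact-conditional OR is available via `fisher.test` if
preferred, but its intervals do not match the printed ones. Cells of zero
get a 0.5 continuity correction. The permutation test for a difference of
medians enumerates all label splits exactly when feasible (≤ `n_perm`
splits) and otherwise samples 5,000 permutations with the +1/(n+1)
correction; its CI is a 5,000-resample bootstrap percentile interval. CIs
are emitted uncorrected even where Bonferroni is applied to p-values,
matching how the published intervals were evidently computed. Note that
complete enumeration for {1,2,3} vs {11,12,13} gives p = 4/20 — besides the
two extreme splits, one more complementary pair reaches the observed
|median difference|.

## Problem sizes and determinism

The validation suite uses 600 s sessions (~110 first calls, ~300 subsequent
calls), 1,000 null units for the type-I calibration, 500 + 200 sessions for
the SALT calibration, and 490 planted units for the type-recovery check;
these sizes give stable Monte-Carlo estimates while keeping a full run in
tens of seconds. Every random stage takes an explicit seed, and
regeneration under a fixed seed is bit-identical; `run_pipeline()` reruns
are byte-identical at the file level.

## Known limitations

Real USV data violate the generator's assumptions in ways that matter:
non-Poisson firing (bursting, refractoriness), rate drift, movement-locked
modulation, harmonic and noisy syllables, and overlapping animals' calls
are all absent. The segmenter is not a substitute for curated USV detection
software on real audio — its detection counts there are not claimed. The
seven-type solution on any real data set is not a reproducible target of
this package; what is validated is that the machinery recovers planted
structure under the stated conditions.
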