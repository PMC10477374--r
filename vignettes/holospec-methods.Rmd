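---
title: "Holo-Hilbert spectral analysis of resting-state EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Holo-Hilbert spectral analysis of resting-state EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holospec)
```

## The problem

Resting-state EEG in early cognitive decline shows a characteristic
redistribution of oscillatory power: slow rhythms (delta, theta) gain power
while fast rhythms (beta, gamma) lose it, with the alpha rhythm behaving
dually — augmented posteriorly, attenuated anteriorly in early disease.
Conventional band power captures only the *carrier* dimension of this change.
The quantity of interest here is one level deeper: how strongly the *amplitude*
of each carrier rhythm itself fluctuates, and at what rate — the
amplitude-modulation (AM) structure of the signal. `holospec` implements a
complete, testable pipeline for this analysis: a two-layer empirical mode
decomposition producing joint AM-by-carrier power spectra, nonparametric
cluster statistics for group contrasts, and a feature-selection plus
classification stage for individual-level discrimination and conversion
prediction.

## The holo-spectral model

### Layer 1: adaptive carrier decomposition

Each 7,000 ms epoch of each channel is decomposed into intrinsic mode
functions (IMFs) by empirical mode decomposition: iterative subtraction of the
mean of the upper and lower cubic-spline envelopes through the local maxima
and minima ("sifting") until the candidate satisfies the two IMF properties
(extrema and zero-crossing counts differ by at most one; local envelope mean
near zero). Sifting stops by the S-number rule — both counts unchanged for
S = 4 consecutive sifts — with a hard cap of 50 iterations. Deliberately
sifting no further than the stop rule demands matters: excess sifting
equalizes amplitudes and destroys the decomposition's dyadic filter-bank
behaviour, which the band grid below relies on. On white noise the package's
EMD halves the mean frequency per mode (ratio 2.0 ± 0.06 across seeds, modes
with at least 14 cycles in the record).

Both layers use the improved complete ensemble EMD with adaptive noise
(iCEEMDAN): at stage *k* the *k*-th EMD mode of each of *E* white-noise
realizations, scaled to a fraction `noise_sd` of the current residual's
standard deviation, is added before estimating the ensemble-averaged local
mean; stage IMFs are differences of successive residuals, so the decomposition
remains exactly complete. With `ensemble_size = 1, noise_sd = 0` it reduces
elementwise to plain EMD. The noise realizations are a deterministic function
of the seed; the decomposed noise ensemble depends only on (length, ensemble,
seed, sift settings) and is cached across calls.

### Layer 2: demodulating the envelopes

Each layer-1 IMF is split by direct quadrature into an amplitude envelope
`a(t)` (cubic spline through the maxima of the absolute IMF) and a unit
carrier whose unwrapped phase gives the instantaneous carrier frequency
`f_c(t)`. The envelope is then itself decomposed (iCEEMDAN again); each
envelope-IMF's own amplitude `b(t)` and instantaneous frequency `f_am(t)`
are extracted the same way, and `b(t)^2` is accumulated, sample by sample,
into the cell (AM band of `f_am(t)`, carrier band of `f_c(t)`) of a dyadic
grid, then divided by the accumulated sample count (time marginal). The grid
bands are Lf (0.5–1 Hz), delta1 (1–2), delta2 (2–4), theta (4–8), alpha
(8–16), beta (16–32) and gamma (32 Hz to the Nyquist frequency, capped at
100 Hz): 27 valid (AM ≤ carrier) cells per channel, of which the 6 diagonal
cells are flagged unreliable (an amplitude modulation as fast as its carrier
is not a well-defined envelope — the Bedrosian condition).

Two accounting decisions deserve emphasis:

* **The layer-2 residue is not counted as AM power.** The non-oscillatory
  level of an envelope is the carrier's unmodulated strength; folding it into
  the lowest AM band would make that band the arg-max for *any* modulated
  signal and destroy the interpretability of the AM axis. When the envelope is
  so flat that no second-layer decomposition is possible (fewer than 4
  extrema), the envelope power is attributed to the lowest AM band and the
  event logged — the constant-envelope limit.
* **Power accounting uses sub-sample-refined envelopes.** Sampled maxima of
  `|x|` systematically undershoot the true envelope when the carrier is
  sampled coarsely (about 10% of power for a 20 Hz carrier at 200 Hz); the
  spectral paths therefore refine each peak by parabolic interpolation through
  its three neighbouring samples. The exported `envelope()` keeps the plain
  interpolating contract (it passes exactly through the sampled maxima), since
  that identity is part of its interface.

### Numerical choices

* Envelope splines use mirror extension of two extrema beyond each end,
  reflecting about the terminal extremum, or about the end sample when it
  protrudes beyond the envelope — the standard boundary treatment for sifting.
* Instantaneous-frequency tracks are median-smoothed over 0.75 s before band
  assignment (`if_smooth_secs`). Raw central-difference estimates wobble at
  the sample level; an AM rate near a band edge (a 4 Hz modulation sits
  exactly on the delta2/theta boundary) would otherwise split between
  neighbouring bands. The window spans several cycles of every carrier of
  interest yet stays below half the slowest AM period of the grid (1 s for the
  Lf band), and a running median preserves monotone frequency ramps (a 5 to
  15 Hz chirp is tracked with < 0.1 Hz RMSE). `direct_quadrature()` itself
  defaults to the unsmoothed estimate.
* 5% of samples at each epoch end are excluded from accumulation (spline end
  effects), and the first/last 5% of every instantaneous-frequency track is
  flagged invalid.
* Instantaneous AM frequencies below 0.5 Hz accumulate into Lf; estimates
  above the top edge are discarded and counted in a leakage diagnostic.
  Carrier estimates below 1 Hz or above the top edge are likewise leakage.
* Degenerate inputs: silent channels produce zero spectra; monotone signals
  are residues (no IMF); envelopes with fewer than two maxima fall back to a
  constant with a warning.

## Group statistics

Group contrasts are two-tailed cluster-based nonparametric permutation tests
on the (channel × AM band × carrier band) cell array. Per cell, a
pooled-variance Student t compares the groups; cells beyond the two-tailed
cluster-forming threshold (`cluster_alpha = 0.05` on the per-cell t, the
convention of the permutation framework; exposed in the API) are clustered by
sign under a declared cell adjacency: same channel and one step along exactly
one band axis, or same cell on channels within 70 mm (sensor neighbourhood
from the packaged 10–20 coordinates). Cluster mass is the summed t; the null
is the maximum absolute cluster mass over random relabelings of subjects —
subjects, not epochs, are the exchangeable units — with the add-one
Monte-Carlo convention `(1 + #{null ≥ |mass|}) / (n_perm + 1)` and a relative
tie tolerance so the identity relabeling is counted as in exhaustive
enumeration. Diagonal (Bedrosian) cells are excluded from clustering by
default. Whether the published analyses clustered across the band axes at all
is not stated in the source literature; the adjacency above is this package's
declared, configurable choice and is reported with results. An optional
per-subject covariate can be regressed out cell-wise before testing (off by
default).

On 4-vs-4 single-cell data the Monte-Carlo p agrees with full enumeration of
all 70 relabelings to < 0.02; on 200 null datasets (n = 15/15, 500
permutations) the family-wise false-positive proportion falls in the nominal
[0.02, 0.09] band.

## Features and classification

Signatures are the per-(channel, valid cell) AM powers — 19 × 27 = 513 on the
default montage. Feature descriptors are the signatures themselves plus all
*ordered* ratios of distinct signatures, n·(n−1) of them; 513 signatures give
exactly 262,656 ratios, which is why ordered-ratios-only is the adopted
reading of that printed total (singles are additionally emitted but tagged).
Ratios are used raw with an ε-floor (default 1e-12) on denominators.

Redundancy pruning is a greedy scan in descriptor order dropping any column
whose absolute Pearson correlation with an already-retained column exceeds
0.95 (deterministic, idempotent). Selection partitions the surviving columns
into consecutive subsets of ≤ 100, fits a LogitBoost of decision stumps per
subset, records per-feature importance as training-loss reduction, pools the
subset winners and re-ranks them with a final fit, returning at most 9
features (below the customary overfitting guard of 10). How subset winners
were merged in the source procedure is unstated; pooled re-ranking is this
package's declared choice, and subset order can be seed-shuffled.

The two boosting learners are implemented here from first principles:
LogitBoost as stagewise Newton fitting of the binomial log-likelihood
(working response `z = (y − p)/(p(1−p))` clipped at ±4, weights `p(1−p)`,
half-step updates, logistic link) and GentleBoost as weighted least-squares
stumps on ±1 labels under exponential-loss reweighting. Both use a
safeguarded step (contribution halved until the training loss does not
increase), making the training loss non-increasing by construction. The
remaining five panel members are established implementations behind a uniform
interface: rpart (decision tree, and a 50-tree stratified-bootstrap bagging
ensemble), e1071 (radial SVM, naive Bayes) and class (k-NN, k = 5), with
z-scoring for the scale-sensitive learners. Evaluation is stratified 10-fold
cross-validation; out-of-fold positive-class scores are pooled into one
confusion matrix (sensitivity defined on the patient class) and one ROC/AUC
per algorithm (pROC). In the end-to-end runs the cohort is first split
≈60/40 (stratified); features are selected and the panel cross-validated on
the training portion, and the best algorithm is rescored on the held-out
subjects. Selecting features on the same training portion that is then
cross-validated mirrors the published procedure and is optimistically biased;
the held-out metrics are the unbiased numbers.

## The synthetic cohort generator

The generator exists so every downstream stage is testable without clinical
recordings. It emulates: 19-channel recordings on the standard 10–20 montage
at 200 Hz in 7,000 ms epochs; five oscillatory components typical of
eyes-closed rest (posterior alpha 10 Hz with a 0.8 Hz modulation, frontal
midline theta 6 Hz, widespread delta 3 Hz, central beta 20 Hz, weak widespread
gamma 40 Hz, each with modulation depth 0.3–0.5 and amplitudes 1.5–8 µV);
a 1/f aperiodic background (spectrally shaped white noise, exponent 1.0,
4 µV SD) independently per channel; and 1 µV white sensor noise. Between-
subject variability is a log-normal gain per component per subject
(σ = 0.2 on the log scale), keeping AM powers positive with realistic spread.
Flat A1/A2 reference channels are appended so the re-referencing path is
exercised.

Group effects multiply the AM power a group expresses at a (channels, AM
band, carrier band) cell, implemented as a `sqrt(multiplier)` amplitude gain
on matching components. No effect sizes are published for the contrasts this
emulates, so the planted magnitudes are this package's choices, made once:
`mci_like_effects()` plants slow-rhythm AM power × 1.8 posteriorly, fast-rhythm
AM power × 0.55 globally, and the dual alpha pattern (× 1.4 posterior, × 0.7
anterior) — moderate effects, clearly detectable at n = 30 per group.

What the generator does *not* emulate — and hence what passing tests cannot
show about clinical data: no volume conduction or head-model mixing (channel
weights are set directly), no non-stationarity beyond the planted AM, no
ocular/muscle artifacts beyond optional amplitude spikes for rejection tests,
no inter-channel correlated noise, and modulation rates are fixed per
component rather than broadband. Synthetic results demonstrate that the
machinery recovers known structure; they say nothing about effect sizes in
real cohorts.

## Problem sizes used in the shipped checks

Simulation sizes were chosen so the full suite exercises every claim at
useful power: planted AM–FM recovery over 50 seeded runs (single channel,
SNR 10 dB, arg-max cell correct in ≥ 90%); EMD dyadic behaviour over 50 noise
seeds; permutation calibration on 200 null datasets of n = 15/15 at 500
permutations; and one full-pipeline cohort of n = 30/30 (one epoch per
subject, ensemble 8, 1000 permutations) for the planted slow-up/fast-down
pattern and classification (best cross-validated AUC > 0.9). The
`iceemdan()` default ensemble is 100 (the method literature's convention);
`holo_config()` defaults to 16 because spectra average over epochs and
channels, and planted-structure recovery is already at ceiling there.

## Known limitations

* The AM estimate inherits EMD's mode-mixing behaviour; modulation at rates
  close to a band edge splits between neighbouring bands (mitigated, not
  eliminated, by the median-smoothed frequency tracks).
* Absolute spectral units are not calibrated against any external standard;
  only relative and contrast quantities are meaningful, which is also why the
  acceptance checks are contrasts, counts and rates rather than raw powers.
* The EDF writer targets the continuous 16-bit EDF subset (no EDF+D, no
  annotations).
* The permutation test assumes exchangeable subjects under the null; the
  optional covariate residualization is a convenience, not a full ANCOVA.
* With one epoch per subject and ensemble 8 the spectra are noisy; real
  analyses should use the full epoch count (about 51 per 6-minute recording)
  and a larger ensemble.

## Reproducing the shipped numbers

```r
# full synthetic study, written to disk with provenance
spec <- cohort_spec(group_sizes = c(CN = 30, MCI = 30),
                    group_effects = list(MCI = mci_like_effects()),
                    n_epochs_per_subject = 1, seed = 2024)
run <- run_discrimination(generate_cohort(spec), out_dir = "run1",
                          holo = holo_config(ensemble = 8, seed = 11),
                          n_perm = 1000, seed = 17)
print(run)
```

`scripts/acceptance.R` recomputes every headline quantity from scratch; see
the README for its interface.
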