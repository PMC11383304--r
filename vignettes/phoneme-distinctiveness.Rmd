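---
title: "Quantifying cortical phoneme distinctiveness from continuous-speech EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical phoneme distinctiveness from continuous-speech EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phondecode)
```

## The analysis problem

When a listener follows continuous speech, the auditory cortex produces a
measurable evoked response to every phoneme. Averaging the EEG time-locked
to all instances of one phoneme yields its *phoneme-related potential*
(PRP): a 61-electrode x 64-sample (0-0.5 s at 128 Hz) fingerprint of how
that category is encoded. The scientific question this package serves is
whether those fingerprints are *distinct* — whether /s/ and /m/ and /i/
occupy separable corners of neural state space — and how distinctiveness
changes with age, hearing status, and acoustic encoding fidelity.

`phondecode` implements the full analysis chain as reusable, tested
components:

1. **`prp`** — preprocessing (resample to 128 Hz, 1-15 Hz minimum-phase
   FIR band-pass, mastoid re-referencing), phoneme selection with
   inventory filtering and instance capping, PRP averaging, and the
   time-resolved separability F statistic.
2. **`decode`** — a compact convolutional classifier in the EEGNet-8,2
   style trained under 20-fold cross-validation with repetitions and
   cohort balancing; accuracy and Shannon-entropy uncertainty.
3. **`relevance`** — DeepLIFT (Rescale rule) attributions of classifier
   decisions to electrodes and time points; dispersion and peak-latency
   summaries.
4. **`rsa`** — representational similarity analysis against binary
   distinctive-feature models ([syllabic], [sonorant], [continuant]),
   with greedy forward electrode selection and a confusion-matrix
   permutation test.
5. **`tracking`** — gammatone-based envelope and onset predictors and
   boosting temporal response functions (TRFs) with unique-contribution
   delta-r and ROI definition.
6. **`stats`** — cluster-mass permutation tests, Welch/Mann-Whitney
   comparisons, RAU and log transforms, WIN SNR-loss scoring, backward
   stepwise AIC regression, residual group analysis, and a permutation
   curve-difference test.
7. **`synth`** — a synthetic-data generator that plants known effects so
   every downstream stage has a recoverable ground truth.

No public recording accompanies the analyses this package operationalizes,
so the synthetic generator is a first-class module: all quantitative
claims in the test suite are claims about planted-effect recovery.

## The synthetic generator and what it emulates

`gen_phoneme_templates()` builds each phoneme's noiseless evoked template
as

    template(p) = base + alpha * sum_f featval(p, f) * component_f
                       + alpha * idiosyncratic(p)

where `featval` is the +-1 coding of the three distinctive features and
each `component_f` is an outer product of a spatial pattern (random
weights over the montage, optionally confined to a known "informative"
electrode subset) and a temporal kernel. The three kernels are Gaussian
bumps centered at 180, 200, and 220 ms with widths 60-80 ms: they are
distinct (satisfying the requirement that each feature has its own
spatio-temporal signature) but overlap around a common *component peak
time* of 200 ms, so that at that latency the Euclidean geometry of the
templates mirrors the binary feature cube. This is what makes both
decoding and RSA recoverable from the same construction: the feature
components carry class structure, and the per-phoneme idiosyncratic
residual (25% of the mean component norm) gives every phoneme an
identity beyond its class so a 12- or 31-way classifier is not ceilinged
at the 5 manner classes.

The generator's dials map onto the effects the analysis measures:

* `alpha` (distinctiveness) scales all identity-bearing structure;
  `alpha = 0` collapses every template onto the shared base.
* `latency_shift` (delta, ms) delays the template insertion relative to
  the annotated onset, emulating slowed cortical responses.
* `kappa` (spatial blur) widens the spatial smoothing kernel
  (`0.15 * kappa` in layout units, head radius 0.5) *before*
  normalization, spreading identity information over more electrodes —
  which lowers relevance dispersion, the effect it exists to emulate.
* `noise_sd` scales 1/f (pink) background noise; pink rather than white
  because EEG spectra are steep and both the 1-15 Hz band-pass and TRF
  estimation behave differently under realistic spectra.

`gen_phoneme_sequence()` tiles the recording with gamma-distributed phone
durations (mean 80 ms, shape 8 — a realistic coefficient of variation for
conversational phone lengths) and draws labels from a Zipf distribution.
The default exponent 0.6 was chosen once so that the most frequent of 32
labels takes a share near 10%, matching the natural-speech skew in which
the schwa dominates; the exponent is a free parameter because per-phoneme
instance counts beyond that anchor are not published.

`gen_participant_covariates()` draws the audiological/cognitive covariate
table from the printed group means and SDs (ABR wave I/V amplitudes,
PTA over 1/2/4 kHz, WIN SNR loss, OSPAN, MoCA). ABR amplitudes are
physically positive, so they are drawn from zero-truncated normals; naive
truncation would inflate the mean (by ~0.007 uV for the younger wave I
distribution, more than the Monte-Carlo tolerance of the recovery tests),
so the underlying location is solved numerically such that the
*post-truncation* mean equals the printed mean. EHF thresholds at
12.5 kHz are only published as group medians (-2.5 and 15 dB HL); they
are drawn as Gaussians centered on those medians with a 5 dB SD, a
typical between-subject spread for extended-high-frequency audiometry.

What the generator does *not* emulate: real phonetic coarticulation
(neighboring events superpose linearly, consistent with the linearity
assumed by PRP averaging), acoustic realism of the speech signal
(envelope bands are 20 Hz-low-passed rectified noise, not formant
synthesis), artifacts (no blinks or muscle), and any nonstationarity.
Passing recovery tests therefore demonstrate that the estimators invert
the generative model they assume — not that real EEG satisfies that
model.

## Numerical and design choices

**Montage and adjacency.** The 61-channel layout is a schematic 10-10
system computed from idealized spherical coordinates; it preserves names
and neighborhood structure rather than digitized positions. Electrode
adjacency is the Delaunay triangulation of the 2-D projected positions
with edges longer than 1.8x the median pruned, which removes the spurious
long hull links Delaunay produces on annular layouts.

**Filtering.** The band-pass is a Hamming windowed-sinc FIR (transition
width 1 Hz, about 423 taps at 128 Hz) converted to minimum phase via the
real cepstrum, then applied causally — so filter energy cannot smear
backward in time ahead of a phoneme onset, which matters when epochs are
time-locked to onsets. Measured response: >=20 dB attenuation at 0.5 Hz,
passband ripple well under 1 dB at 8 Hz. Epochs are baseline-free; the
causal 1 Hz high-pass plays the role a pre-stimulus baseline would.

**The separability F.** At each (electrode, time) cell a one-way
fixed-effects F across single epochs grouped by phoneme; the curve is the
electrode average. Computing F on single-epoch pools (rather than on
sub-averaged replicas) is the only definition with a well-defined
within-phoneme variability, and it is verified cell-by-cell against a
direct ANOVA oracle at 1e-8.

**The classifier.** With no deep-learning runtime in the dependency
stack, the compact CNN is implemented natively (RcppArmadillo): temporal
convolution (8 kernels of 32 samples, same padding), depthwise spatial
convolution over all electrodes (2 filters per temporal filter), ELU,
average pooling by 4, dropout 0.5, separable temporal convolution
(kernel 16), ELU, average pooling by 8, dropout, dense softmax. Training
is Adam at lr 0.01 decayed by 0.7 every 100 epochs, batch 16,
cross-entropy, and the model snapshot at the validation-loss minimum is
the one that predicts the held-out fold. Within the "maximum of N
epochs" contract, training stops early after 8-12 epochs without
validation improvement. Computation is single precision, as is standard
for network training; gradients are verified against finite differences
and attribution runs in double precision (below). Inputs are scaled by
the training fold's global SD — multiplicative only, no centering, so the
all-zero attribution baseline remains meaningful. Folds are stratified by
phoneme label (a 5% test fold would otherwise miss classes); a
config switch stratifies by participant instead. Cohort balancing drops
the surplus participants of the larger cohort at random each repetition,
generalizing the published drop-four rule to any size difference.

**Attribution.** DeepLIFT multipliers propagate from the pre-softmax
score of the target class (completeness is exact there; softmax would
break it) through linear stages as weights and through ELUs by the
Rescale rule (secant slope between input and baseline activation, with
the derivative as the fallback when the two coincide within 1e-9). The
baseline is the all-zero PRP — the natural resting reference after
high-pass filtering. Attributions are computed for all test PRPs toward
the true class, including misclassified ones. The attribution path runs
in double precision so the completeness identity holds to ~1e-7 even
though training is single precision.

**RSA.** Feature RDMs are Euclidean distances between binary feature
vectors; neural RDMs are electrode-space distances per time point;
alignment is Spearman rho over the upper triangle (checked against a
rank-then-Pearson oracle at 1e-12, with RDMs aligned by label before
comparison). Forward selection starts from the top two relevance-ranked
electrodes and adds the next-ranked electrode while the time- and
participant-averaged rho improves, stopping at the first non-improvement;
the objective averages over the full 0-500 ms window. The
confusion-to-RDM mapping row-normalizes the confusion matrix to
prediction profiles and takes Euclidean distances between profiles — a
documented default, since only "derived from the confusion matrices" is
specified upstream. The permutation test shuffles the rows of both
matrices; the default p-value is the standard two-sided
"at-least-as-extreme" proportion, with the literal one-sided variant
("proportion of differences smaller than observed") available as
`mode = "literal"`. Affricates are coded [-continuant] with the stops.

**Tracking.** Gammatone filterbank (4th-order FIR kernels at ERB-spaced
center frequencies, Hilbert envelopes, resampled to 1 kHz), power-law
compression with exponent 0.6, summation into 8 log-spaced bands, and a
simplified rectified-difference edge detector (leaky integrator, 20 ms
time constant) standing in for the neural-inhibition onset model behind
one interface so a faithful port can replace it. Boosting estimates the
TRF by coordinate descent with L1 error: the default step is 0.005x the
response SD following the boosting literature, and kernels are
constrained to sums of 50 ms Hamming basis bumps — implemented by the
exact equivalence "boost spikes on basis-smoothed predictors, then
convolve the coefficient kernel with the basis". Fifteen contiguous
segments are grouped into 5 test folds (3 segments each); one training
segment, rotated per fold, serves as the validation set; fold kernels are
averaged and per-electrode r is computed on each fold's held-out
segments. Predictors at 1 kHz are polyphase-resampled to the EEG rate
before fitting. Noiseless recovery benchmarks in the tests use a coarser
step (0.02x SD) because without noise there is nothing for a fine step to
regularize and the coarse step converges within the iteration budget.

**Group statistics.** The cluster-mass machinery thresholds per-electrode
t values at the two-sided (or one-sided) critical value for uncorrected
p <= 0.05, clusters suprathreshold electrodes of the same sign under the
montage adjacency, and compares each cluster's mass to the permutation
null of the maximum mass (sign flips for one-sample designs, group-label
exchanges for two-sample designs; exact enumeration when the permutation
space is smaller than the requested count). The curve-difference test is
its 1-D analogue over time and replaces generalized additive modelling
for localizing group differences in series data — one inferential
framework fewer, same question answered, at the cost of modelling
smooth participant-level trends. Backward stepwise regression delegates
to `stats::step` (the n ln(RSS/n) + 2k AIC convention); predictors are
z-scored so coefficients are comparable. The RAU transform follows the
Studebaker convention `(146/pi) * (asin sqrt(k/(n+1)) +
asin sqrt((k+1)/(n+1))) - 23`.

## Problem sizes used by the test and acceptance suites

Simulation sizes were chosen so the full suite runs on a single CPU in
well under half an hour while leaving each effect comfortably
recoverable: 12-phoneme inventories, 8 synthetic participants per cohort,
40-50 s of simulated recording per participant with a 30-instance cap,
and the reduced classifier protocol (3 repetitions, 60 max epochs). The
published full protocol (31 phonemes, 319-instance cap, 20 repetitions,
300 epochs, 10,000/5,000 permutations) is the package default wherever a
default is exposed.

## Known limitations

* The schematic montage is adequate for adjacency and topography but not
  for source-level interpretation.
* The boosting iteration cap (`max_iter`) can under-fit strongly driven
  data at the default fine step; raise `max_iter` or the step for
  high-SNR recordings.
* The edge detector is a deliberate simplification of the published
  auditory-nerve onset model; its time constant is a documented default,
  not an authors' value.
* BrainVision/EDF readers are not bundled; recordings enter as in-memory
  matrices (`new_recording`) plus BIDS-style events TSVs, which covers
  the simulation-driven workflows the package tests.
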