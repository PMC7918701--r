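---
title: "Frequency recognition for SSVEP brain-computer interfaces: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency recognition for SSVEP brain-computer interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepTRCA)
```

## The decoding problem

A steady-state visual evoked potential (SSVEP) speller presents `Nf`
flickering targets, each at its own frequency (conventionally an 8–15.8 Hz
grid in 0.2 Hz steps). Gazing at a target entrains occipital EEG at that
frequency and its harmonics; decoding one selection means identifying, from
a short multichannel EEG segment `X` (channels × samples), which of the `Nf`
frequencies drove it. The decision time window `tw` is the critical resource:
a usable online speller needs reliable decisions from 0.2–0.5 s of data, and
the information transfer rate (ITR) rewards exactly that trade-off.

All methods in this package share one decision structure: compute a score
`rho_i` for every candidate frequency `i` and select `argmax_i rho_i`. They
differ in what the score is and what is learned from training data.

### Canonical correlation against sinusoidal references (`cca`)

The classical baseline scores `X` against a reference matrix `Z_i` of
stacked `sin(2*pi*h*f_i*t)` / `cos(2*pi*h*f_i*t)` rows for harmonics
`h = 1..Nh`: `rho_i` is the largest canonical correlation between `X` and
`Z_i`, i.e. the maximum over weight pairs `(w_x, w_y)` of the Pearson
correlation between `w_x' X` and `w_y' Z_i`. It needs no training data, but
it is phase-blind and struggles to separate neighbouring frequencies at
short windows. `Nh` defaults to 5; the appropriate number of harmonics is
hard to pin down in general, which is one motivation for subject-specific
templates.

The solver whitens the cross-covariance and takes its leading singular
value; a relative ridge of `1e-8 * trace/dim` on each auto-covariance
guards against rank deficiency (disable with `ridge = 0`, in which case a
singular input is an error). Weight signs are canonicalized — largest
absolute entry of `w_x` positive, `w_y` oriented for a nonnegative
projection correlation — so that results are reproducible; all decision
scores are invariant to this choice because both operands of every
correlation share the same filter.

### Individual templates and extended CCA (`extcca`)

The individual template `Y_i` is the element-wise average of the training
trials of class `i` — a subject-specific reference capturing the actual
response waveform and phase. The extended method fuses four correlations
per class, each a Pearson correlation of two 1-D projections: the canonical
correlation of `(X, Z_i)` itself; `X` against `Y_i` through the `X`-side
CCA weight of `(X, Y_i)`; the same pair through the `X`-side weight of
`(X, Z_i)`; and through the template-side weight of `(Y_i, Z_i)`. The four
values are combined by the signed-square sum `sum(sign(r) * r^2)`, which
emphasizes strong correlations while preserving the discriminative value of
negative ones. (The projected-pair correlation of two equal-shape matrices
is defined once, package-wide, as the Pearson correlation of their
vectorized, mean-removed entries.)

### Task-related component analysis (`trca`)

TRCA learns, per class, a spatial filter `w` over channels that maximizes
inter-trial reproducibility: with `S` the sum of cross-trial channel
covariances over all ordered pairs of distinct training trials and `Q` the
channel covariance of the concatenated (per-trial centered) trials, `w` is
the leading eigenvector of `Q^-1 S`. Projection through `w` amplifies the
time-locked component shared across trials and cancels spatially correlated
background activity. The standard TRCA score for class `i` is the Pearson
correlation of `w_i' X` with `w_i' Y_i` — each class judged through its own
filter only. An ensemble variant (all filters stacked, `ensemble = TRUE`)
is also provided, since it is common in the literature and motivates the
two-step method.

Numerical choices: covariances divide by the number of samples (the
normalizer cancels in the Rayleigh quotient; fixing it keeps fits
bit-reproducible); each trial is mean-centered per channel before entering
`S` or `Q`, since concatenation without centering would inject inter-trial
offset artifacts; a ridge of `1e-8 * trace(Q)/Nc` stabilizes short-window
fits; the eigenproblem is solved on the Cholesky-symmetrized form; filters
are unit-norm with the largest-magnitude entry positive.

### The two-step method (`tstrca`)

The package's centrepiece reuses the whole bank of TRCA filters as an
ensemble. Candidate class `i` is scored by the correlation vector

    beta_i = ( cor(Y_i, X),                  # no filter
               cor(w_1' Y_i, w_1' X),
               ...,
               cor(w_Nf' Y_i, w_Nf' X) )

— the same template/test pair examined through every class's filter plus
once unfiltered — fused by the same signed-square kernel,
`rho_i = sum_k sign(beta_ik) * beta_ik^2`. When the true class is `i`, all
filters (not only `w_i`) tend to agree that `Y_i` and `X` are correlated,
and averaging over `Nf + 1` views suppresses the variance of any single
projection; this is precisely what helps at short windows, where single
projections are noisy. Restricted to the own-class entry without squaring,
the score reduces exactly to standard TRCA — a reduction the test suite
checks.

### Filter-bank variants (`fbtrca`, `fbtstrca`)

Harmonic structure can be exploited by decomposing the signal into
sub-bands `[b*8, 90]` Hz, `b = 1..Nb` (the M3 scheme), fitting the base
method per band, and combining per-band scores with weights
`s_b = b^-1.25 + 0.25` that compensate for the falling SNR of higher
harmonics. The package combines as `sum_b s_b * sign(r_b) * r_b^2`. Two
conventions required a decision here: the combination rule in the source
formulation elides the band summation and the square, so we follow the
established filter-bank convention of a weighted sum of squared scores; and
we keep the sign because base scores (the fused extended-CCA and two-step
scores in particular) can be negative, and a signed square is monotone —
guaranteeing that a single band with unit weight ranks classes identically
to its base method. The unfiltered correlation `beta_i0` is recomputed per
band (on band-filtered data), for uniformity. `Nb` defaults to 5, placing
the last band at 40–90 Hz.

## Preprocessing

Epochs are band-pass filtered 7–90 Hz with a zero-phase (forward–backward)
Chebyshev Type I filter, order 4 per direction, 1 dB passband ripple —
family and zero-phase application follow SSVEP convention; order and ripple
are this package's declared defaults, as conventional filter-bank-CCA
values. Filtering runs on the full epoch *before* window extraction so
start-up transients stay outside the analysis window. Note that a 1 dB
ripple design legitimately droops passband amplitude by up to 2 dB after
the forward–backward pass; the filter realization is the b/a
transfer-function form of `signal::cheby1` applied with `signal::filtfilt`.

The analysis window starts `latency_s = 0.64` s after stimulus onset
(accounting for visual-system latency) and spans `round(tw * fs)` samples,
half-open on the sample grid, with `t0` tracking the absolute position so
windows remain auditable. Channel selection to the nine occipito-parietal
electrodes (Pz, PO5, PO3, POz, PO4, PO6, O1, Oz, O2) is the standard
montage for SSVEP work.

## The epoch container

Epochs travel as a 4-way array (class × trial × channel × sample) plus
sampling rate, channel labels, stimulus frequencies, `t0`, and an
append-only preprocessing log. On disk this is a single self-describing
serialized file written atomically; round-trips are bit-exact and rewrites
byte-identical (`compress = FALSE` deliberately, so file digests are
stable). An adapter converts benchmark-style (channel, sample, class,
block) arrays, with the axis order declared explicitly — never guessed —
and classes reordered so frequencies are strictly increasing; the file's
declared sampling rate is trusted over any nominal acquisition rate.

## The synthetic study conditions

The generator emulates the structure that makes template- and
reproducibility-based decoding meaningful, at a scale where full
evaluations run in seconds:

* **Task**: 8 classes at 8–9.4 Hz (0.2 Hz spacing, the hard regime where
  neighbouring frequencies are nearly indistinguishable within a short
  window), 6 blocks, 9 channels, 250 Hz, 1.5 s epochs plus 0.64 s latency
  padding.
* **Signal**: per class, a harmonic stack
  `sum_h decay^(h-1) sin(2*pi*h*f_i*t + h*phi_i)` with 3 harmonics and
  decay 0.5 (typical SSVEP harmonic roll-off); the phase `phi_i` is drawn
  once per subject and class and frozen across trials — the time-locking
  TRCA exploits. A `phase_jitter_sd` option breaks it deliberately. The
  source reaches the sensors through one fixed random unit mixing vector
  per subject.
* **Noise**: volume-conducted background EEG is emulated by `Nc`
  independent 1/f ("pink") sources mixed through a per-subject random
  matrix fixed across trials, plus a 10% spatially white sensor floor.
  The spatial correlation is essential: against channel-i.i.d. noise a
  spatial filter has nothing to cancel and the methods this package exists
  to compare would be indistinguishable. White noise remains available as
  an option.
* **SNR**: defined at the sensor level *on the analysis band* (7–90 Hz,
  periodogram power averaged over channels) and calibrated exactly per
  trial; `snr_db = Inf` gives the noise-free limit in which every trial
  equals its class template and every method is exact.

What the generator does **not** emulate: real-EEG nonstationarity, trial-to-
trial amplitude variation, eye blinks, electrode drift, or response
waveforms that deviate from a fixed harmonic stack. The last point matters
when interpreting simulation results: because the noise-free source is
exactly a harmonic stack, sinusoidal references form a perfect basis for
it, so the extended CCA performs relatively better here than on real
recordings, where waveform mismatch handicaps it. Passing simulation tests
therefore validates correctness and the main qualitative orderings, not
benchmark-scale effect sizes.

## Evaluation protocol

Leave-one-block-out cross-validation: each of the `Nt` blocks serves once
as test data, the decoder is fitted on the remaining blocks, and all `Nf`
trials of the held-out block are classified. Accuracy is averaged per fold
then over folds (with balanced folds this equals the pooled decision
accuracy; the equality is tested). ITR uses `T = tw + 0.5` s, the 0.5 s
being the conventional gaze-shift allowance, and is computed per fold then
averaged — which is why mean accuracy and mean ITR need not jointly satisfy
the ITR formula. Precision, recall and F1 are macro-averaged over classes;
with the balanced block design macro and weighted averaging coincide.
`sweep_methods()` produces the long-format table (subject × method × tw)
and `run_evaluate()` writes results as CSV plus JSON summaries with no
timestamps, so identical configurations yield byte-identical artifacts.

```{r example, eval = FALSE}
ep <- bandpass(simulate_subject(snr_db = -10, seed = 1))
fit <- ssvep_decoder(subset_trials(extract_window(ep, 0.3), 1:5),
                     method = "tstrca")
summary(fit)
loocv(ep, "tstrca", tw_s = 0.3)
```

## Problem sizes used by the test suite

The shipped tests and the acceptance script run entirely on generated data:
oracle checks on instances up to 4 trials × 4 channels × 60 samples
(exhaustive naive-loop comparisons), single subjects with 2–4 classes for
fixed-point and limit checks, one 40-class subject for the chance-level
control, and a 10-subject cohort at −10 dB / 0.3 s for the qualitative
method comparison. These sizes were chosen so that a full evaluation is a
seconds-to-minutes affair while every statistic still has enough decisions
(48 per subject per condition, 480 per cohort cell) to be meaningful.

## Known limitations

* Scores and orderings, not calibrated probabilities: no posterior class
  probabilities are produced.
* The per-seed three-link ordering TSTRCA ≥ TRCA ≥ ExtCCA ≥ CCA is fragile
  at the simulator's accuracy ceiling (48 decisions per subject give 2.1%
  accuracy granularity, and the harmonic-stack sources flatter ExtCCA, see
  above); cohort means order as expected, individual subjects near ceiling
  may tie or invert single links by one or two decisions.
* The container format is this package's own serialized layout, readable
  only through `read_epochs()`; adapters for vendor EEG formats are out of
  scope.
* No artifact rejection, re-referencing or notch filtering is provided —
  inputs are assumed cleaned to that level already.
* Offline decoding only; no streaming or asynchronous operation.
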