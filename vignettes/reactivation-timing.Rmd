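---
title: "Inferring the direction and dynamics of neural information flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the direction and dynamics of neural information flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the methods implemented in **reactime**: what each
stage computes, the assumptions it makes, every tunable parameter with its
units and default, and the known limitations. The package addresses a single
scientific question: given time-resolved multivariate recordings (e.g. MEG
sensor arrays) in which a stimulus evokes a rapid feed-forward sequence of
activation patterns, and later trials in which that sequence is *replayed* at
an unknown time and speed, can we recover the **direction** (same order or
reversed) and **speed** of the replay — and detect whether the replay
*alternates* direction rhythmically, the signature of recurrent processing?

# 1. Data model and containers

All analyses operate on `epochs` objects: a numeric array of shape
`trials x sensors x time`, a binary class label (0/1) per trial, a subject id
per trial, a time axis in seconds, and the sampling rate in Hz. The time axis
must be uniform at `1/fs` (tolerance `1e-9` s) and all samples finite.
`read_epochs()` / `write_epochs()` persist these via RDS;
`write_events()` exports trial metadata as TSV.

Assumptions the downstream analyses inherit:

* binary classification only (two stimulus classes);
* classes are meaningfully compared within subject — classifiers are never
  trained across subjects;
* slow spatial drifts common to all trials carry no class information, so
  they can be removed by demeaning (below).

# 2. Decoding: time-resolved shrinkage LDA

`crossval_evidence(train, test, train_times, ...)` trains one linear
discriminant per training time point and evaluates each on every test time
point, producing an *evidence tensor* of shape
`trials x train_times x test_times`.

Procedure, in order:

1. **Demeaning** (`demean_data = TRUE`): for each (sensor, time) cell the
   mean over trials is subtracted. This removes condition-independent evoked
   structure; it assumes that structure is shared across classes.
2. **Class balancing**: within each training fold, the larger class is
   randomly subsampled to the size of the smaller (seeded), so the
   discriminant is not biased toward the prevalent class.
3. **Shrinkage LDA** (`train_lda`): at training time `t` the pooled
   within-class covariance `S` is blended toward a scaled identity,
   `S* = (1 - gamma) S + gamma * nu * I` with `nu = mean(diag(S))`, and the
   weight vector is `w = solve(S*, mu0 - mu1)`. Default `gamma = 0.05`:
   enough regularisation to keep `S*` well-conditioned at typical
   trials-per-fold / sensors ratios, small enough to leave the discriminant
   essentially data-driven. `gamma = 0` recovers textbook LDA exactly (this
   is pinned by an oracle test).
4. **Signed evidence** (`evidence`): the decision value
   `w'(x - (mu0 + mu1)/2)`, with the sign flipped for class-1 trials so that
   positive evidence always means "correct side of the hyperplane". Signed
   distance is used rather than accuracy because it is graded at the single
   trial level — the whole point of the method is single-trial timing.
5. **Cross-validation**: stratified `k_folds = 5` folds. When the test set is
   the training set (within-epoch decoding, used for recurrence analysis),
   each trial's evidence comes from the fold in which it was held out, so no
   trial is ever scored by a classifier that saw it.

`accuracy_matrix(ev)` reduces the tensor to the conventional temporal
generalisation matrix: the fraction of trials with positive evidence at each
(train, test) pair.

# 3. Per-trial reactivation times

`build_table(ev, window, lowpass_hz, peak)` converts each trial's evidence
trace (one per training time) into a single **reactivation time**: the time
of the trace's maximum within `window`.

* `lowpass_hz = 30` (default in the pipeline): traces are low-pass filtered
  before the argmax so the peak reflects the slow evidence envelope, not a
  single noisy sample. The filter (`lowpass`) is a zero-phase 4th-order
  Butterworth, realised in the frequency domain as `|H(f)|^2` applied to the
  FFT of the odd-reflection-padded trace. Zero phase matters: any phase lag
  would bias every reactivation time in one direction. Odd-reflection
  padding (length `min(n - 1, 3 * ceiling(fs / cutoff))`) suppresses edge
  transients that would otherwise attract peaks to the window boundaries.
* `peak = "signed"` (default) takes the argmax of signed evidence —
  appropriate when the class patterns reactivate with their original
  polarity. `peak = "abs"` is available for polarity-agnostic peaks.
* Ties take the earliest time; an all-NA trace is an error, not an NA row.

The result is a `reactivation_table`: one row per (trial, training time)
with columns `subject`, `trial`, `train_time`, `peak_time`. TSV round-trip
via `write_reactivation_table()` / `read_reactivation_table()`.

# 4. Order inference

The core regression is `peak_time ~ train_time`. If the replay preserves the
original order, later training times peak later: positive slope. If replay
is reversed, the slope is negative. The slope *magnitude* estimates the
replay speed relative to the original sequence (a sequence slowed 10x yields
a slope magnitude near 10).

* `fit_order_lm(tab)` — pooled OLS over all rows; reports `beta0`, `beta1`,
  their standard errors, the slope t statistic, residual dof, and p value.
* `fit_order_lmm(tab)` — fits five candidate mixed models via **lme4**
  (maximum likelihood, `REML = FALSE`): no random terms, subject intercepts,
  trial intercepts, subject + trial intercepts, subject intercepts + slopes.
  The winner is the candidate with the **lowest BIC** (the standard reading
  of "BIC-preferred"; BIC is reported for every candidate so the full table
  can be inspected). Non-converging candidates are excluded rather than
  silently retained.
* `subject_level_fit(tab)` — averages peak times within subject x
  train_time first, then fits subject-intercept models; requires at least 3
  subjects. This is the conservative analysis when trial-level
  exchangeability is in doubt.
* `shuffled_control(train, test, settings, seed)` — re-runs the *entire*
  pipeline (decoding included) with class labels permuted **within
  subject**, and fits the same regression. Permuting within subject keeps
  the per-subject label multiset intact, so the null preserves everything
  except the label-pattern association.

Inference uses the t distribution with residual degrees of freedom. For the
mixed models this is the large-sample approximation (no Satterthwaite
correction); with the row counts these analyses produce (thousands of rows),
the approximation is inconsequential.

`realign(epochs, tab, fit)` re-cuts each trial at its per-trial peak sample
for each training time and attaches the regression-implied time axis
`beta0 + beta1 * train_time`, so realigned class differences can be compared
against the original sequence patterns.

# 5. Spectral characterisation

* `morlet_power(x, times, freq, cycles)` — complex Morlet convolution.
  The wavelet is sampled on `t in [-0.5, 0.5]` s at the data's `1/fs`, with
  `sigma_t = cycles / freq` (the "cycles" parameterisation; `scaling =
  "radian"` gives the alternative `cycles / (2 pi freq)`). Power outside the
  wavelet's support is marked by a `"valid"` attribute rather than silently
  returned.
* `fft_spectrum(x, times)` — Hanning-tapered FFT amplitude spectrum
  (`Mod/n`, frequencies up to Nyquist at spacing `fs/n`).
* `coherence_at(x, y, freq)` and `coherence_permutation_test(...)` —
  trial-averaged single-window coherence at the nearest frequency bin, with
  a per-trial trace-swap permutation null (default `n_perm = 10000`) and
  Benjamini–Hochberg correction across tested frequencies. Two-sided p
  values use the `(exceed + 1)/(n_perm + 1)` convention, so p is never
  exactly zero.
* `xcorr_lag(x, y, max_lag, fs)` — the lag maximising the Pearson
  correlation; **positive lag means `x` leads `y`**. Given trial matrices it
  also bootstraps a CI over trials.

# 6. Phase parsing and the Recurrence Index

Recurrent processing is operationalised as *rhythmic alternation of replay
direction*. The analysis window (default 0–400 ms post-stimulus) is split
into phases in one of two ways:

* `fixed_freq_phases(freq, window)` — half-period tiles of a fixed rhythm;
  at 10 Hz over 400 ms: eight 50 ms phases with alternating nominal
  direction. Used when the rhythm is hypothesised a priori
  (`phases = "freq:10"` in `pipeline_config`).
* Data-driven: `emd()` (hand-rolled empirical mode decomposition: cubic
  spline envelopes with 2-extrema mirror extension, standard-deviation
  sifting threshold 0.2, at most 50 sifts; reconstruction is exact to
  floating point), `select_imf(dec, n_extrema = 8)` picks the intrinsic
  mode whose extrema count is nearest the target (ties go to the faster
  mode), and `segment_phases()` cuts phases between successive extrema.
  The target of 8 extrema corresponds to a 10 Hz mode over 400 ms.

`phase_slopes(ev, train_phases, test_phases, ...)` then fits, for every
(train phase i, test phase j) pair, the pooled OLS slope of per-trial peak
time (within test phase j) on train time (within train phase i). Slopes are
stored with per-trial contributions `c_t` such that `slope = mean(c_t)`,
which makes trial bootstrap of any linear functional of the slope matrix an
O(1)-per-resample operation.

`hypothesis_matrix(test_phases, train_phases)` encodes the alternation
hypothesis: `+1` where the two phases share nominal direction (replay should
run forward: positive slope expected), `-1` where they differ. The
**Recurrence Index** is the dot product

`RI = sum_ij H_ij * slope_ij`

computed by `recurrence_index(slopes, H, n_boot, level, null_slopes)` with a
percentile trial bootstrap CI (default `n_boot = 10000`, `level = 0.95`) and
a permutation p value against shuffled-label slope matrices when supplied.
`neighbor_ri()` contrasts near-diagonal (|i − j| <= 1) against distant phase
pairs, each normalised by its pair count, to separate local from long-range
recurrence.

# 7. End-to-end pipelines

`pipeline_config()` collects all tuning parameters in one place:

| parameter | default | units | role |
|---|---|---|---|
| `train_window` | `c(0.070, 0.130)` | s | feed-forward window; at 300 Hz contains 19 training time points |
| `test_window` | `NULL` (full epoch) | s | where evidence is evaluated |
| `folds` | 5 | – | stratified CV folds |
| `gamma` | 0.05 | – | LDA shrinkage |
| `lowpass` | 30 | Hz | evidence smoothing before the peak |
| `phases` | `"freq:10"` | – | `"freq:F"` or `"emd"` |
| `phase_window` | `c(0, 0.4)` | s | recurrence analysis window |
| `boot` | 10000 | – | bootstrap resamples |
| `n_null` | 1 | – | shuffled-label pipeline re-runs for the RI null |
| `seed` | 1 | – | master seed; all sub-analyses derive seeds from it |

`run_reversal_analysis(train, test, config)` decodes **per subject**, pools
the reactivation tables, and reports the OLS fit, the mixed-model selection,
an optional shuffled-label null fit, the subject-mean accuracy matrix, and
the **accuracy-ridge statistic**: for each subject, the Spearman correlation
between each training time and the test time of its maximal accuracy,
averaged over subjects (`ridge_rho`). Accuracy is a within-subject quantity
— decoders never cross subjects — so the ridge statistic is defined per
subject first. The scientific contrast this supports: under heavy trial-wise
onset jitter the trial-averaged accuracy matrix loses its ridge
(`|ridge_rho|` small) while the per-trial slope still recovers order and
speed, because averaging destroys structure that survives at the single
trial level.

`run_recurrence_analysis(epochs, config)` decodes within-epoch, parses
phases, computes the slope matrix, the RI with bootstrap CI, `n_null`
shuffled-label RI replicas (labels permuted within subject; the full
pipeline re-run each time), and the neighbor contrast.

Reports serialise to JSON via `write_report_json()`.

# 8. The synthetic generator

`sim_config()` / `simulate_dataset()` generate ground-truth data for
validation. The generator's defaults are the package's study conditions —
they were fixed before the confirmatory analyses and are not adjusted per
run.

* **Sequence**: 5 random sensor patterns (20 sensors), each normalised to
  unit norm, played as 50%-overlapping Hann envelopes across a 60 ms
  sequence; pattern `k` peaks at `(k-1)/(n-1)` of the sequence duration, so
  the first pattern peaks at sequence onset. The training sequence runs at
  0.070–0.130 s (19 grid points at `fs = 300` Hz).
* **Replay**: the test sequence is the same pattern train slowed by
  `slowdown = 10` (600 ms), in the same or reversed order, with per-trial
  onsets drawn from a Gaussian (`onset_mean = 0.8` s, `onset_sd` 0.1 or 0.5
  s). Onsets are **not clipped**: they stay exactly Gaussian and sequences
  are simply truncated by the 2 s trial window. Clipping onsets into the
  feasible range was considered and rejected: at `onset_sd = 0.5` it piles
  roughly a fifth of trials onto two fixed boundary onsets, which both
  shrinks the realised jitter well below nominal and manufactures a
  deterministic accuracy ridge — defeating the purpose of the jitter
  manipulation.
* **Noise**: multivariate AR(1) ongoing activity. The shipped coefficient
  fixture (`inst/extdata/ar1_synthetic_*.tsv`) is a *synthetic* stationary
  model — spatially smooth coefficients rescaled to spectral radius 0.95 —
  generated by `data-raw/make_ar1_fixture.R`; it produces spatially and
  temporally correlated, 1/f-weighted noise. `fit_ar1()` can re-fit such a
  model from any epochs object. Noise is scaled so its stationary standard
  deviation equals `noise_scale`.
* **`noise_scale = 6`** (relative to unit-norm patterns) is the calibrated
  default: cross-validated single-trial peak accuracy lands around
  0.55–0.65 — typical for MEG category decoding — and the
  jitter-dissociation above reproduces (at `onset_sd = 0.5` the subject-mean
  ridge statistic is near zero while the slope keeps the ground-truth sign
  at p < 0.001). At noise comparable to the pattern norm, decoding is
  near-ceiling and the averaged matrix retains a monotone ridge even under
  heavy jitter, which is not the regime of interest.
* `simulate_recurrence_dataset()` generates the recurrence condition:
  within each 50 ms half-period of a 10 Hz alternation the sequence plays
  forward or backward (or constantly forward, `alternating = FALSE`, as the
  negative control).

What the generator deliberately does **not** emulate: lead fields or source
geometry (patterns are abstract sensor vectors), per-trial amplitude
variability, eye/muscle artifacts, or between-subject pattern differences
beyond independent pattern draws. It is a validation instrument, not a
forward model of MEG physics.

Typical problem sizes used throughout the package's own analyses: 10
subjects x 200 trials x 20 sensors x 2 s at 300 Hz for the reversal study;
5 subjects x 200 trials for the recurrence study; these run in tens of
seconds on a single core.

# 9. Known limitations

* **Below-chance structure under label permutation.** With cross-validation,
  permuted-label training folds are slightly anti-correlated with their held
  out folds (a fold's label surplus is the complement of the training
  surplus), so shuffled-label evidence is weakly *below* chance rather than
  exactly at it. At the calibrated noise level the resulting bias in null
  fits is negligible, but at very high SNR shuffled-label null statistics
  can sit slightly away from zero. Correspondingly, a *single* shuffled-label
  RI replica has permutation-to-permutation spread comparable to its own
  trial-bootstrap CI half-width (both scale as `1/sqrt(n_trials)`); users
  wanting a tight null should raise `n_null` rather than rely on one
  replica's CI.
* **Mixed-model p values** use the residual-dof t approximation; for small
  tables prefer `subject_level_fit()`.
* **EMD** is the classic sifting algorithm without ensemble averaging; on
  very noisy traces mode mixing is possible, which is why the fixed
  frequency segmentation is the pipeline default.
* The evidence peak is a hard argmax; multimodal evidence traces are reduced
  to their (earliest) global maximum by design.

# 10. Reproducing the headline numbers

```bash
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes every headline quantity from scratch (all randomness flows from
`--seed`) and writes them as JSON; see the README for details.
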