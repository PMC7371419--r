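# reactime

Infer the **direction, speed, and dynamics of information flow** from
time-resolved multivariate neural recordings (MEG/EEG-style sensor arrays).

## The problem

A visual stimulus evokes a rapid feed-forward cascade: distinct activation
patterns follow one another over a few tens of milliseconds. Later — during
recognition, imagery, or memory replay — the same patterns can reactivate at
an unknown time, at a different (usually slower) speed, and possibly in
**reverse order**. Trial-averaged decoding cannot answer "which way did the
information flow?": if reactivation onset jitters from trial to trial,
averaging smears the sequence and the temporal-generalisation accuracy
matrix loses all order structure.

`reactime` solves this at the **single-trial** level:

1. Train a shrinkage-LDA classifier at every time point of the feed-forward
   window (default 70–130 ms, 19 classifiers at 300 Hz).
2. Apply each classifier to every time point of the test epochs,
   cross-validated, yielding signed distance-to-hyperplane **evidence** per
   trial — graded, unlike accuracy.
3. Low-pass the evidence traces (zero-phase, 30 Hz) and take each trial's
   **reactivation time**: the time of peak evidence.
4. Regress `peak_time ~ train_time` (pooled OLS, and mixed models with
   BIC-based random-structure selection via lme4). The **sign** of the slope
   gives the replay direction, its **magnitude** the slowdown factor, and a
   shuffled-label re-run of the whole pipeline gives the null.
5. For recurrent dynamics, parse the evidence into oscillatory phases
   (fixed-frequency half-periods or empirical-mode-decomposition phases) and
   compute a **Recurrence Index**: the hypothesis-weighted sum of
   phase-pair slopes, positive when replay direction alternates with the
   rhythm, with trial-bootstrap and label-permutation inference.

A synthetic generator with known ground truth (sequential unit-norm sensor
patterns, Gaussian onset jitter, multivariate AR(1) ongoing noise) validates
every stage; its defaults are the package's study conditions.

## Worked example

Simulate a reversed-order replay slowed 10x, with trial-wise onset jitter
(SD 100 ms) and spatially correlated AR(1) noise, then run the full reversal
analysis:

```r
library(reactime)

cfg <- sim_config(n_subjects = 4, onset_sd = 0.1, noise_scale = 2,
                  order = "reversed", seed = 7)
sim <- simulate_dataset(cfg)
print(sim$train)
#> epochs: 800 trials x 20 sensors x 41 samples (fs = 300 Hz, t = [0.03333, 0.1667] s)
#>   classes: 400 / 400, subjects: 4

rep <- run_reversal_analysis(sim$train, sim$test,
                             pipeline_config(seed = 8, boot = 0),
                             shuffle = FALSE)
print(rep)
#> Reversal analysis
#> -----------------
#> order fit [none]: peak_time = 1.816 -7.255 * train_time
#>   slope t(15198) = -47.513, p = 0, BIC = 10696.3
#> mixed model winner [trial_intercept]: beta1 = -7.255, t(15198) = -51.124, p = 0
#> accuracy-ridge rank correlation: -0.981
```

The slope is strongly negative — the replay ran in **reverse** — and its
magnitude (here 7.3 under noise; 9.9 at low noise) estimates the 10x
slowdown. At heavy onset jitter (`onset_sd = 0.5`) the accuracy-ridge
correlation collapses toward 0 while the per-trial slope keeps its sign at
p < 0.001: order information that trial averaging destroys survives at the
single-trial level.

Recurrence: simulate replay whose direction alternates with a 10 Hz rhythm
(forward in one 50 ms half-period, backward in the next), then test for it:

```r
rec <- simulate_recurrence_dataset(seed = 81)
rep <- run_recurrence_analysis(rec$data,
                               pipeline_config(seed = 82, boot = 2000,
                                               n_null = 9, phases = "freq:10"))
print(rep)
#> Recurrence analysis
#> -------------------
#> 8 phases (decreasing/increasing/decreasing/increasing)
#> Recurrence Index = 8.26 (95% bootstrap CI 7.888 to 8.649), permutation p = 0.1
#> shuffled-label RI: -0.122 [-0.341, 0.11]; -0.11 [-0.306, 0.0765]; ...
#> near-diagonal RI 0.13 vs distant 0.1286 (p = 0.58)
```

The alternating data yield a Recurrence Index far above every shuffled-label
replica (its CI excludes 0); a constant-order control
(`simulate_recurrence_dataset(alternating = FALSE)`) yields an RI whose CI
includes 0.

## Package tour

| area | key functions |
|---|---|
| containers & I/O | `epochs`, `window_indices`, `read_epochs`, `write_epochs`, `write_events` |
| synthetic data | `sim_config`, `simulate_dataset`, `simulate_recurrence_dataset`, `fit_ar1`, `default_ar_model` |
| decoding | `crossval_evidence`, `train_lda`, `evidence`, `accuracy_matrix` |
| reactivation timing | `lowpass`, `peak_time`, `build_table`, `realign`, `write_reactivation_table` |
| order inference | `fit_order_lm`, `fit_order_lmm`, `subject_level_fit`, `shuffled_control` |
| spectral | `morlet_power`, `fft_spectrum`, `coherence_at`, `coherence_permutation_test`, `xcorr_lag` |
| phases & recurrence | `emd`, `select_imf`, `segment_phases`, `fixed_freq_phases`, `phase_slopes`, `hypothesis_matrix`, `recurrence_index`, `neighbor_ri` |
| resampling | `bootstrap_ci`, `paired_bootstrap_p`, `permute_labels`, `fdr_correct` |
| pipelines | `pipeline_config`, `run_reversal_analysis`, `run_recurrence_analysis`, `write_report_json` |

The methods vignette (`vignettes/reactivation-timing.Rmd`) documents every
stage's assumptions, all tunable parameters with units and defaults, the
generator's calibration, and known limitations.

A small command-line wrapper lives at `inst/cli/reactime.R`
(`Rscript inst/cli/reactime.R simulate|reversal|recurrence ...`).

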