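# seizecast

Patient-specific seizure prediction and forecasting from scalp EEG, as
an R package plus a reproducible analysis workflow.

People with drug-resistant epilepsy could act on a reliable advance
warning of seizures. The standard EEG approach assumes a *preictal*
state — a window of minutes to an hour before onset in which the EEG
background shifts — and turns its detection into alarms. This package
implements that methodology end to end, on synthetic long-term EEG
with a known ground truth (the clinical databases such work is built
on are access-restricted), together with the statistics needed to
judge such a system honestly and the procedures used to explain its
decisions.

## What is implemented

* **Synthetic long-term EEG** (`sim_config()`, `simulate_patient()`):
  days-long 256-Hz multichannel records with annotated seizures
  (≥ 4 h 30 min apart), 1/f background, posterior alpha, circadian and
  sleep–wake modulation, muscle-artifact bursts, and a configurable
  preictal band-power signature with per-window ground truth.
* **Feature bank** (`extract_features()`): 54 univariate linear
  features per channel in 5-s windows — relative power in 8 spectral
  bands, 28 band ratios, spectral edge frequency (SEF50) and its
  cumulative power, 4 statistical moments, 3 Hjorth parameters,
  decorrelation time, 8 db4 wavelet detail energies.
* **Chronological training** (`chronological_split()`,
  `grid_search_preictal()`, `train_patient_model()`): first three
  seizures for training, preictal duration grid-searched over
  30–60 min by a leave-one-seizure-out alarm-level score, per-feature
  z-scoring, inverse-frequency class weights or segment-wise
  interictal subsampling, stochastic-forest feature selection, and
  either a deterministic weighted logistic regression or a seeded
  voting ensemble of 15 linear SVMs.
* **Firing Power alarms** (`firing_power()`, `generate_alarms()`,
  `classify_alarms()`): moving-average smoothing over the preictal
  span, alarms at 0.7 with an equal refractory period, and correctness
  under a 10-min seizure prediction horizon (lead time within
  `[SPH, SOP]`).
* **Evaluation** (`evaluate_patient()`, `surrogate_test()`,
  `circadian_forecast()`, `compare_forecasters()`,
  `binomial_count_test()`): seizure sensitivity, FPR/h with
  refractory exclusion, time under warning, Monte-Carlo surrogate
  onset-relocation significance testing, and a circadian (±30 min
  around training onset times of day) forecasting baseline.
* **Explanations** (`counterfactual_per_feature()`,
  `counterfactual_ensemble()`, `single_feature_retrain()`,
  `fp_feature_scatter()`, `export_timeplot()`): minimal per-feature
  changes that flip a window decision, single-feature-group ablation
  retraining with aligned Firing Power traces, and the data behind the
  standard scatter and annotated time-series plots.

The methods vignette
(`vignettes/seizure-prediction-methods.Rmd`) documents the model
assumptions, every tunable parameter with its default and rationale,
the numerical conventions, and what the synthetic validation does and
does not demonstrate.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
demonstration patient (30 h, 2 channels, five seizures, a 40-min
preictal signature tripling beta/gamma power) and write their tables
under `results/`:

```sh
Rscript analysis/01_simulate.R   # synthetic patient + annotations
Rscript analysis/02_features.R   # windowed feature matrix
Rscript analysis/03_train.R      # grid search + LR + SVM ensemble
Rscript analysis/04_evaluate.R   # SS, FPR/h, TiW, surrogate, circadian
Rscript analysis/05_explain.R    # counterfactuals, ablation, time plot
```

A condensed session:

```r
library(seizecast)
cfg <- sim_config(n_seizures = 5, record_days = 1.25, n_channels = 2,
                  true_preictal_min = 40, effect_size = 3, seed = 11)
p  <- simulate_patient(cfg)
fm <- extract_features(p$record, features = c("relpower", "moments", "hjorth"))
sp <- chronological_split(fm, p$annotations)

grid_search_preictal(sp$train, sp$train_ann)$best_minutes
#> [1] 40

tr  <- label_windows(sp$train, sp$train_ann, 40)
mdl <- train_patient_model(tr, "lr", seed = 3)
evaluate_patient(mdl, sp$test, sp$test_ann, surrogates = 500, seed = 5)
#> <evaluation> SS 0.50 (2 seizures), FPR/h 0.000 over 14.0 h, TiW 0.36 h
#> <surrogate test> observed SS 0.500, surrogate mean 0.001, p = 0.0040
#>   (above chance at alpha = 0.05)
```

Read: one of the two held-out seizures was preceded by a valid alarm
(lead time between 10 and 40 min), no false alarms occurred over 14
interictal hours (refractory time excluded), the system spent about
22 min under warning, and the fixed alarms re-scored against 500
random relocations of the test onsets beat chance (p ≈ 0.004). On the same
patient the circadian baseline, warned ±30 min around the training
onset times every day, catches neither test seizure while spending
more time in warning — the pattern the EEG-based forecaster is
supposed to beat.

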