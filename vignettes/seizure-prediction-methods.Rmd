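---
title: "Patient-specific EEG seizure prediction: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-specific EEG seizure prediction: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Patients with drug-resistant epilepsy could act on a timely warning —
take rescue medication, avoid hazardous situations — if an algorithm
watching their scalp EEG could announce seizures minutes to an hour in
advance. The standard formulation assumes a *preictal* state: a
predefined interval before each seizure onset during which the EEG
background differs measurably from the seizure-free (*interictal*)
baseline. A classifier is trained to recognise preictal windows, its
noisy window-by-window decisions are smoothed into a seizure-risk
score, and alarms are raised when the score crosses a threshold.

`seizecast` implements this pipeline end to end, together with the
statistical machinery needed to judge it honestly (chance-level
surrogate testing, a circadian no-EEG baseline) and the explanation
procedures used to probe *why* a model alarms (counterfactual feature
changes, single-feature-group retraining). Because the long-term
clinical recordings this methodology is developed on are
access-restricted, the package ships a synthetic-EEG generator with a
controllable ground truth, so that every stage is testable and every
claimed property is demonstrated on data whose answer is known.

## The pipeline and its parameters

**Windows and features.** The signal is cut into 5-second
non-overlapping windows (1280 samples at 256 Hz; trailing samples are
dropped). Per channel and window the package computes 54 univariate
linear features: relative spectral power in eight bands (0.5–4, 4–8,
8–13, 13–30, 30–47, 53–75, 75–97, 103–128 Hz — the two notch gaps
count toward total power but toward no band), the 28 pairwise band
ratios, the 50% spectral edge frequency and the cumulative power at
that edge, the four statistical moments (kurtosis in the Pearson,
non-excess convention), the three Hjorth parameters, the decorrelation
time, and the energies of the eight detail levels of a periodized db4
wavelet decomposition.

Numerical conventions, chosen once and recorded in the feature
metadata: the PSD estimator is a single Hann-tapered periodogram of the
mean-detrended window (0.2 Hz resolution); band intervals are
half-open `[f_low, f_high)` with the Nyquist bin closing the last band;
band ratios guard the denominator with `1e-12`; the spectral-edge
wording "power at 50%" is implemented as the SEF50 frequency *plus*
the absolute cumulative power at that edge (SEF90 is available through
`sef_fractions`); the 8–13 Hz and 13–30 Hz bands are named by their
frequency ranges, with the conventional alpha/beta labels carried as
metadata, because printed sources disagree on which label belongs to
which range. Decorrelation time uses the *raw* (undetrended) window: a
mean-removed biased autocorrelation must cross zero at some lag, which
would make the documented saturation case (no crossing within the
window) unreachable. Degenerate (constant) windows produce flagged
zeros rather than NaNs; no NaN/Inf ever leaves the module.

**Training protocol.** Everything is patient-specific and
chronological: the first three seizures (and all data up to the end of
the third) are the training period; nothing fitted — standardization
means and SDs, class weights, selected features, model coefficients —
ever sees the test period. The preictal duration is grid-searched over
30, 40, 50, 60 minutes. For each candidate the training windows are
relabelled, and a leave-one-seizure-out loop trains a weighted
logistic probe on two seizures and runs the *full alarm chain* on the
held-out seizure's pre-onset block. The fold score is
`predicted − false_alarms / max_alarms` (with `max_alarms` the
refractory-bounded maximum, so the penalty lies in [0, 1]); candidates
are ranked by mean score, then by mean held-out window AUC, then by
the shorter duration. The alarm-level score is primary because the
deployed quantity is alarms, not window accuracy. Two details were
settled by null simulations (no planted signal, where no candidate
deserves to win): folds start mid-record, so warm-up windows are
excluded from alarm generation inside the search — with the
partial-mean warm-up active a chance-level probe (positive rate
≈ 0.5) alarms almost immediately at every fold start, and the
τ-dependent penalties then bias the selection; and when no candidate
raises a single alarm in any fold, selection falls back to a seeded
uniform draw over the grid, flagged `no_evidence` — both a
shortest-wins rule and an AUC maximum are systematically biased in
that regime (AUC variance differs across candidate label sets, so an
argmax favours the extremes).

Two classifiers are provided. The *logistic regression* balances
classes by inverse-frequency weights (`n_total / (2 n_c)`) and is fit
by IRLS to a 1e-8 tolerance, so it is deterministic and its
coefficients are directly interpretable. The *SVM voting ensemble*
(15 members by default) balances by subsampling instead: each member
draws its own interictal sample (equally spaced time segments, uniform
draws within each) to match the preictal count, selects features with
a stochastic forest of trees (impurity importances, top 20 of 100
trees by default), and fits a linear SVM (C = 1). All member
randomness derives from one master seed, so the ensemble is
reproducible bit-for-bit. The ensemble decision is a majority vote of
binary member outputs; the logistic decision is probability ≥ 0.5,
with a zero margin documented as the positive class. Kernel, C, tree
count and the number of kept features are exposed as arguments, not
asserted as canonical: the methodology they come from does not state
them.

**Alarms.** The Firing Power at window *n* is the mean of the binary
outputs over the last τ windows, where τ spans the selected preictal
duration (τ = 480 for 40 min of 5-s windows); it lies in [0, 1]. An
alarm is raised when it reaches 0.7 outside a refractory span;
refractory periods equal the preictal duration, start at the alarm,
and apply to true and false alarms alike. During the first τ − 1
windows the partial mean over available windows is used and flagged:
normalising the warm-up keeps early record segments from being
silently alarm-proof, and evaluation can exclude flagged windows if
configured. Windows inside ictal spans never raise alarms. An alarm is
correct when a seizure follows it by at least the 10-minute seizure
prediction horizon (time for intervention) and by no more than the
preictal duration (the occurrence period): lead times in
`[SPH, SOP]`, both ends inclusive, with each alarm crediting the
earliest eligible onset.

**Evaluation.** Seizure sensitivity is the fraction of test seizures
with at least one correct alarm. FPR/h divides false alarms by the
interictal duration *minus* refractory time. TiW (time under warning)
is the total time the Firing Power sits at or above threshold. The
surrogate test relocates every test onset uniformly within its own
contiguous pre-onset recording block (leaving room for SPH + SOP),
re-classifies the *fixed* alarms, and recomputes sensitivity; with
1000 draws by default the add-one p-value is
`(1 + #{SS_surr ≥ SS_obs}) / (n + 1)` and "above chance" means
p < 0.05. The relocation span is the recording block by default (a
fixed window around the onset is the alternative reading of "within
each seizure data"; the block choice is the less favourable, more
conservative one). The circadian baseline warns ±30 minutes around
each training onset's time of day, every day, merging overlaps;
forecast-mode sensitivity asks only whether the onset falls inside a
warning (no SPH — a forecaster states risk, not a countdown). Count
claims ("k of n patients show X") use the one-sided exact binomial
tail, which requires an explicit null proportion `p0`: no default is
baked in because no canonical value exists.

**Explanations.** For a linear model the smallest change of feature j
that flips a window decision has the closed form `−margin/w_j` (an
epsilon past the boundary, since a zero margin counts as positive);
features with zero weight are reported infeasible, and deltas are
given in standardized and raw units (clinicians read raw band powers).
For the ensemble a seeded line search (coarse grid then bisection)
finds the smallest flip of the majority vote within bounds. The
ablation procedure retrains the model once per feature group — each
band's relative power, total band power, the signal variance — with
identical splits, labels and seeds, and emits aligned Firing Power
traces; if the gamma-only model reproduces the original alarm dynamics
while the delta-only model does not, the discriminative information
sits in gamma, which is how a muscle-artifact hypothesis can be
rejected without video EEG. "Moments of interest" on scatter plots are
user-supplied timestamps: selecting them is an analyst's judgement,
not an algorithm.

## The synthetic ground truth

`simulate_patient()` emulates long-term presurgical scalp monitoring:
256 Hz, 10–20 labels, at least four seizures separated by ≥ 4 h 30 min
(the generator refuses infeasible schedules), each onset followed by
60 s of large-amplitude 4-Hz "ictal" oscillation that is excluded from
training and evaluation. The background per channel is 1/f-coloured
Gaussian noise (synthesized blockwise in the frequency domain; block
seams align with window boundaries so they never fall inside an
analysis window) plus a 10-Hz posterior alpha rhythm while awake.
Sleep intervals (23:00–07:00 by default) double delta power and
suppress alpha; a 24-h sinusoid (amplitude 0.2, acrophase 18:00)
modulates broadband amplitude; optional muscle artifacts add 0.5–2 s
tapered 20–100 Hz bursts on a Poisson schedule. The preictal signature
multiplies the power of configurable bands (13–30 Hz plus the four
gamma bands by default) by `effect_size` over the `true_preictal_min`
span. The profile is constant by default — the mean preictal/
interictal power ratio then equals `effect_size` exactly, which is the
property the effect-injection test asserts — with a linear ramp
available (`preictal_profile = "ramp"`) to emulate a gradual
transition; under a pure ramp the threshold crossing drifts to
≈ τ(1 − 0.7/p) before onset, which sits at the SPH boundary, so
parameter recovery is not expected in that regime. No claim of
physiological seizure morphology is made: ictal content exists only
for refractory and exclusion bookkeeping, artifacts are a single
class, and none of the evaluation quantities ever uses ictal data.

Everything derives from one master seed through per-stage substreams
(scheduling, per-block noise, artifacts, ensemble members,
surrogates), so a patient is reproducible bit-for-bit and two stages
never share a stream. The magnitude of a real preictal change is
unknown — the generator therefore exposes `effect_size` rather than
asserting one, and the validation suite states the value it uses
(`effect_size = 3`) as its study condition.

What passing tests on this generator do **not** show: that real scalp
EEG carries a separable preictal signature (the headline clinical
result of this methodology on real data is that most patients do
*not* beat chance), that artifacts as rich as real EMG/movement are
handled, or that circadian structure in real seizure times matches a
single sinusoid plus fixed sleep schedule. The suite shows that the
*machinery* is correct: metrics equal hand-derived values, the
surrogate test is calibrated and powerful, the grid search recovers a
known preictal duration, and the ablation logic localizes a known
planted effect.

## Validation design and problem sizes

The test suite runs entirely on generated data at sizes chosen to keep
the full suite in the tens of minutes on one core while leaving the
statistical conclusions stable:

* *Oracle equivalence*: every feature is recomputed by an independent
  direct-formula implementation (an O(n²) DFT for spectral features —
  sharing only the Hann-taper definition — explicit moment sums, a
  literal autocorrelation loop, a hand-rolled IRLS, a brute-force
  counterfactual scan, re-summed Firing Power means) on 100 random
  windows; agreement to 1e-9 relative (1e-6 for spectral), and db4
  energies additionally match PyWavelets reference values frozen from
  a seeded window and conserve energy to 1e-6.
* *Surrogate calibration*: 1000 schedule-only patients with
  uniform-random alarms, 200 surrogates each, rejection rate compared
  against 0.05 + 2·SE; *power*: 100 patients with oracle alarms placed
  SPH + 1 min before each onset.
* *Preictal recovery*: 100 compact patients (three seizures 90 min
  apart, one channel, band-power features, `effect_size = 3`,
  truth 40 min) for the recovery rate, 60 with `effect_size = 1` for
  the null-uniformity χ² (α = 0.01). The compact spacing trades
  realism for runtime; the recovery geometry (block length ≫ SOP) is
  preserved.
* *Forecaster comparison*: 20 patients, each a training day (three
  seizures at 01:30/03:12/04:54) plus a separate test day (onsets at
  07:12 and 10:24 — ≥ 2 h away from every training time of day), so
  the circadian baseline must miss while the EEG forecaster, driven by
  the planted signature, should not; paired sign test at α = 0.05.
* *Ablation discrimination*: 20 seeded patients with the effect planted
  in the gamma bands only; the gamma-group model must dominate the
  delta-group model's preictal Firing Power (sign test, α = 0.05).

`scripts/acceptance.R` reruns the pipeline's headline computation from
scratch at a demonstration scale (one 30-h two-channel patient with
five seizures, full protocol with 1000 surrogates, plus a 20-replicate
recovery rate) and writes the resulting numbers as JSON.

## Known limitations

The generator's spectra are stationary within state; real EEG drifts.
Electrode geometry is label-deep: no volume conduction or montage
correlations are simulated, so multichannel results mostly add
independent replicas rather than true spatial structure. The SVM
ensemble's hyperparameters are defaults, not tuned values. The
binomial count test requires the analyst to supply `p0`. Only the
feature-based models are implemented: raw-signal deep-learning
variants (CNN ensembles and learned artifact removal) and off-the-shelf
attribution wrappers (SHAP/LIME/ICE/PDP) are out of scope, as is any
reproduction of performance values on access-restricted clinical data.
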