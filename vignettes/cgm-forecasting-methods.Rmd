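---
title: "Methods: Kalman-smoothed CGM and stacked-LSTM glucose forecasting"
author: "cgmforecast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Kalman-smoothed CGM and stacked-LSTM glucose forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

People with type-1 diabetes manage blood glucose (BG) with insulin dosing
decisions made every few hours. A continuous glucose monitor (CGM) samples
interstitial glucose every 5 minutes, but the sensor is noisy, lags blood
glucose, drops out, and suffers transient artifacts such as pressure-induced
sensor attenuation (PISA). Short-horizon forecasting — 30 or 60 minutes
ahead — gives enough warning to head off hypo- and hyperglycemic events, if
the forecast is accurate and comes with a usable uncertainty estimate.

`cgmforecast` implements a complete forecasting pipeline:

1. a canonical per-patient data model on a uniform 5-minute grid, read from
   OhioT1DM-style XML event files or an equivalent CSV dialect;
2. CGM sensor-fault correction by Kalman filtering plus
   Rauch–Tung–Striebel (RTS) fixed-interval smoothing;
3. physiological feature crafting: effective carbohydrates, effective bolus
   insulin, and a weighted step count;
4. a stacked-LSTM probabilistic forecaster trained with a Gaussian
   negative log-likelihood (NLL);
5. RMSE evaluation against fingerstick references and, on synthetic data,
   against ground truth, with a persistence baseline for skill;
6. a seeded type-1-diabetes simulator so that every stage is testable
   without access-restricted clinical data.

## Sensor-fault correction

The CGM channel is modelled with a linear-Gaussian state space
$x_{k+1} = \Phi x_k + w_k$, $y_k = H x_k + v_k$. The default is a two-state
local linear trend — state (glucose, rate of change),
$\Phi = \begin{pmatrix}1 & 1\\0 & 1\end{pmatrix}$, $H = (1, 0)$ — the
minimal model that both tracks glucose dynamics and interpolates gaps. The
process covariance is the white-noise-jerk discretisation
$Q = q\begin{pmatrix}1/3 & 1/2\\ 1/2 & 1\end{pmatrix}$.

The forward pass is the standard Kalman filter; at slots with no CGM sample
the measure update is skipped, so gaps are propagated (never imputed) and
re-enter later with honestly inflated variance. The backward pass is the
RTS smoother with gain $C_k = \hat P_k \Phi^\top \bar P_{k+1}^{-1}$.
Smoothing is applied **per data file**: a patient's training and test files
are smoothed separately so no information crosses the split.

Parameter choices, with units:

* `r` = 25 (mg/dl)² — measurement noise, i.e. a CGM noise sd of ~5 mg/dl,
  the scale reported for modern sensors.
* `q` = 1 (mg/dl)²/slot — the glucose rate of change wanders by roughly
  1 mg/dl per 5-minute slot once physiological noise and meal/insulin
  kinetics are accounted for. Much smaller values (e.g. 0.05) over-stiffen
  the trend: on simulated data they flatten genuine meal excursions enough
  that the "smoothed" trace is *further* from the truth than the raw
  sensor, which defeats the purpose of the preprocessing stage. We measured
  this directly during development and fixed the default accordingly; both
  parameters remain exposed.
* `P0` = diag(1e4, 1e2) — a diffuse start from the first observation.

Degenerate inputs: fewer than two observed CGM values is an error; a
singular one-step covariance aborts with the offending index (a
pseudo-inverse fallback is available but off by default).

## Feature crafting

Four channels feed the forecaster: glucose (raw or smoothed), effective
carbohydrates, effective insulin, and weighted steps.

**Effective carbohydrates.** After a meal of $C_{meal}$ grams at slot
$t_{meal}$, with elapsed slots $e$: nothing for the first 3 slots (15 min,
gastric delay); an increasing phase
$C_{eff} = \min\{C_{meal},\ (e-3)\,\beta_{inc}\,C_{meal}\}$ for the next
9 slots, with $\beta_{inc} = 0.111 \approx 1/9$ so the peak reaches ~100%
of the meal one hour post-meal; then a decreasing phase
$C_{eff} = C_{meal}\,(1 - d\,\beta_{dec})$ clamped at zero, where $d$
counts slots past the peak and $\beta_{dec} = 0.028 \approx 1/36$ exhausts
the meal in about 3 hours. Two bookkeeping conventions here are genuinely
open and we fixed them for internal consistency: the rise multiplies
$(e-3)$, not $e$ (otherwise the peak overshoots, $12 \times 0.111 = 1.33$),
and the decay clock starts at the peak (otherwise the response jumps
discontinuously there). A new meal replaces the tracked $(t_{meal},
C_{meal})$ pair; an additive-superposition mode is available for
sensitivity analysis when meals overlap.

**Effective insulin.** A bolus of $I$ units decays linearly,
$I_{eff} = \max\{0, I - e \cdot r_{insulin}\}$ with
$r_{insulin} = 5 \times 0.014$ per slot — the 0.014/min weighted
two-pathway absorption rate (67% slow at 0.011/min, 33% fast at
0.021/min) — and no absorption delay.

**Weighted steps.** $S_{avg}(t) = \frac1n \sum_{i=0}^{n-1}(n-i)\,
steps(t-i)$ with $n = 10$ (50 min), emphasising the most recent walking.
Missing step slots are 0: absence of a fitness-band record most plausibly
means no recorded steps, and the kernel needs a dense series.

**Windows.** One supervised example per slot $t$ whose $L = 24$ history
slots (2 h) all have defined glucose and whose target slot $t + PH$ does
too; $PH$ = 6 slots for 30 min, 12 for 60 min. Channels are z-scored with a
scaler fitted on training windows only; targets stay in mg/dl and
predictions are inverse-transformed before any RMSE. $L = 24$ matches the
2-hour evaluability threshold (histories of 30–240 min are all
configurable).

## The forecaster

Input $(L \times 4)$ → LSTM(128, full sequence) → dropout(0.2) →
LSTM(128, final vector) → dense(512, ReLU) → dense(128, ReLU) → output
head. Training uses Adam at 1e-3, batch 128, a chronological 80/20
train/validation split (no shuffling across the boundary — time-series
leakage discipline), up to 6000 epochs with early-stopping patience 128,
returning the best-validation-epoch weights.

The output head deserves a note. A single exponential-activated output
neuron and an NLL loss with plotted predictive standard deviations are
incompatible as a pair: NLL needs a variance output. The default head is
therefore a two-parameter Gaussian (affine mean unit plus a log-variance
unit whose exponential is the variance); the literal single
exponential-activated mean with one global learned variance is available as
`single_exponential`. Dropout is 0.2 (unstated in the source material;
configurable). Prediction is direct (single-shot at $t + PH$), not a
recursive rollout — this matches per-horizon RMSE reporting and avoids
compounding errors.

The network is implemented in single-precision RcppArmadillo with an
explicit `mt19937_64` RNG: one seed drives weight initialisation
(Glorot-uniform, forget-gate bias 1), dropout masks and batch order, so a
fixed seed reproduces training bit-for-bit on one platform in
single-threaded mode. Gradients are clipped at global norm 5 and the
log-variance is clamped to ±15 as numerical guards; neither binds in
normal training.

## The simulator

The generator is a deliberately minimal discrete-time glucoregulatory
model, not a physiological simulator (no Bergman/UVA-Padova fidelity, no
circadian hormones). True BG follows

$$G_{k+1} = G_k + g_C\,C_{eff,k} - g_I\,I_{eff,k} - g_S\,S_{avg,k}
  + \rho\,(G_b - G_k) + \epsilon_k$$

clamped to the displayable 40–400 mg/dl, with the *same* input kinetics as
the feature module — so the forecaster's inductive bias matches the
generator and skill comparisons are meaningful rather than vacuous.
Defaults: basal 120 mg/dl, carb gain 0.5 mg/dl/g, insulin gain 3 mg/dl/U,
activity gain 0.002 mg/dl per weighted step, mean reversion 0.05/slot,
process noise 1 mg/dl. The CGM observes the truth with a one-slot lag (the
interstitial-vs-blood delay collapsed to one grid step) plus N(0, 5²)
noise; 3–5 daytime meals/day of 20–100 g with proportional boluses
(0.1 U/g); four fingersticks/day at truth ± 2 mg/dl; steps as a daytime
Poisson background plus two brisk walks.

Sensor faults are injected on top: dropouts (1/day, 3–12 slots), additive
spikes (2/day, +30–80 mg/dl) and PISA events (1/day, depth 0.2–0.5, 6–18
slots), Poisson counts with uniform placement — rates chosen once as
realistic CGM artifact frequencies. What the simulator does **not**
emulate: calibration drift, compression of real meal-absorption
variability, exercise intensity beyond step counts, sensor-warmup
artifacts, or the heavy-tailed error structure of real CGM. Passing tests
on this generator therefore demonstrate the pipeline's internal
correctness and directional behaviour (smoothing helps; the model has
skill over persistence), not clinical performance.

## Evaluation

`rmse()` is the standard $\sqrt{\frac1N\sum(\hat y - y)^2}$. Sensor
accuracy pairs each fingerstick with the glucose channel at the same grid
slot (floor rule). Forecast accuracy is computed at the target slots
against, by preference, the simulator's ground truth; on real data the
reference is the chosen glucose channel, and both raw and smoothed
references are reported where the distinction matters. The skill reference
is the persistence baseline (predict the last observed glucose), whose lag
error on a linear ramp of slope $m$ is exactly $|m| \cdot PH$ — a useful
closed-form test. Evaluation refuses to score a model on its own training
file (fingerprint check).

## Problem sizes and numerical choices

Experiment helpers default to a desk-scale profile chosen as the package's
own study conditions: skill experiments train on 10 simulated days
(~2850 windows), test on 5 independent days, with a 20-epoch budget and
patience 8 — on this generator the validation NLL is essentially converged
after a handful of epochs, so the larger reference budget (6000 epochs,
patience 128) buys nothing and remains available via `model_config()`.
Sensor-correction experiments use 30 days. Constant input channels get a
unit scaler sd (guard against division by zero); ties in dense grid
alignment keep the later event with a warning.

## Known limitations

* The smoother is linear-Gaussian: sustained PISA attenuation looks like
  genuine glucose decline and is only partially corrected; an
  outlier-robust or drift-state extension is out of scope.
* One model per patient; no transfer learning, no GRU or attention
  variants.
* The simulator's simplicity means absolute RMSE numbers on synthetic data
  are not comparable to clinical results; only directions and orderings
  carry over.
* Timestamps are timezone-naive local clock times; daylight-saving folds
  are the caller's problem.
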