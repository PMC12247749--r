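---
title: "Models and methods behind mbfus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mbfus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbfus)
```

# The problem

Microbubble-mediated focused ultrasound (MB-FUS) transiently opens the
blood-brain barrier. The operator's dial is the peak-negative pressure of a
pulse train (here 0.5 MHz, 10 ms pulses at 1 Hz for 130 s); the feedback
signal is the spectrum of acoustic emissions (AE) re-radiated by circulating
microbubbles and recorded by a passive cavitation detector (PCD). Harmonic
and ultra-harmonic lines track stable (useful) bubble oscillation; elevated
energy *between* the lines — broadband emission — signals inertial collapse
and tissue damage. A pulse counts as a broadband **event** when the level in
the broadband bin (7.22 f0, near the PCD's 3.5 MHz sensitivity peak) is at
least 6 dB above baseline noise; the tie at exactly 6.0 dB counts as an
event, and this single rule is used everywhere in the package.

Conventional controllers are *reactive*: they drop pressure by 5% only after
an event is detected. `mbfus` implements, on top of a simulated in-vivo
world, the *predictive* alternative: a small classifier trained to flag,
from the current pulse's features, whether the **next** pulse will contain a
broadband event, wired into the closed-loop controller as an advisory safety
layer (ML-CL) that acts as if the event had already occurred.

# The synthetic world

No in-vivo corpus is distributed, so the package carries a stochastic
surrogate generator (`generator_params()`, `simulate_run()`). It is a stated
world, not a tuning knob; its defaults encode the following structure and
were fixed once:

* **Bolus kinetics.** Normalized concentration follows a difference of
  exponentials: zero before arrival (~8 s), rise constant 6 s, clearance
  constant 180 s in mice and 90 s in rats (rats clear roughly twice as
  fast), normalized analytically so the peak is exactly 1.
* **Dose-response.** The 7th-harmonic level is
  `L7 = 37 * tanh(max(0, trans * p * conc - 0.06) / 0.06)` dB: linear at low
  effective dose, plateauing near 37 dB. The anchor is that 0.14 MPa at peak
  concentration yields ~32 dB — the top of the linear regime — while 36 dB
  sits beyond it. Other harmonics are scaled replicas peaking near the
  receiver's 3.5 MHz sensitivity; all levels carry 1.5 dB Gaussian noise.
* **Latent instability.** A leaky accumulator (leak 0.9 per pulse, gain 7)
  integrates the pressure-concentration excess above the half-saturation
  pressure 0.17 MPa. Ultra-harmonics rise with it (5 dB per unit), giving
  events observable one-pulse-ahead precursors.
* **Events.** Each pulse draws a Bernoulli with log-odds
  `-14.5 + 16 * instability + 1.0 * tumor + 0.8 * [conc > 0.7]`. The steep
  slope makes events conditionally near-deterministic given the precursors —
  the premise that a predictor can work at all — while the tumor and
  bolus-first-pass terms reproduce the qualitative risk factors. On an
  event the broadband level is 6 dB plus an exponential excess and the
  accumulator partially resets (factor 0.8).
* **Skull.** Transmission multiplies pressure (mouse 1.0, rat 0.8) with 5%
  lognormal per-target jitter.

**Calibration procedure (run once, then frozen).** With the spec-pinned
anchors kept verbatim (plateau 37 dB, p50 = 0.17 MPa, slope width 0.06 MPa,
1.5 dB level noise, 32 dB at 0.14 MPa), the four free event-model constants
were chosen so that a 200-run constant-pressure mouse corpus (pressures
uniform on 0.12–0.40 MPa, 30% tumor targets) shows (i) a marginal event rate
in the 5–10% band (measured 6.05%), (ii) ultra-harmonic precursor separation
of at least 3 dB between pre-event and pre-non-event pulses (measured
~11 dB), and (iii) held-out balanced sensitivity of at least 0.95 for the
trained predictor (measured ~0.97). Those three properties are asserted by
the test suite, not merely claimed here.

**What the generator does *not* emulate:** physical bubble dynamics
(Rayleigh–Plesset), acoustic propagation and standing waves, skull
aberration, vascular heterogeneity, inter-pulse spectral correlations beyond
the single latent accumulator, or real DCE-MRI. The permeability output
(`ktrans_surrogate()`) is a labelled synthetic stand-in: a saturating
function of cumulative 7th-harmonic dose with seeded per-subject jitter. A
green test therefore establishes that the *algorithms* behave as specified
on data with the stated statistical structure — not that the published
in-vivo effect sizes are reproduced.

# The predictor

A 12-10-1 fully connected network, sigmoid throughout (141 parameters).
Features: ultra-harmonics 1–7, pressure, target coordinates, the
microbubble-kinetics proxy, and the tumor flag. The label of row *t* is the
event flag of pulse *t + 1*; the final pulse of each run is dropped.

* **Class imbalance.** Events are ~6–8% of pulses. Inside the 80% training
  split every positive is kept and an equal number of negatives is sampled
  without replacement (1:1); the 20% test split keeps the natural ratio. The
  original description of the under-sampling arithmetic is internally
  inconsistent (it also matches equal class totals in its confusion matrix);
  the 1:1 reading reproduces that confusion structure and is used here. An
  oversampling route (duplicating positives) exists behind the same
  interface.
* **Training.** Levenberg–Marquardt on the exact Jacobian: damped
  Gauss-Newton, initial damping 0.01, damping divided by 10 on an accepted
  step and multiplied by 10 otherwise, stopping at 1000 epochs, a 1e-7
  gradient norm, or damping overflow. Targets are 0/1 under squared error;
  the *output* sigmoid (the original specifies only the hidden activation)
  makes outputs probabilities comparable to the 0.5 threshold. Features are
  z-scored with training-split statistics stored in the model. A model
  output of 0.5 or greater — including exactly 0.5 — is a positive
  prediction.
* **mb_kinetics proxy.** The controller cannot see the latent concentration;
  the feature is the tracker-pulse 4th-harmonic level normalized by its
  running (training: within-run) maximum, clipped to [0, 1].
* **Attribution.** `shap_attributions()` is a permutation-sampling Shapley
  estimator with marginal replacement from a background set. Background rows
  are cycled in balanced order, which makes the local-accuracy identity
  `base + sum(phi) = f(x)` hold to machine precision and the linear-model
  case exact. Global importance is mean |phi|; `top_k_features()` ranks
  descending with ties broken by feature index (k = 7 mirrors the feature
  reduction used upstream).

# The attention variant

`train_amp_cv()` implements a cross-attention classifier: six
patient/context features (pressure, target x/y, kinetics, tumor, pulse
number) are encoded to a d = 32 query; the two spectral blocks (harmonics
2–8, ultra-harmonics 1–7) are embedded as two tokens providing keys and
values; scaled dot-product attention, layer normalization, dropout 0.1, L2
1e-4, and a sigmoid head follow. Class imbalance is handled not by
resampling but by weighted cross-entropy with positive weight
`epsilon * N_total / N_pos` (epsilon = 2; with the reference counts
54,040/4,299 this is 25.14) while splits keep the natural ratio. Training
uses first-order stochastic updates with adaptive per-parameter step sizes;
hidden sizes, epochs and batch size are config, as the source leaves them
unstated. Model selection is stratified 10-fold cross-validation inside the
80% training split by fold sensitivity (ties: precision), evaluated once on
the untouched 20%. Only a single attention head is implemented; the head
count is exposed in the config for forward compatibility. Two-token
embedding (rather than per-frequency tokens) matches the [7, 7] block
structure of the feature description.

# The controller family

All controllers share the kinetics gating state machine driven by the 60 kPa
tracker pulse's 4th harmonic (H4): `waiting -> recording -> active ->
ceased`, never skipping or revisiting.

* **On-trigger:** +10 dB H4 rise over background (background = running
  median of pre-trigger H4).
* **Recording:** for `min_record_s` (20 s mouse, 40 s rat) the clearance
  slope of normalized H4 is fit by least squares over a trailing 15-pulse
  window and updated in real time. *Design choice:* therapeutic control runs
  during recording — the recording window is the controller's minimum
  operation time and was lengthened for rats precisely because their
  kinetics are faster; gating it at tracker pressure would invert that
  logic. The cease rule is simply not armed until the window has elapsed.
* **Cease:** when the fitted normalized H4 falls to 0.80 of its maximum
  (20% decay), pressure freezes at the last value until 130 s. The running
  maximum is taken over a 3-pulse median of H4, since a maximum over raw
  noisy levels is biased high and would trigger the decay rule early.
* **Control laws.** OL: constant pressure. CL: multiplicative ramp — median
  of the last 3 pulses' 7th-harmonic level versus a target (here 36 dB),
  +/-5% per pulse outside a +/-1 dB deadband, clamped to [p_min, p_max]. The
  ramp internals (step size, deadband, smoothing) are reconstructed — the
  source defers them to earlier work — and are all config. ML-CL: CL plus
  the advisory layer; a positive prediction skips the ramp and applies the
  same 5% drop as a real event. One safety action per pulse at most
  (prediction and detection never stack), and after any safety action the
  ramp may not raise pressure on the immediately following pulse.
* **Reactive rule (all kinds):** a detected event drops pressure 5% on the
  next pulse, clamped at p_min.

# Evaluation statistics

Event and prediction rates are exact integer arithmetic with percentages
rounded to 2 decimals; percent reductions round to integers for reporting.
The treatment-window analysis fits `y = a + b tanh((x - c)/d)` by
multi-start least squares (`nls` with a Nelder–Mead fallback; width
canonicalized positive; constant-y inputs flagged degenerate, since c is
unidentifiable). The window's upper bound is the fitted inflection c; the
lower bound is an input — on synthetic data it is derived as the smallest
arm-mean pressure whose permeability surrogate exceeds background + 2 SD.
Skewness is the adjusted Fisher–Pearson statistic; the F test is the plain
variance-ratio test, and the Levene test uses median centering
(Brown–Forsythe), appropriate for the skewed harmonic-level distributions it
is applied to.

# Numerical choices and degenerate inputs

* Band levels use the **mean** in-band linear power (stable under grid
  resolution changes); the per-band baseline is the median power over
  pre-microbubble pulses. The broadband bin is read as center 3.61 MHz with
  the same +/-0.3 kHz half-width as the harmonic bins (its printed units are
  internally inconsistent in the source description).
* Ties: 6.0 dB is an event; model output 0.5 is a positive prediction;
  feature-importance ties break by feature index.
* The 20-feature set includes `pulse_number` to reach D = 20 (the source's
  feature table enumerates 19; its prose lists pulse number); whether the
  12-feature model excludes it by construction or by feature reduction is
  ambiguous upstream — here the 12-feature set is fixed by construction.
* RNG: every experiment takes one root seed, split into named substreams
  (kinetics, noise, events, corpus), so adding a consumer to one stream
  never shifts another; records are byte-reproducible.
* Zero-denominator confusion ratios are NaN with a warning; probabilities
  outside (0,1) in the weighted cross-entropy are clamped at 1e-12 with a
  warning; non-overlapping bands, missing baselines, non-monotone time and
  empty windows are errors.

# Known limitations

* The generator's event process has a single latent driver; real inertial
  cavitation has richer memory and spatial structure. Absolute event rates
  and reduction factors from simulation (e.g. an ~85% ML-CL vs CL reduction
  at 50 runs/arm) should be read as qualitative reproductions of the
  published ordering, not quantitative predictions.
* The Levenberg-Marquardt trainer is exact but dense; it is sized for the
  141-parameter network, not for wide models.
* The attention model is single-head and CPU-scale; cross-validated training
  on large corpora is the slowest path in the package.
* `ktrans_surrogate()` is synthetic by construction and labelled as such;
  no claim about real DCE-MRI quantification follows from it.
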