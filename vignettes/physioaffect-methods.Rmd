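---
title: "Predicting felt musical emotion from peripheral physiology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting felt musical emotion from peripheral physiology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When people listen to music, their bodies respond: heart rate and breathing
change, sweat glands activate, facial muscles tense or relax. **physioaffect**
asks whether those peripheral signals alone carry enough information to
predict the emotion the listener reports feeling, expressed as *valence*
(unpleasant to pleasant) and *arousal* (calm to excited) on the 1–9
Self-Assessment-Manikin scale. The package implements the full analysis
chain — signal features, linear models, a small feedforward neural network,
and a contribution analysis of the trained network — together with a
synthetic-data generator that reproduces the statistical structure the
analysis assumes, so every stage is testable without access to raw
recordings.

The study design the package targets: 20 participants each hear 12 classical
excerpts (3 per quadrant of the valence–arousal grid), every 40 s excerpt
preceded by 30 s of RMS-matched white noise as an emotionally neutral
baseline, with five channels recorded throughout — skin conductance level
(SCL), a photoplethysmographic pulse waveform (from which heart rate is
derived), a respiration belt, and surface EMG over zygomaticus major
(smiling) and corrugator supercilii (frowning).

# Feature extraction

Each trial is reduced to one number per channel:

1. **Filtering** (zero-phase 2nd-order Butterworth, applied
   forward–backward): none for SCL and respiration; 0.5–3 Hz band-pass for
   the cardiac pulse; 1–500 Hz band-pass for EMG, with the upper cutoff
   clamped to 0.45 × sample rate when 500 Hz is not representable. The filter
   family and order are not dictated by the protocol; forward–backward
   Butterworth is standard psychophysiology practice and gives a testable
   zero-phase contract.
2. **Rate conversion** for the cardiac and respiration channels: peaks with
   an enforced minimum separation of 60/max-rate seconds (bounds 40–180
   beats/min for heart rate, 5–180 events/min for respiration), located on a
   lightly smoothed copy of the signal and refined to the raw local maximum.
   A *prominence guard* additionally requires each event to be separated from
   its neighbours by a dip of at least a quarter of the signal's robust
   amplitude range — without it, noise wrinkles riding near the crest of a
   slow respiratory wave are counted as events and wreck the rate estimate.
   Inter-event intervals implying rates outside the channel's bounds are
   rejected, and the events-per-minute series is linearly interpolated across
   the gaps (and held constant beyond the first/last accepted interval) on
   the original sample grid: rejection must not empty the feature windows.
   Rate conversion precedes standardization — z-scores of the raw pulse
   waveform would not be "heart rate" in any meaningful sense.
3. **Rectification** of the filtered EMG (absolute value). The mean of a
   band-passed EMG signal is zero by construction, so a mean-based feature
   would be degenerate without it; full-wave rectification is the standard
   amplitude summary. This step is an explicit assumption of this
   implementation.
4. **Standardization** per participant: each channel (the rate series for
   cardiac/respiration, the rectified series for EMG) is converted to
   z-scores using the mean and SD pooled across *all* of that participant's
   trials, baselines included. Units and stable individual differences drop
   out here, which is also why the generator's per-participant offsets are
   harmless by design.
5. **Baseline subtraction**: the feature is the mean z-value over seconds
   10–40 of the music minus the mean over the final 20 s of the white-noise
   baseline. The first 10 s of both baseline and music are excluded as a
   startle guard, so exactly 20 s of baseline and 30 s of music enter every
   feature.

Features are averaged over participants (unweighted), giving a 12 × 5 matrix
alongside the per-excerpt mean valence and arousal. Averaging before or
after the baseline subtraction is equivalent for unweighted means; the
per-participant subtraction is done first.

# Linear stage

Each feature is correlated with the mean ratings (Pearson, two-tailed t test
on n − 2 df). Multiple regression uses **stepwise forward entry**: the
candidate with the smallest partial-F p-value enters while that p-value is
below `alpha_enter`; after each entry, members whose p-value has drifted
above `alpha_keep` are removed. The thresholds are not part of the published
protocol; the defaults `alpha_enter = 0.10`, `alpha_keep = 0.15` are chosen
so that a marginal respiration predictor (p ≈ 0.07) is retained in the
arousal model, as in the reference analysis, and both are configurable.
Ties break deterministically on the fixed column order (scl, hr, resp, zyg,
corr). The empty model is a legitimate outcome and predicts the training
mean. Once a fit becomes numerically exact (R² within 1e−12 of 1), entry
stops: partial-F statistics on zero residuals are noise. A caution is logged
when the case-to-predictor ratio falls below 5, honouring the small-sample
caveat without refusing to fit.

# The 5-5-2 network

The network maps the five scaled features to scaled valence and arousal
through one hidden layer of five logistic units (hidden size fixed equal to
input size as an overfitting guard). Inputs are min–max scaled to [0, 1]
using the training excerpts only; ratings map to [0, 1] via (r − 1)/8, whose
inverse 8o + 1 returns predictions to the rating scale — the output
nonlinearity is logistic, so (r − 1)/8 is the natural choice although the
original protocol does not state its map. Test inputs are scaled with the
training parameters and *not* clipped, keeping distribution shift visible.

Training is full-batch backpropagation: all eight training patterns are
presented per epoch in randomized order, per-pattern weight deltas for the
summed squared-error loss are accumulated, and the summed update is applied
once at the epoch's end with step 0.1. The presentation order is provably
irrelevant under summed accumulation; it is retained for fidelity to the
protocol and costs nothing. Weights start i.i.d. uniform on [0, 0.05).
Training runs a fixed 80,000 epochs — no early stopping — and convergence is
*reported* as whether the final mean squared error (averaged over patterns
and outputs; the averaging convention is this implementation's documented
choice) is below 0.02. The protocol's step 2 literally passes the inputs
through a sigmoid before the first weight layer; this is implemented as
stated behind the `input_sigmoid` flag (default on), with the conventional
variant available. Biases are not mentioned in the protocol; they default to
on, initialized like weights, because a sigmoid-output network without
biases and all-positive initial weights cannot express targets below 0.5. A
strict-literal no-bias mode exists. The training loop is compiled (C++) —
ensembles retrain hundreds of networks in the test suite — and its gradients
are verified in the tests against an R finite-difference oracle at 1e−6 and
against a single-epoch R reference update at 1e−12.

The full protocol trains 20 independently re-initialized networks on the
fixed split (train M1, M2, M4, M5, M7, M8, M10, M11; test M3, M6, M9, M12 —
two of three per quadrant) and reports the per-excerpt mean prediction
across the ensemble.

# Contribution analysis

For a single-hidden-layer network, each input's influence on each output is
decomposed sign-preservingly: within each hidden unit the input weights are
normalized by the unit's total absolute input weight, scaled by that unit's
weight to the output, summed over hidden units, and finally normalized per
output so absolute contributions sum to 1. Biases are excluded —
contributions partition the influence of the inputs. The exact algebraic
form is locked by a hand-derived two-input toy case ((3, 1) input weights
through a single hidden unit give contributions (0.75, 0.25)) and by
invariance properties (positive rescaling of an output's weights changes
nothing; negative rescaling flips all of that output's signs; input
permutations permute contributions).

Across the 20-trial ensemble, the absolute contribution sizes are compared
with a one-way repeated-measures ANOVA (trial as subject, feature as the
repeated measure, uncorrected df (4, 76) at the defaults), and features are
reported against the *null threshold* 1/5 = 0.2, the size expected were all
inputs equal. The ANOVA uses absolute sizes: "relative size" is interpreted
as magnitude, which is the quantity the threshold comparison also uses. The
threshold is applied to the trial-mean magnitudes.

# Error and accuracy reporting

Per test excerpt and dimension the error is |predicted − observed| (the
one-dimensional Euclidean distance). The mean error divided by 8 — the span
of the 1–9 scale — gives the error percentage, and accuracy is its
complement; this is the only denominator under which the published
per-excerpt errors reproduce the published percentages, which is why the
per-dimension reading of "Euclidean distance" is used (the combined 2-D
distance is reported as a supplementary column). RMSE is computed on the
(r − 1)/8-scaled space, the only convention consistent with RMSE values an
order of magnitude below rating-unit mean errors; it is documented output,
not an acceptance quantity.

# The synthetic generator

`simulate_study()` emulates the study conditions: 20 participants × 12
excerpts whose latent valence/arousal default to the published per-excerpt
mean ratings (so synthetic studies cover the same grid), 30 s baseline +
40 s music at a configurable rate (default 100 Hz; the original hardware
sampled at 1000 Hz, supported but slower), and integer ratings
`round(clip(latent + N(0, 1.8), 1, 9))` — the 1.8 SD matching the reported
inter-subject rating variability.

Planted effects (defaults, per unit of latent value centred on 5):

* heart rate 72 + 2.5·(arousal − 5) beats/min — a comfortably detectable
  autonomic arousal response within realistic resting-rate bounds;
* respiration 15 + 1.0·(arousal − 5) + 0.4·(valence − 5) breaths/min;
* SCL music-minus-baseline shift −0.10·(valence − 5) conductance units
  (higher for unpleasant excerpts);
* corrugator EMG amplitude × (1 − 0.12·(valence − 5)); zygomaticus
  × (1 + 0.06·(valence − 5)) — amplitude modulation, not a mean shift,
  because the feature stage rectifies EMG and a mean shift would vanish.

Effects ramp in over the first 2 s of music, mimicking sluggish autonomic
onsets. The cardiac channel is an asymmetric raised-cosine pulse train with
3% beat-to-beat jitter (any peaked periodic waveform satisfies the
rate-extraction contract); respiration is a quasi-sinusoid; EMG is
broadband noise; SCL adds a slow AR(1) wander (stationary SD 0.05,
autocorrelation 0.995 per sample) on top of white measurement noise.
Per-participant offsets are drawn with SD equal to half each channel's noise
SD — the reference study reports rating variability but no physiological
variance components, so this fraction is a fixed, documented choice — plus
modest resting-rate variation (SD 3 beats/min, 1 breath/min) that
standardization removes downstream. One RNG substream per trial is derived
by hashing (participant, excerpt) with the study seed, so output is
bit-reproducible and independent of generation order.

`valence_interaction = TRUE` switches every valence-coupled channel to
respond to (valence − 5)(arousal − 5)/2 instead of valence: no linear
combination of the five features then carries valence, which is the regime
in which the network demonstrably outperforms the linear models.

What the generator does *not* emulate: biophysically realistic hemodynamics
or electrodermal kinetics, motion/electrode artifacts, missing channels,
familiarity or musical-training covariates, and any temporal structure of
emotion within an excerpt. Passing tests therefore show that the pipeline
recovers effects of the planted kind at realistic noise levels — not that
real recordings would yield the published accuracies.

# Problem sizes and numerical choices

The test suite and the acceptance script run the generator at the default
100 Hz with 20 participants for the planted-effect and training-criterion
checks (20 seeded replicates where a replication count is asserted), and at
50 Hz with 2–4 participants for structural checks where only the shape of
the computation matters. Null-calibration checks use 25 replicate studies ×
both rating dimensions. Degenerate inputs error early and loudly: constant
channels (zero pooled SD), fewer than two detected events, planted rates
outside 40–180 beats/min or 5–60 breaths/min (naming the channel),
overlapping train/test splits, collinear selected predictors (condition
number above 1e10), zero residual variance in the ANOVA, and hidden units
with all-zero input weights in the contribution analysis.

# Known limitations

* The contribution decomposition applies to one hidden layer only.
* The stepwise procedure tests entry/removal by partial F only; no
  cross-validation beyond the fixed 8/4 split is provided.
* The rate detector assumes a dominant quasi-periodic component; it is not
  an artifact-robust clinical beat detector.
* With 8 training points and 47 free parameters the network memorizes its
  training set; generalization claims rest entirely on the held-out
  excerpts, as in the protocol it implements.
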