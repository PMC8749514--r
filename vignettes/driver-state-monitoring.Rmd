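---
title: "Monitoring driver vigilance from body-worn sensors: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring driver vigilance from body-worn sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driverstate)
```

## The problem and the modelling approach

Drowsiness and inattention (absent-minded driving with reduced vigilance)
degrade driving performance in different ways and on different timescales:
drowsiness develops over minutes and is visible in autonomic nervous
activity, while lapses of vigilance change the fine motor pattern of
steering within seconds. Neither state is easy to label directly, and
per-driver annotated data are scarce. `driverstate` therefore treats
detection as *anomaly detection*: models are trained only on a recording of
normal driving from the same person, and a state is flagged when the
current sensor pattern deviates from that person's normal pattern.

Three detectors run in parallel on sliding windows, each on its own
feature set and window length, and a fixed-priority flow merges their votes
each second:

1. **Body movement** (window 2 s): per-channel mean and variance of wrist
   acceleration, the standard human-activity-recognition pair. Large
   movements (repositioning a hand, releasing the wheel) are flagged first
   and terminate the flow, because they disturb the other feature sets.
2. **Drowsiness** (window 120 s): eight heart-rate-variability features
   from the RR-interval stream — meanNN, SDNN, RMSSD, total power, NN50 in
   the time domain; LF (0.04–0.15 Hz), HF (0.15–0.4 Hz) and LF/HF from a
   Yule–Walker autoregressive spectrum of the 1 s-resampled RRI trace.
3. **Inattention** (window 60 s): sub-window-difference motion features.
   Each 60 s window of a wrist-acceleration axis is split into 60
   sub-windows; the mean amplitude of each sub-window is taken, adjacent
   means are differenced, and the variance, skewness and excess kurtosis of
   the 59 differences summarise how much fine steering micro-correction is
   present. Two wrists × three axes × three statistics give 18 features.
   When vigilance drops, micro-corrections become sparse and small, and the
   difference distribution concentrates near zero.

If no enabled stage votes anomaly the state is NORMAL; if an enabled stage
cannot be evaluated (missing RRI data, truncated stream) the state is
MISSING — the flow never silently skips a stage it cannot evaluate.

## The anomaly model

Each detector is a multivariate statistical process control (MSPC) model
fitted by `mspc()`. Training windows form a matrix $X \in \mathbb{R}^{N
\times P}$; each feature is standardised to its training mean and standard
deviation, the SVD $Z = USV^\top$ is taken, and $R$ components are
retained. A new standardised sample $z$ scores Hotelling's

$$T^2 = z V_R S_R^{-2} V_R^\top z^\top ,$$

and is anomalous when $T^2$ strictly exceeds the control limit. Design
points:

* **$R = 1$ by default.** One retained component is the configuration the
  method is defined with; it monitors deviation *along* the dominant mode
  of normal variation and is blind to the orthogonal complement. This is a
  real limitation (see below); the residual Q statistic (SPE) is available
  via `predict(model, data, type = "spe")` and `residuals()` but is not
  used in detection.
* **Empirical control limit.** The limit is the nearest-rank
  90th-percentile of the training $T^2$ values, so by construction 90 % of
  training windows fall at or below it and 10 % above. No parametric
  (F-distribution) limit is assumed; training windows are heavily
  overlapping and far from independent, so a distributional limit would be
  miscalibrated anyway.
* **Identity check.** Training scores satisfy $\sum_i T^2_i = R$ exactly
  (orthonormality of $U$); the test suite asserts this to $10^{-8}$ against
  a brute-force eigendecomposition oracle.
* **Reproducibility.** Singular-vector signs are fixed (largest loading
  positive) so serialised models are byte-stable; $T^2$ is sign-invariant.
* **Standardisation.** `scale = TRUE` (unit training variance) is the
  default, as HRV and motion features mix units; `scale = FALSE` (centre
  only) is available when features share a unit.
* Zero-variance training features are dropped with a warning and recorded
  in the model; samples with any missing feature score `NA`, never 0.

## Windows, time convention and alignment

Windows are half-open spans $[t-W, t)$ labelled by their **end** time, so a
detection at time $t$ uses only past data (causal). A signal of duration
$D$ yields $\lfloor (D-W)/s \rfloor + 1$ windows at slide $s$. The fused
timeline starts once the longest enabled window (120 s by default) is
available. The RRI stream starts at the first detected beat, so its window
end times are offset by a fraction of a second from the accelerometer
grid; stages are aligned to the timeline grid by nearest end time within
half a slide interval.

## Preprocessing choices

* **Low-pass filtering**: 3rd-order Butterworth, 12.5 Hz cut-off at a
  100 Hz sampling rate, applied forward and backward (zero phase) so
  features are not time-shifted against annotations. Odd-reflection
  padding (up to 300 samples) removes startup transients; DC gain is
  exactly 1. The effective magnitude response is the squared one-pass
  response, which the test suite checks analytically at 25 Hz.
* **RRI screening**: intervals outside 300–2000 ms are implausible; in
  addition, an interval longer than 1.75× the median in-band interval is
  treated as a gap left by an undetected beat (a single dropped beat at a
  mean RR of 800 ms produces a ~1600 ms interval that is *inside* the
  plausibility band, so a band check alone cannot see it). Flagged
  intervals are excluded from time-domain features, bridged by the spline
  for resampling, and windows with more than 30 % flagged intervals are
  excluded from model fitting and scored as missing.
* **Resampling**: cubic-spline interpolation of the valid (beat time,
  interval) pairs, sampled at 1 s. Cubic splines reproduce affine data
  exactly, which the tests use as an oracle.
* **Spectrum**: the windowed, mean-removed 1 Hz trace is fitted with a
  Yule–Walker AR(10) model; the one-sided density is evaluated on 512
  points over [0, 0.5] Hz and band powers are trapezoidal integrals with
  interpolated band edges. The normalisation is fixed by a Parseval-style
  property — the integral over [0, Nyquist] approximates the sample
  variance — which the tests assert within 15 % on white noise.
* **Conventions**: SDNN and total power use population (1/N)
  normalisation, so total power equals SDNN² exactly. NN50 counts
  successive differences *strictly* greater than 50 ms (boundary-tested).
  LF/HF is reported as a plain ratio. Motion skewness is the third
  standardised moment and kurtosis is excess kurtosis, both population
  normalised; a window whose difference spread is below 1e-10 g is
  degenerate and reports (0, 0, 0) so the multivariate monitor always
  receives finite values. Sub-window boundaries for a window of $n$
  samples are $\mathrm{round}(i\,n/N_{sw})$, a maximally even partition.
  "Average amplitude" is the plain arithmetic mean (not mean absolute
  value), which makes the features exactly invariant to constant offsets —
  gravity, posture and steering position drop out at DC.

## Annotation labeling

Ground truth for evaluation follows the standard operationalisations:
referee drowsiness scores on a 6-point scale every 5 s are averaged over
three referees and an interval is drowsy when the average is **2.0 or
more** (inclusive); vigilance is probed by reaction times to an LED cue,
and an RT event marks its interval inattentive when RT ≥ mean + 1 SD of
that participant's RTs. The SD is the sample (n−1) standard deviation —
with RTs [200, 400] the threshold is 300 + 141.4 = 441.4 ms and no event
is flagged. An RT event at time $t$ labels the grid from the previous
event (exclusive) up to $t$; grid points after the last event are
unlabelled (`NA`) and excluded from evaluation. Both thresholds are
returned with the labels for audit.

## Evaluation and the transition guard

`evaluate_timeline()` counts per-grid-point confusion (sensitivity =
TP/(TP+FN), specificity = TN/(TN+FP)), excluding MISSING predictions and
unlabelled truth. A causal window that straddles an episode edge covers
both regimes and has no unambiguous label; the `guard` argument (default
0 s) excludes grid points within a chosen distance of every truth
transition. The recovery tests and the acceptance script set the guard to
the stage's window length (120 s for the HRV stream, 60 s for motion),
which removes exactly the mixed-content windows and nothing else.
Sensitivity is reported as `NA`, not 0, when the truth contains no positive
samples.

## What the synthetic generator emulates — and what it does not

The generator (`scenario()`, `simulate_driving()`) produces the statistical
structure the detectors assume, with ground-truth episode labels:

* **RRI stream**: beat times integrate an instantaneous RR model: mean
  800 ms, LF and HF sinusoids at the band centres 0.10 Hz (25 ms) and
  0.30 Hz (15 ms) — fixed carriers make band-power checks unambiguous —
  plus 10 ms per-beat noise. A slow vagal-tone wander (10 ms, 300 s
  period) moves mean RR and HF amplitude *together*; this is the dominant
  normal mode the $R=1$ monitor retains, and it is the same axis along
  which a drowsy episode moves (mean RR +10 %, HF ×3, LF ×0.2 at strength
  1 — a parasympathetic-dominance signature; the method only requires a
  consistent deviation, and this choice makes it physiologically
  coherent). Beats are dropped independently at a configurable missing
  rate (0 by default; 0.17 reproduces a realistically poor wearable ECG).
* **Wrist acceleration**: 100 Hz per wrist; constant gravity offset,
  sensor noise (0.01 g), and steering micro-corrections as
  Poisson-timed smooth pulses (1.5 Hz, 0.05 g, 0.2–0.5 s). A slow
  common-mode intensity modulation (±25 %, 300 s period, shared by both
  wrists, acting on pulse rate and — at half amplitude — pulse height)
  encodes the fact that a normal driver's movement intensity waxes and
  wanes; it is the dominant training mode of the motion features.
  Inattentive episodes thin the pulse rate and shrink the amplitude by
  90 % × strength, concentrating the difference distribution near zero.
  Body-movement episodes inject 1–3 s, ~1 g transients on one wrist.
* **Annotations**: three simulated referees score 1 + 3·strength with 0.3
  noise, clipped to [1, 6] and averaged; LED cues fire at random 2–10 s
  intervals with RT = 352.5 ms + 176 ms·strength + 25 ms noise, anchoring
  the alert and inattentive regimes near 352.5 and 528.5 ms.
* Episode edges are tapered with a 10 s raised cosine to avoid
  discontinuity artefacts in the AR fit; generation is fully seeded and
  restores the caller's RNG state.

The generator deliberately omits much of real data: no ectopic beats or
respiration coupling in the RRI, no road vibration spectrum, no posture
drift or sensor slippage, no inter-individual differences, and episodes
with clean tapered edges rather than gradual ambiguous onsets. Passing
recovery tests therefore demonstrates that the pipeline is implemented
correctly and recovers deviations *of the kind it models* — it does not
certify field performance on real drivers, where reported detection rates
are far from perfect.

A consequence worth stating plainly: with $R=1$ the detector sees only the
projection of a deviation onto the dominant normal mode. If normal-state
variation were structureless noise, the first principal component would be
arbitrary and detection of a real deviation would be unreliable. The
generator's common-mode terms exist precisely because the MSPC method
presumes such a dominant mode; on data without one, a larger $R$ or the Q
statistic would be needed.

## Problem sizes and runtime

The recovery tests and the acceptance script use five 40-minute sessions
(2400 s; ≈ 2280 HRV and ≈ 2340 motion windows each at 1 s slide) with the
first 1000 s as the normal training segment, one 400 s drowsy episode and
one 400 s inattentive episode at strength 0.8, plus five episode-free
sessions for the baseline alarm rate, where models are fitted on the full
normal recording and applied to it (the alarm rate then equals the
calibrated 10 % by construction, up to ties). Feature extraction is
vectorised over windows via cumulative sums, so a full session extracts in
a few seconds; the entire suite runs in about a minute on one CPU.

## Known limitations

* Per-participant models only; no pooled or transferable model.
* The control limit is calibrated on overlapping windows; the effective
  number of independent training samples is far smaller than $N$.
* Personalised limits (e.g. ROC-based) and the three-model integration are
  natural extensions, not implemented here.
* R-peak detection from raw ECG and gyroscope channels are out of scope;
  the pipeline starts from RR intervals and accelerometer series.
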