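---
title: "Adaptive Max-Min Threshold R-wave detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive Max-Min Threshold R-wave detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmtqrs)
```

## The problem

Exercise and wearable single-lead ECG is contaminated by three noise
families that defeat naive R-peak pickers: electromyographic (EMG) noise
from skeletal muscle, 50/60 Hz powerline coupling, and baseline wander from
respiration and body swing. At the same time the R amplitude itself drifts
with posture and effort, so any fixed threshold is wrong within minutes.
`mmtqrs` implements a lightweight detector designed for this regime: every
stage is causal (streamable sample by sample), cheap enough for
microcontroller-class devices, and the decision thresholds adapt to the
signal.

## The processing chain

### Preprocessing

1. **Notch filter.** A second-order IIR notch at the powerline frequency
   (default 50 Hz, `notch_freq`), quality factor `notch_q = 30` — the
   bandwidth `f0/Q` ≈ 1.7 Hz removes mains interference while leaving the
   5–40 Hz QRS band essentially untouched (unity DC gain, < 5% amplitude
   error at 5 Hz; both are asserted in the test suite).
2. **FIR low-pass.** A causal order-40 equiripple (Parks–McClellan) filter
   \deqn{y_n = \sum_{i=0}^{N} a_i\, x_{n-i}}
   with passband edge 40 Hz and stopband edge 100 Hz at fs = 500 Hz,
   removing EMG content above the QRS band. For other sampling rates the
   edges scale proportionally in normalized frequency. The filter is linear
   phase, so its group delay is exactly `order/2` samples; the pipeline
   subtracts that delay when reporting beat indices on the raw timeline
   (`compensate_delay`).

Both filters run strictly causally with zero-padded history — no
zero-phase (forward–backward) filtering — because the detector's streaming
contract requires chunked output to equal whole-signal output exactly.

### Baseline correction

The baseline estimate at sample *k* is the median of a window of
`W = fs * window_time + 1` samples centred on *k* (forced odd; default
`window_time = 0.7` s, and at least 0.6 s so the window always contains a
majority of isoelectric samples — the median then ignores the QRS itself,
which is why an isolated spike keeps ≥ 95% of its height through this
stage). Subtracting the median removes wander without distorting the QRS.
The first and last `(W−1)/2` samples use the median of the truncated
available window, which keeps output length equal to input length; in
streaming mode the corrected sample is emitted with a fixed `(W−1)/2`
latency.

Only "at least 0.6 s" is prescribed by the method; 0.7 s is this package's
default because it comfortably exceeds the minimum at every supported
sampling rate while still spanning less than one RR interval at resting
rates. It is exposed as `baseline_config(window_time =)`.

### Signed-square window difference

\deqn{T_n = X_{n+2} - X_n, \qquad
      Y_n = \mathrm{sign}(T_n)\, T_n^2}

The two-sample lag approximates the derivative; squaring emphasizes the
steep QRS slopes over P/T waves and residual noise, and keeping the sign
preserves the up-slope/down-slope structure the detector pairs up.

### Threshold initialization

Because the causal filters are still settling at record start, the first
`warmup = 1` s is excluded outright: detection never reports beats there,
and the evaluation harness symmetrically excludes reference beats in that
span. Over the next `init_span = 2` s:

\deqn{T_R = \mathrm{coef}_1 \cdot X_{max}, \quad
      T_{max} = \mathrm{coef}_2 \cdot Y_{max}, \quad
      T_{min} = \mathrm{coef}_2 \cdot Y_{min}}

with defaults `coef1 = 0.5`, `coef2 = 0.4`. The method's source leaves
these coefficients (and `coef`, `Rate` below) unpublished; the defaults
here put the amplitude threshold at half the largest R and the slope
thresholds at 40% of the slope extrema, and the synthetic-recovery tests
pass with these values as-is. All four are configuration parameters.

### MMT detection (S1/S2 pairing)

Within each maximal run of `Y > T_max` the index of the run maximum is a
candidate **S1** (ties break to the earliest index); within each run of
`Y < T_min` the run-minimum index is a candidate **S2**. A beat candidate
is an S1 followed by the next S2 with

* `S1 < S2` and `(S2 − S1) ≤ refractory_window · fs` (default 0.2 s — the
  physiological upper bound on the spacing of a QRS slope pair), and
* `max X over [S1, S2] > T_R`; the R position is the argmax (earliest on
  ties).

A later up-slope run simply replaces an unconsumed S1, and a down-slope
run with no pending S1 is ignored — which is exactly why a *negative*
(inverted) R, whose down-slope precedes its up-slope, is invisible to the
detector (see Limitations).

### Error correction

With `Dif` the index gap between the current and previous accepted R and
`Last_Dif` the running RR estimate:

* `Dif > 1.66 · Last_Dif` — a beat was probably missed: the gap is
  rescanned with all three thresholds at 90% of their current values,
  repeating at 81% and 72.9% (up to `max_redetect = 3` reductions) until
  something is found; recovered beats re-enter the normal acceptance path
  in chronological order.
* `Dif < 0.6 · Last_Dif` — the candidate is implausibly close to the
  previous beat and is rejected (the new peak is discarded; keeping
  whichever peak is larger was considered and left out to keep the
  streaming path single-pass).
* otherwise the candidate is accepted and `Last_Dif <- Dif`.

The first two accepted beats bypass correction and seed `Last_Dif`.

**`Last_Dif` and unexplained gaps.** The method's description leaves open
what `Last_Dif` becomes when redetection fails and the long interval is
accepted anyway. This implementation deliberately does *not* absorb such a
gap into `Last_Dif`: a doubled interval is evidence of a beat lost to
noise, not a physiological RR, and absorbing it makes the 0.6 rule reject
the next true beat — which re-poisons `Last_Dif` and cascades into every
second beat being dropped for the rest of the record. With the guard, one
noise-buried beat costs exactly one FN. The symmetric case (a genuine
sudden halving of heart rate) still detects every beat; it merely triggers
one futile redetection scan per beat until the rate recovers.

Redetected beats do trigger threshold updates, like any accepted beat.

### Adaptive thresholds

After each accepted beat with amplitude `R_R` and slope extrema `D_S1`,
`D_S2`:

\deqn{T \leftarrow T \cdot \mathrm{Rate} +
      m \cdot \mathrm{coef} \cdot (1 - \mathrm{Rate})}

for the pairs (`T_R`, `R_R`), (`T_max`, `D_S1`), (`T_min`, `D_S2`), with
defaults `coef = 0.5`, `Rate = 0.8`. Under a constant input the recursion
converges geometrically to `m · coef` — e.g. `T_R` settles at half the R
amplitude, mirroring the initialization.

**Trend freeze.** If the R amplitude changes in the same direction for two
consecutive beats (`trend_freeze_count = 2`), adaptation is suspended
until the direction changes. A monotone amplitude ramp — typical at the
start of exercise — would otherwise drag the thresholds along and make
them overshoot when the ramp ends. A direction change resets the counter
to 1 (the first change in the new direction), so a simple alternation
never freezes; an equal amplitude resets it to 0. Frozen beats still
update `Last_Dif`.

## Streaming semantics

`detect()` and `detect_stream()` share one incremental engine, so batch
and streamed results are identical by construction for *any* chunking
(down to single-sample chunks; asserted over randomized chunkings in the
tests). The engine finalizes a baseline-corrected sample once its
`(W−1)/2` future window is available and finalizes a threshold run once
the signal has crossed back over the threshold, so end-to-end latency is
bounded by the FIR delay plus the baseline half-window plus the refractory
window. Indices are 0-based everywhere (WFDB convention).

## The synthetic generator

`synth_ecg()` exists so that every stage — and the acceptance checks — can
run with no external data. Each beat is a sum of five Gaussian waves
(P, Q, R, S, T) with fixed default widths and offsets (`SYNTH_WAVES` in
the source); P and T offsets compress with `sqrt(RR)` at high rates. Beat
times follow a linear heart-rate ramp integrated exactly (the next beat
time solves the cumulative-rate equation, avoiding drift over long ramps),
with optional multiplicative RR jitter; beats are only placed while the
full QRS fits inside the record. Because the R apex of the template is
analytically known, the ground-truth indices are exact.

Noise models: a baseline-wander sinusoid (random phase), a 50 Hz
powerline sinusoid, and white Gaussian noise band-passed to 20–150 Hz for
EMG, scaled so the clean-signal-to-noise power ratio matches `emg_snr_db`
exactly over the record; a linear envelope (`noise_ramp`) can grow the
noise with exercise intensity while preserving the stated average power.
Generation is deterministic given `seed` (Mersenne–Twister, inversion
normals).

What the generator does **not** emulate: ectopy and conduction
abnormalities (widened or bizarre QRS), pacing artifacts, electrode
pops/saturation, respiratory HRV, and genuinely non-stationary EMG bursts.
Passing the synthetic recovery checks therefore demonstrates correctness
of the mechanism under controlled, morphologically regular conditions —
not clinical-grade performance on arrhythmia databases, which requires the
WFDB benchmark path (`evaluate_record()` / `pool_results()`) on real
records.

The scenarios used by the tests and the acceptance script are the
`synth_preset()` bundles: `clean` (505 s at 60 bpm, ≈ 504 beats, mild
jitter, no noise), `exercise` (270 s ramping 60→170 bpm, ≈ 515 beats,
10 dB EMG SNR, 0.1 mV powerline, 0.25 mV wander, noise doubling over the
record), `inverted` (120 s with R polarity flipped in the middle third)
and `noisy_powerline` (60 s, 0.5 mV 50 Hz — half the R amplitude). These
sizes keep the full suite under a few seconds on one CPU while exceeding
500 beats where the recovery properties demand it.

## Numerical and degenerate-input choices

* `W` is forced odd by rounding `fs · time + 1` up, so the window median
  is always a single order statistic (no midpoint averaging in the
  interior).
* Ties in run extrema and in the R argmax break to the earliest index.
* `Y = 0` exactly where `X[n+2] = X[n]` (sign(0) = 0).
* A flat signal initializes `T_max = T_min = 0` and detects nothing
  (strict inequalities).
* Inputs shorter than `warmup + init_span` (or than `W`) raise argument
  errors rather than returning empty results.
* Se/+P with a zero denominator return `NA` with a warning — never 0 or
  100.
* Beat matching is greedy nearest-in-time in chronological reference
  order. With the default ±150 ms tolerance and physiological reference
  spacing, reference windows do not overlap and greedy matching equals
  optimal bipartite matching (asserted against exhaustive matching in the
  tests); with tolerances larger than half the reference gap the greedy
  result can be suboptimal.

## Limitations

* **Inverted R waves.** The S1-before-S2 rule encodes positive polarity;
  records with intermittent R inversion lose the inverted segments
  entirely (the `inverted` preset demonstrates the Se drop). A
  dual-polarity mode (running the detector on −X in parallel) would
  mitigate this but is intentionally not the default, to keep the
  reference behavior.
* Threshold initialization assumes the init span contains at least one
  representative beat; a 3 s asystole at record start would initialize
  from noise.
* The notch is fixed-frequency; mains drift beyond the notch bandwidth is
  not tracked (no adaptive LMS notch).
* Evaluation implements beat-location scoring only — no AAMI episode or
  rhythm statistics.
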