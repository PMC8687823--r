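---
title: "vitalink: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vitalink: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalink)
```

vitalink reimplements, at desk scale, the computational chain of a compact
IoT monitor for heart rate, blood oxygen saturation (SpO₂) and body
temperature: a sensor simulator with known ground truth, the patient-side
signal processing, an AES-secured telemetry leg, and the statistical
validation suite used to compare such a device against commercial reference
instruments. This vignette explains the models, the tunable parameters, the
places where the design was genuinely open and how they were settled, and
what the tests do and do not demonstrate.

## The measurement model

A pulse oximeter records reflected light at two wavelengths, red and
infrared. Each channel is a slowly varying baseline (DC, reflectance of
stationary tissue) plus a pulsatile component (AC) at the beat frequency.
Saturation enters through the ratio of ratios

$$R = \frac{(AC/DC)_{red}}{(AC/DC)_{IR}},$$

mapped to percent by an empirical calibration line
$SpO_2\% = a_0 - a_1 R$. Two presets are provided: `classic` $(110, 25)$
and `maxim` $(104, 17)$; the latter is the default because it is the line
published for the sensor family the simulated device models. The forward
map clamps to $[0, 100]$ and flags the clamp (small $R$ legitimately maps
above 100 on the classic line; clamping, not erroring, keeps the pipeline
total). Heart rate is $60/\mathrm{median}(\Delta t_{peaks})$ in bpm.
Temperature readings are quantized to the sensor grid (default 0.0625 °C,
a 12-bit converter), nearest multiple with half-steps rounding away from
zero.

## The synthetic-data generator

The generator stands in for hardware; its defaults are the study
conditions.

* **Pulse shape.** No waveform equation is standard, so the package uses
  $p_0(\theta) = \sin\theta - 0.3\cos 2\theta$ — a fundamental plus a
  0.3-amplitude second harmonic at phase $-\pi/2$ — normalized to zero mean
  and unit peak-to-trough. The shape has a single dominant systolic peak
  and a small late-diastole bump (prominence ≈ 0.8 % of peak-to-peak), a
  stylized dicrotic wave. Zero mean is analytic, which keeps the DC
  estimator unbiased over whole beats.
* **Amplitude convention.** AC means peak-to-trough throughout, in the
  generator and the extractor, so the convention cancels in $R$. The IR
  perfusion index (AC/DC) defaults to 0.05 — a healthy fingertip value —
  and the red AC/DC is $R \cdot (AC/DC)_{IR}$ with $R$ from the inverted
  calibration line, so the configured saturation is encoded exactly.
* **Noise.** Additive white Gaussian, equal SD on both channels; the
  simplest model that exercises robustness. Sensor-specific artifacts
  (motion, ambient light, quantization of the optical front end) are not
  modelled.
* **Temperature error.** The thermometer datasheet gives only a bound
  (±0.5 °C), so per-reading error is truncated Gaussian with
  SD = bound/2, truncated at the bound, then quantized.
* **Sampling.** Default 100 Hz (a common pulse-oximeter configuration;
  the source hardware's rate is not documented), minimum 25 Hz — at least
  twice the highest modelled harmonic across the admissible heart-rate
  band. Default window 10 s. One integer seed drives each synthesis call;
  no global RNG state leaks.

## The extraction pipeline

* **Peak detection** (nowhere specified for the original device) is a
  parameter-light local-maxima search on the baseline-removed, lightly
  smoothed (0.15 s moving average) channel: topographic prominence at
  least 0.3 × the window's peak-to-peak range, minimum separation
  $60/\mathrm{HR}_{max}$ s (taller peak wins), parabolic sub-sample
  refinement. Defaults $\mathrm{HR} \in [30, 220]$ bpm. A flat window
  yields an empty, flagged train.
* **Heart rate** uses the median inter-peak interval — robust to one
  missed or spurious beat, which would drag a mean.
* **DC** is the window mean of the raw channel. This equals the mean of a
  slow moving-average baseline up to that filter's edge effects, and makes
  the noiseless round trip exact; it is also the conventional definition.
* **AC** is estimated by matched projection. The baseline-removed IR
  channel is fitted with its first three harmonics at the detected beat
  frequency; that fitted waveform is the shared reference pulse shape.
  Each channel's AC is its least-squares projection coefficient onto the
  reference, times the reference's peak-to-trough range (the range is
  taken from a fit over the filter's edge-unaffected interior). Rationale:
  a per-beat max-minus-min is a range statistic and inflates under white
  noise, badly enough to push saturation errors past a percentage point at
  1 %-of-DC noise; projection over the whole window averages noise down
  and is efficient. Because both channels project onto the same shape,
  shape-estimation error cancels exactly in $R$ — for noiseless
  proportional channels the recovered $R$ is exact to machine precision,
  while per-channel AC values carry a few-per-mille bias from baseline
  filtering. Three harmonics cover the generator's two-harmonic pulse with
  one to spare; real PPG has more harmonics, and the parameter is exposed.
* **Normal-range classification** treats 60 and 100 bpm as inclusive
  bounds (the verbal definition "between 60 and 100" does not specify
  openness).

## The secure-payload layer

Records serialize to canonical `key: value` lines (fixed field order,
heart rate and saturation as integers, temperature at 4 decimals — the
precision the chain delivers), then AES-128-CBC with PKCS#7 padding and
RFC 4648 Base64 without line wrapping. Design points:

* **Cipher.** Standard AES-128, 10 rounds. The cipher tables are derived
  algebraically (GF(2⁸) inversion plus the affine map) and the
  implementation is pinned byte-exactly to published known-answer vectors
  (FIPS-197 single block; NIST SP 800-38A ECB and CBC multi-block) in the
  test suite. Prose descriptions of round counts vary in quality across
  the literature this device family comes from; the vectors are the
  arbiter.
* **IV.** Fresh random 16-byte IV per message, stored alongside the
  ciphertext. A fixed IV under CBC would leak equality of repeated
  records.
* **Granularity.** Default one ciphertext per record; per-field payloads
  (heart rate / SpO₂ / temperature encrypted separately, as some telemetry
  dashboards store them) are supported via `field`.
* **Transport.** The cloud database is out of scope and replaced by an
  in-process put/get ciphertext store with the same contract. The send
  period is configurable with a default of 5 s (device descriptions of
  this class quote both 5 s and 2 s periods; the default follows the more
  conservative figure). A wrong key or corrupted ciphertext surfaces as an
  authentication failure, never a partial record, and corruption of one
  message does not halt the stream.

## The agreement suite

For $K$ pairs (measured $m_i$, reference $r_i$):
$\mathrm{RMSE} = \sqrt{\sum (r_i - m_i)^2 / K}$,
$\mathrm{MAE} = \sum |r_i - m_i| / K$,
$\mathrm{MRE} = \frac1K \sum |r_i - m_i| / r_i$ (reported both as a
fraction and ×100 as percent — both scales are conventional). The linear
fit regresses reference on measured; $R^2$ is the squared Pearson
correlation — on the packaged SpO₂ table the errors are small but the
correlation is weak (≈ 0.075), which only this definition reproduces.
Bland–Altman differences are measured − reference, limits
$\bar d \pm 1.96\,\mathrm{SD}(d)$ with the sample SD (divisor $K-1$) by
default; the population divisor is available and the choice is recorded in
the report. Points strictly beyond a limit count as outside. All internal
computation is full precision; the print method rounds for display
(RMSE/MAE to 2 decimals, MRE and $R^2$ to 3).

Two observations about the packaged tables, both recomputed by the test
suite and the acceptance script rather than asserted from memory:

* The tables' own printed summary digits mix rounding conventions: the
  error magnitudes match half-up rounding, while the tabulated
  SpO₂ $R^2$ and the percent-scale MREs match truncation of the last
  digit. Tests therefore accept one unit in the last printed place where
  the conventions conflict.
* The claim that every difference point lies within the 95 % limits of
  agreement holds for the heart-rate table only: the SpO₂ table has three
  differences (each −2) strictly below its lower limit and the temperature
  table one (−0.3), under either SD divisor. The corresponding acceptance
  expectation is left failing deliberately; the computed outside-counts
  (0, 3, 1) are what the package reports.

## Problem sizes and test design

The round-trip recovery study runs a 10 × 10 grid of heart rate
(50–180 bpm) × saturation (85–100 %) at 30 s windows — the duration a
spot-check oximetry reading realistically needs for a stable estimate —
once noiseless (every run must land within ±2 bpm and ±1 percentage
point) and once at 1 %-of-DC noise (at least 95 % of runs). The
statistics suite is cross-checked against an independently coded
brute-force oracle on 1000 random small tables at $10^{-12}$ relative
(the OLS intercept and the mean difference are compared at $10^{-12}$ of
the reading scale, being small differences of large terms). Bland–Altman
coverage is checked at $n = 10^4$ Gaussian differences (95 % ± 2 %).

## Limitations

The simulator's clean two-harmonic pulse and white noise make the
extraction task easier than real fingertip PPG with motion artifacts,
baseline wander and ambient-light steps; passing the recovery study shows
the chain is correct and statistically efficient under the stated model,
not that it is field-robust. Calibration lines are taken as given — there
is no optical (Beer–Lambert) model behind them, and saturations outside a
line's attainable range are rejected rather than extrapolated. The secure
layer provides confidentiality of records at rest and in transit within
the emulated path; it does not implement key exchange, authentication of
endpoints, or integrity tags (a flipped ciphertext byte is detected only
through padding/parse failure, which is not a cryptographic MAC).
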