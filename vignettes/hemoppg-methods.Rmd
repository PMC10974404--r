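---
title: "Non-invasive hemoglobin estimation from multi-wavelength PPG: models and methods"
author: "hemoppg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-invasive hemoglobin estimation from multi-wavelength PPG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoppg)
```

## The measurement problem

Total hemoglobin concentration (Hb, g/dL) is normally measured invasively
from a blood draw. Transmissive photoplethysmography (PPG) offers a
non-invasive alternative: light of several wavelengths is shone through a
finger, and the pulsatile part of the transmitted intensity — caused by
arterial blood volume changes with each heartbeat — carries information
about the absorbing species in arterial blood, chiefly oxygenated and
reduced hemoglobin.

`hemoppg` implements a complete estimation pipeline for an
eight-wavelength system (610, 630, 660, 690, 750, 805, 850, 940 nm,
sampled at 100 Hz for 2 minutes per subject), together with a synthetic
cohort generator so every stage can be validated against a known ground
truth without clinical data.

## Optical model

By the Beer–Lambert law, transmitted intensity is
$I = I_0 e^{-\varepsilon(\lambda) c d}$. Static tissue (skin, bone,
muscle) contributes a fixed attenuation; the cardiac pulse changes the
average optical path through arterial blood by $\Delta\langle L\rangle$,
so the per-beat absorbance swing at wavelength $\lambda_i$ is

$$\Delta A_i = \big(\varepsilon_{o}(\lambda_i)\,c_1 +
\varepsilon_{d}(\lambda_i)\,c_2\big)\,\Delta\langle L\rangle,$$

with $c_1 = s\,c_{tHb}$ and $c_2 = (1-s)\,c_{tHb}$ the oxygenated and
reduced hemoglobin concentrations at saturation $s$. In practice
$\Delta A_i$ is estimated by the AC/DC ratio of the PPG channel, and the
ratio-of-ratios features

$$R_{ij} = \frac{AC_{\lambda_i}/DC_{\lambda_i}}{AC_{\lambda_j}/DC_{\lambda_j}}
\approx \frac{\Delta A_i}{\Delta A_j}$$

cancel both the unknown path change $\Delta\langle L\rangle$ and the
emission intensity. With 8 channels there are $8 \times 7 = 56$ ordered
pairs; age and gender are appended for a 58-entry feature vector.

`theoretical_ratio()` evaluates the closed-form $\Delta A_i/\Delta A_j$,
and is the oracle against which the extraction pipeline is tested.

### An important structural property

In this linearized model the ratio $R_{ij}$ depends on $c_1, c_2$ only
through the saturation $s$: total hemoglobin cancels between numerator
and denominator. The *measured* AC/DC ratio of a channel is
$r_\lambda / (1 - r_\lambda \bar p)$, where
$r_\lambda = (\varepsilon_o c_1 + \varepsilon_d c_2) \Delta\langle L\rangle$
is the fractional intensity swing and $\bar p$ the cycle-mean of the
pulse waveform, so Hb re-enters the features only through the
second-order term $(1 - r_\lambda \bar p)$ — a relative feature change of
order $10^{-3}$ per g/dL on the strongest pairs. The consequences for
noise robustness are discussed under *Limitations*.

## Synthetic cohort generator

`generate_ppg()` simulates each channel as
$I(t) = DC_\lambda (1 - r_\lambda\,\mathrm{pulse}(t)) + \text{noise}$,
with $DC_\lambda = I_0 e^{-A_\lambda}$ from the static tissue absorbance
$A_\lambda$. Generator choices, fixed once:

* **Extinction coefficients.** Standard literature values for oxy- and
  deoxyhemoglobin at the eight wavelengths, shipped as configuration
  (only ratios and products with $\Delta\langle L\rangle$ matter to the
  pipeline).
* **Path pulse amplitude.** $\Delta\langle L\rangle = 3\times10^{-6}$
  (units consistent with the extinction table and g/dL), giving
  perfusion indices of roughly 2–6% across channels — typical for
  transmissive finger PPG.
* **Pulse waveform.** Raised-cosine systolic wave (0.34 of the cycle)
  plus a dicrotic bump (amplitude 0.25, width 0.26), normalized to unit
  range. The widths make the template effectively band-limited to the
  physiological 1–10 Hz PPG band (out-of-band energy about $2\times10^{-4}$),
  so the 10 Hz low-pass stage is near-transparent for clean signals.
  Only the AC amplitude enters the feature model.
* **Cohort distributions.** Hb from the mixture
  $0.8\,N(14,1) + 0.2\,U(7,19)$ truncated to (4, 22) g/dL —
  concentrated in the clinical normal range with sparse abnormal tails;
  SpO2 $\sim N(0.97, 0.02)$ truncated to [0.90, 1]; heart rate
  $N(72, 10)$ bpm; respiratory rate $N(0.25, 0.05)$ Hz; age
  $N(41.7, 24.3)$ years truncated to [18, 90]; gender Bernoulli(100/249)
  male. Hemoglobin is sampled independently of the other covariates.
* **Noise model.** White Gaussian noise at 0.3% of DC per channel
  (independent across channels), a respiratory baseline-wander sinusoid
  at 5% of DC, a 50 Hz mains tone at 1% of DC, and Gaussian-shaped
  motion transients (probability 0.03 per 5 s segment, 5% of DC), the
  latter three shared across channels as optical-path disturbances.

What the generator does **not** emulate: photon-transport/scattering
effects (wavelength-dependent path lengths, melanin), beat-to-beat
morphology variability, sensor nonlinearity, and any coupling between
hemoglobin and demographics. Tests passing on this generator therefore
validate the pipeline's signal-processing and learning machinery, not
clinical performance.

## Preprocessing

Each channel passes through three stages (`preprocess_channel()`):

1. **Low-pass filter**: 101-tap Hamming-window linear-phase FIR with a
   10 Hz cutoff, normalized to exact unit DC gain, applied
   forward–backward for zero net group delay. Endpoints are
   odd-reflection padded to suppress start-up transients. Passband
   (≤ 8 Hz) is flat to well under 1%; stopband attenuation at 25 Hz
   exceeds 40 dB by a wide margin.
2. **Baseline-drift removal**: 7-level coif5 discrete wavelet transform;
   the level-7 approximation (the band below $f_s/2^8 \approx 0.39$ Hz at
   100 Hz) is zeroed and the signal reconstructed. The DWT is a
   periodized orthogonal transform applied after symmetric reflection
   padding (margin ≥ 1024 samples so the circular wrap sits far from
   retained samples); reconstruction is exact to machine precision.
3. **Comb filter**: feed-forward average of $M = 4$ cardiac periods,
   $y[t] = \tfrac1M \sum_k x[t - kT]$. Exactly periodic signals pass
   unchanged; white noise is attenuated by $1/\sqrt M$ and isolated
   transients to $1/M$. The period is estimated once per record from the
   channel with the strongest relative pulsation: FFT magnitude peaks in
   0.7–3 Hz are scored by their summed magnitude at the first three
   harmonics (plain peak-picking can lock onto a strong second
   harmonic), and the winner is refined by parabolic interpolation. The
   comb uses the fractional period with per-lag rounding so rounding
   error does not accumulate.

Because baseline removal destroys the mean, the DC feature is read from
the low-pass stage output and the AC feature from the fully preprocessed
signal.

## Feature extraction

Signals are cut into non-overlapping 5 s windows. Per window and channel,
beats are landmarked by first-derivative sign changes; prominence filters
keep maxima in the top 40% and minima in the bottom 40% of the window
swing (transmissive PPG dips on systole, so beat extremes sit near the
global extremes while dicrotic bumps stay mid-range). Landmark values are
read from the vertex of a least-squares parabola over ±4 samples (no
extrapolation beyond the fitted span), and each trough is measured
against a baseline interpolated between its flanking peak levels, which
cancels residual low-frequency drift to first order. AC is the mean
peak-to-trough amplitude over complete cycles; DC is the window mean of
the low-pass signal. The 56 ratios are computed per window and aggregated
across windows by the median (robust to windows with residual
artifacts); age and gender are appended. All 58 features are z-scored
with training-set statistics before selection and regression.

On noiseless synthetic records the extracted ratios agree with
`theoretical_ratio()` to well under 2% for all 56 pairs.

## Feature selection: SVR-RFE

A linear-kernel $\varepsilon$-SVR (C = 1, $\varepsilon$ = 0.1) is trained
on the surviving features; feature importance is the squared entry of the
primal weight vector $w = \sum_i \alpha_i x_i$; the single least
important feature is removed; 5-fold CV RMSE is recorded for every
subset size down to one. The chosen size $k^*$ minimizes CV RMSE, ties
toward smaller $k$. All 58 features, including age and gender, are
treated uniformly. On clinical data the reference protocol reports a
best subset of 29 features; that number is dataset-specific and
illustrative only.

## Regression: ensemble extreme learning machine

A single ELM with $K$ hidden neurons maps
$\hat y = \sum_{j=1}^{K} \beta_j\, g(w_j x + b_j)$ with
$g(z) = 1/(1+e^{-z})$. $W$ and $b$ are drawn i.i.d. Uniform(−1, 1) from a
seed and frozen; the output weights solve $H\beta = Y$ in closed form via
the SVD pseudoinverse, $\beta = H^+ Y$ (singular values below
$\max(\mathrm{dim}) \cdot \epsilon_{mach}$ relative are cut; no ridge
term). Note the bias sits inside the activation — the standard ELM form.

Random initialization makes a single ELM unstable; the ensemble trains
$P$ members differing only in their hidden layers (member seeds derived
deterministically from the base seed by an integer mixing rule that stays
within exact double precision) and averages their predictions. Defaults
$P = 200$, $K = 20$, sigmoid. Prediction spread across re-trainings
shrinks roughly as $1/\sqrt P$; the test suite verifies it is
non-increasing over $P \in \{1, 10, 50, 200\}$.

## Evaluation protocol

`repeated_evaluation()` repeats (default 200 times): random 8:2 split
(249 subjects → 199 train / 50 test), standardize on the training rows,
apply the RFE mask, train the EELM, predict the held-out subjects. By
default the RFE ranking is computed once on the first training split and
reused (a config flag enables per-repeat re-ranking). Reported metrics
are averaged over repeats:

* **RMSE** and **Pearson correlation** (two-sided p from the t transform,
  n − 2 df);
* **Bland–Altman**: mean difference (predicted − reference), sample SD,
  limits of agreement mean ± 1.96 SD, and the fraction of points within
  the limits (≈ 95% for normal differences);
* **Error grid** (Clarke-style, adapted to hemoglobin): region A
  |error| ≤ 1 g/dL, region B 1 < |error| ≤ 2 g/dL, region C > 2 g/dL,
  with inclusive boundaries (an error of exactly 1 g/dL is region A).

## Numerical choices and degenerate inputs

* Windows with no complete cardiac cycle on any channel are flagged
  invalid; subjects with no valid window raise an unusable-record error;
  cohort featurization drops such subjects with a warning.
* A repeat whose test split has degenerate variance is skipped with a
  warning and counted in the report.
* Constant target vectors are rejected by `svr_rfe` (degenerate-target
  error); equal CV scores resolve to the smallest subset size.
* All generators and trainers are pure functions of (parameters, seed)
  and restore the caller's RNG state.

## Problem sizes used in the shipped checks

The validation suite exercises the pipeline at the protocol's own scale
where the property demands it (2-minute, 100 Hz records; parameter
recovery on 250-subject cohorts with an EELM of 200 members), and at
reduced sizes (30 s records, small cohorts, P ≤ 50) for unit-level
properties where length is irrelevant. The repeated-evaluation protocol
defaults to 200 repeats in configuration; its correctness tests run 2–12
repeats, which is sufficient to pin down determinism and averaging
behaviour.

## Limitations

* **Hb observability under the linearized model.** As derived above,
  total hemoglobin cancels at first order in the ratio features; the
  usable signal is the second-order $(1 - r\bar p)$ term,
  $\sim 0.1\%$ relative per g/dL. On noiseless synthetic cohorts the
  pipeline recovers Hb essentially perfectly (test PCC ≈ 0.98, RMSE
  ≈ 0.45 g/dL). Under the full noise model the per-pair feature noise
  (0.7% for typical records, several percent for weakly pulsatile
  channels and high respiratory rates) exceeds that signal, and test-set
  correlation drops well below the noiseless case. This is a property of
  the idealized forward model, not of the estimator: real tissue adds
  wavelength-dependent scattering and path-length effects that break the
  first-order cancellation, which is one reason the method works better
  on real data than this simulator can show. Conversely, passing the
  noiseless recovery check validates the machinery, not clinical
  accuracy.
* The simulator treats the eight channels as simultaneously sampled;
  the real acquisition time-multiplexes the LEDs.
* No motion-reference cancellation or beat-quality classification is
  implemented; heavy artifacts are handled only by the comb filter and
  the median window aggregation.

## A minimal example

```{r example, eval = FALSE}
cfg <- default_config()
cfg$cohort$n <- 40            # small demo cohort
cfg$acquisition$duration <- 30
cfg$model$P <- 50
cfg$evaluation$n_repeats <- 10
cfg$selection$use_rfe <- FALSE

report <- run_experiment(cfg, verbose = FALSE)
print(report)
```
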