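---
title: "Quantifying trace odorant impurities from GC-coupled calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying trace odorant impurities from GC-coupled calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcimpurity)
```

## The measurement model

An olfactory receptor channel recorded with a calcium sensor acts as a
single-analyte detector with a sigmoidal transfer function. When the
odorant headspace is first separated on a GC column, each component of the
sample arrives at the antenna at its own retention time, so a contaminant's
response is temporally isolated from the main odorant's. The pipeline
turns this into a concentration measurement in five stages.

**Bleach correction.** Raw fluorescence decays with illumination. We model
the decay as a single exponential with offset, $A e^{-t/B} + C$, fitted by
least squares to the samples *outside* known or automatically detected
response windows, and subtract the decay component while keeping the
offset: $F^{corr}_i = F_i - A e^{-t_i/B}$. A single-exponential model is an
assumption: multi-component bleaching or slow drifts of other origin are
absorbed only approximately.

**ΔF/F.** Relative fluorescence change is $(F_i - F_0)/F_0$ with $F_0$ the
mean over an explicit pre-stimulus baseline window (default: the first
60 s of a GC-coupled recording, 5 s of a direct-stimulation recording).
Correction precedes ΔF/F; with $F_0 \approx C$ this keeps amplitudes
comparable across trials. The order is a design choice (either order is
defensible); it matters little here because of the normalization below.

**Normalization.** ΔF/F amplitudes vary across animals (expression level,
optics). Each animal's traces are divided by that animal's response
amplitude to a shared reference stimulus — the first response peak of
ethyl butyrate, which corresponds to the ethyl acetate contamination that
ethyl butyrate samples characteristically carry. Because the reference
peak sits at the same elution time as the analyte and multiplicative
factors (gain, residual bleach mismatch, measurement shape factors) are
common to both, they cancel exactly in normalized units. This is also why
the subtractive bleach correction, which leaves a factor
$b(t_{peak})/C$ on recovered amplitudes, introduces no bias into the final
estimate.

**Calibration and inversion.** Normalized peak responses $R$ to a dilution
series of the pure contaminant are fitted with the logistic
$$R(c) = \frac{R_{max}}{1 + e^{-h (c - EC_{50})}}$$
on the log$_{10}$-dilution axis $c$; $R_{max}$ is the saturation
asymptote, $EC_{50}$ the half-effective dilution, $h$ the steepness. The
model has a zero lower asymptote by construction; inhibitory responses are
handled by sign at the measurement stage, not by a four-parameter curve. A
sample's response in the contaminant's elution window is inverted through
the fitted curve, $c = EC_{50} - \ln(R_{max}/R - 1)/h$, giving the
apparent delivered concentration.

**Co-dilution and aggregation.** A contaminant dilutes with its sample, so
its relative fraction in the neat sample is (in log$_{10}$) the apparent
concentration minus the sample dilution. Fractions measured at different
sample dilutions are averaged as *linear* fractions (the mean of
$10^{-5.4}$ and $10^{-5.1}$ is $10^{-5.22}$); the alternative log-space
mean differs only at display rounding but needs a tie-breaking rounding
rule, so the linear mean is the default. Display rounding is one decimal
on the log$_{10}$ fraction and one significant figure on ppm and percent;
full precision is always retained. The spread of the per-dilution
fractions is reported as an explicit consistency check — if the
contaminant truly co-dilutes, dilutions should agree to within calibration
error.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `window_halfwidth` | 10 | s | Elution landmarks (~100 s vs ~240 s) are far apart; ±10 s covers alignment error and the smoothed apex. |
| `min_prominence` | 3 × robust noise SD | trace units | Peak detection threshold; robust SD is `1.4826·median|diff|/√2`, insensitive to drift and sparse transients. |
| `min_width` | 2.5 samples | s | Genuine elution/response peaks span many samples; single-sample noise spikes do not. |
| `smooth_sd` | 2 | s | Gaussian pre-measurement smoothing, about a quarter of the calcium kernel time constant; see below. |
| `detection_mult` | 2 | — | Responses below 2 × the baseline noise SD are "not detected": no concentration is reported. |
| `search_window` | 30 | s | Alignment search half-window around the reference retention time. |
| Saturation cut | 0.95 × Rmax | — | Near-saturating sample responses are flagged and excluded from aggregation rather than clipped (inversion is ill-conditioned there). |

**Why smooth before measuring.** The response amplitude is the signed
extremum of (value − local baseline) in a ±10 s window. On an unsmoothed
trace the extremum of ~20 noisy samples has a null distribution centred
about two noise SDs above zero, which both inflates weak responses and
defeats a threshold expressed in noise SDs. Smoothing with a kernel
matched to the calcium response (SD 2 s against a decay constant of ~8 s)
brings the extremum's null scale down to the threshold's scale, and the
common amplitude shape factor it introduces cancels under reference
normalization. The detection threshold itself is computed from the
*unsmoothed* bleach-corrected baseline (first differences of a smoothed
trace underestimate its own SD).

## The synthetic-data generator

The generator is the package's stand-in for fly recordings and defines the
conditions under which the pipeline is validated:

* GC-coupled trials: 1 Hz for 540 s; direct-stimulation trials: 4 Hz for
  20 s with two 1-s pulses injected at 6 and 8.5 s, arriving after a
  0.75 s delay at 6.75 and 9.25 s.
* Elution peaks are symmetric Gaussians at substance-specific retention
  times (ethyl acetate ~100 s, benzaldehyde ~240 s); FID apex height is
  response-factor × delivered amount; contaminants co-dilute.
* Response kernels rise instantaneously and decay exponentially
  (τ = 8–10 s); above a saturation amplitude (0.3 ΔF/F) the time constant
  stretches linearly, reproducing the right-tailing of near-saturating
  responses. Mixture responses add in signed amplitude — sufficient to
  reproduce the inhibitory-to-excitatory crossover when an excitatory
  contaminant is titrated into an inhibitory odorant, but deliberately not
  a model of syntopic (competitive) interactions.
* Fluorescence is `bleach(t) · (1 + Σ kernels) + C·ε`: bleaching is
  multiplicative (`A = 250`, `B = 180 s`, `C = 750` counts, jittered ~10%
  per animal), noise is additive Gaussian in ΔF/F units. The default
  `noise_sd = 0.006` gives the ethyl butyrate reference peak (~0.116
  ΔF/F) a signal-to-noise ratio of about 20 — recovery tests are
  meaningful but stable. Per-animal gain is lognormal with log-SD 0.2.
  Neither the imaging noise level nor the gain spread is an empirical
  estimate; both are declared defaults chosen to be realistic.
* The ethyl butyrate reference sample carries an ethyl acetate
  contamination of relative fraction $10^{-3.6}$ (so the reference peak
  corresponds to $10^{-5.6}$ ethyl acetate at the standard $10^{-2}$
  dilution) plus two further trace contaminants, giving its
  characteristic four-peak response, with the unidentified impurity
  eluting between ethyl propionate and ethyl butyrate.

What the generator does **not** emulate: optics and point-spread, motion
artifacts, GC column thermodynamics (retention-time drift), spike-to-
calcium transforms, multi-exponential bleaching, correlated noise. Passing
tests therefore show that the estimators are correct under the stated
statistical model, not that real recordings satisfy that model.

## Numerical choices

* **Bleach fit.** For fixed $B$ the model is linear in $(A, C)$, so the
  fit seeds from a 40-point log-grid profile over $B$ and refines with
  Levenberg–Marquardt (tolerances $10^{-15}$, bounded restarts at
  0.3× and 3× the seed). $B$ is bounded to $[\mathrm{span}/100,
  5\,\mathrm{span}]$ of the full trace: on short pre-stimulus segments
  $B$ is unidentifiable and unbounded $(A, B)$ ridges extrapolate
  arbitrarily into the masked response windows. When $|A|$ is negligible
  the trace is effectively constant, $B$ is reported as `NA`
  ("unidentifiable") and correction reduces to subtracting a constant.
* **Logistic fit.** Seeds: $R_{max,0} = \max R$, $EC_{50,0}$ at the point
  nearest $R_{max,0}/2$, $h_0 = 1$; bounds $R_{max} \in (0, 10 \max R]$,
  $h \in (0, 50]$. Near-step data can drive $h$ to the boundary where the
  saturated logistic has a singular Jacobian; the fit then falls back to
  a dense (EC50, h) grid with $R_{max}$ profiled out, which always
  returns the bounded-box optimum. Points are unweighted; per-point SEM
  is carried for reporting only. The calibration is fitted to
  across-animal mean responses (per-animal pooling would weight animals
  by their noise).
* **Peak attribution.** When several detected peaks fall in one search
  window, candidates below half the largest amplitude are discarded and
  the remaining peak nearest the expected (aligned) retention time is
  attributed to the substance; exact ties go to the larger amplitude.
  Local baselines are medians of 5-s flanking bands — robust to
  neighbouring peaks.
* **Masks.** Response windows for the bleach fit come from trial metadata
  when present; otherwise one iteration of fit → flag |residual| > 3
  robust SD → refit.
* **Degenerate inputs** are refused with diagnostics rather than guessed
  at: zero baselines, empty windows and ROIs, all-zero dose–response
  tables, missing reference peaks, out-of-range measurement windows.

## Validation problem sizes

The test suite validates the pipeline at the scale of the original
experiments: three animals per simulated experiment, nine calibration
dilutions ($10^{-10}$–$10^{-2}$), two sample dilutions ($10^{-2}$,
$10^{-1}$). Monte-Carlo checks use 200 replicates for EC50 recovery at 5%
noise and 100 full simulated experiments (contamination between
$10^{-6.5}$ and $10^{-4.5}$) for end-to-end recovery; qualitative pattern
checks (excitation at the contaminant's elution time, inhibition at the
main odorant's; the mixture sign crossover) use 50 seeded replicates.
Experiments whose sample responses all fall below the detection threshold
return an honest "not detected" verdict rather than a number; at the
bottom of the contamination range this is the correct answer, and such
replicates are counted against recovery in the validation summaries.

## Limitations

* Identity of the contaminant is an input (chosen by retention-time
  matching); the package reports retention-time agreement as a check but
  performs no chemical identification and no deconvolution of co-eluting
  substances.
* The additive-amplitude mixture model ignores syntopic suppression: a
  contaminant that dominates the purified (GC-separated) response may
  contribute less in a simultaneous mixture.
* Inverse calibration is only defined strictly inside $(0, R_{max})$;
  responses near either end are flagged (`not_detected` / `saturated`)
  and excluded, so very weak and near-saturating contaminations carry
  asymmetrically larger uncertainty.
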