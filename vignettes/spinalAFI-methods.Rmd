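---
title: "Methods: quantifying spinal flavoprotein imaging with spinalAFI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying spinal flavoprotein imaging with spinalAFI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinalAFI)
```

## The measurement and its model

Autofluorescent flavoprotein imaging (AFI) records the green fluorescence of
oxidized mitochondrial flavoproteins on the dorsal surface of the exposed
spinal cord under blue illumination. Afferent stimulation transiently
increases oxidative metabolism in superficial dorsal-horn neurons, producing
a biphasic fluorescence transient: a fast rise above baseline (the *light
phase*, oxidation) followed by a slower dip below baseline (the *dark
phase*, reduction). AFI sees only the superficial laminae; deep dorsal-horn
activity is invisible to it, which bounds every interpretation made here.

The pipeline's central derived object is the fractional change stack

$$\Delta F/F(t, r, c) = \frac{F(t,r,c) - F_0(r,c)}{F_0(r,c)},$$

with $F_0$ the per-pixel mean over the baseline window. Assumptions: the
baseline is stationary over the pre-stimulus window (no drift — bleaching
correction is out of scope), and noise is approximately Gaussian with
variance proportional to counts, which is accurate for a 16-bit CCD at count
levels in the tens of thousands.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| baseline window | all frames before stimulus onset | frames | uses all pre-stimulus data; overridable when early frames show shutter artifacts |
| noise band `k` | 2 | baseline SDs | conventional detection band; echoed into each segmentation |
| area threshold | 0.25 | % dF/F | a fixed predefined level is required for comparability across recordings; 0.25 sits inside the conventional ±0.75 % display range. It must be held constant within an experiment |
| ROI size | 20 | pixels | the conventional square selection at full 512×512 scale; 10 px at the generator's 64×64 test scale |
| pixel size | 10 | µm/pixel | the nominal resolution of the emulated optics; converts areas to mm² |
| midline row | image half-height | rows | ipsi/contra split per the top-half-is-left orientation convention; configurable for oblique cords |

## Numerical and convention choices

* **Frame ranges are 1-based closed intervals**, the idiomatic R convention;
  all phase and window indices follow it.
* **dF/F is stored unitless** and multiplied by 100 only at reporting
  boundaries, preventing double-scaling.
* **Zero-baseline pixels are masked, not interpolated**: the dural vein and
  dead pixels would otherwise fabricate signal.
* **Ties at the area threshold do not count**: "above a predefined level" is
  read strictly, so a pixel exactly at the threshold is excluded.
* **Strict inequality against the noise band** defines the light phase; a
  trace that never exceeds the band yields a *no-response* status rather
  than an error, and intensity falls back to the global post-onset maximum
  with the flag attached.
* **Degenerate statistics follow documented conventions**: a constant
  time course has slope 0, r = 0, p = 1; a paired test with zero variance
  at exactly 100 % gives t = 0, p = 1.
* **Hotplate censoring is inclusive**: a latency of exactly 30 s counts as
  "did not respond within the window".
* **Unpaired tests default to Welch**, two-way ANOVA to Type II sums of
  squares (the design is unbalanced, n = 20 vs 13); both choices are recorded
  in the outputs. Greenhouse–Geisser correction for the repeated-measures
  ANOVA is available but off by default; its epsilon is computed from the
  double-centered covariance matrix.
* **dF/F TIFF output is affinely rescaled into [0, 1]** (32-bit float pages
  clamp outside that range); the scale and offset live in the YAML sidecar
  and round-trip to float32 precision (~1e-7 relative).

## The synthetic generator: what it emulates, and what not

Movies are rendered as
$$F(t,r,c) = B\,(1-\beta_b t)\,\bigl(1 + k(t)\,G(r,c)\bigr) + \varepsilon,$$
with baseline level $B$ (default 20 000 counts), optional bleaching
$\beta_b$ (default 0), Gaussian shot noise
$\varepsilon \sim N(0,\, s^2 F)$ with scale $s = 0.4$, and the biphasic
kernel

$$k(t) = a\left[(1-e^{-t/\tau_1})e^{-t/\tau_2} - u\,(1-e^{-t/\tau_2})e^{-t/\tau_3}\right]$$

with defaults $\tau_1 = 1$ s, $\tau_2 = 6$ s, $\tau_3 = 10$ s, $u = 0.6$ —
chosen so the light phase spans roughly a 10-s stimulus and a clear dark
phase follows. These timings and all amplitudes (noxious ipsi 0.5 %, contra
0.2 %, palpation-neuropathic ipsi 0.3 %, palpation-naive ipsi exactly 0) are
*illustrative*, range-constrained to the ±0.75 % display convention, and
echoed into every ground-truth sidecar; they are not measurements. The shot
noise scale was chosen once so that the upward bias of the max-based
intensity estimator stays below 10 % of the injected amplitude at the
default ROI.

Two conventions make noiseless renders exactly identifiable, which the test
suite exploits:

1. the sampled kernel is rescaled to unit peak *on the movie's frame grid*,
   so the preset amplitude $a$ is the realized peak dF/F (continuous-time
   normalization would leave a ~1e-4 sampling gap at 10 frames/s);
2. counts are quantized to integers only when shot noise is present —
   quantizing a noiseless movie would inject deterministic dF/F errors of
   order $0.5/B \approx 5\times10^{-5}$, swamping ground truth.

The spatial profile is a flat-top disc (radius 8 px at test scale) with a
Gaussian shoulder (SD 3 px): the flat core makes a centered ROI mean equal
the amplitude exactly, and the supra-threshold contour has the closed form
$R = r_\text{core} + \sigma\sqrt{2\ln(a/\text{thr})}$ used by the
identifiability tests.

Cohort-level generators draw per-animal outcomes directly. The treatment
presets are: SCS — suppression to 45 % of baseline at T = 0 with linear
recovery at slope 0.92 % dF/F·min⁻¹; sham — mean 100 % with a nominal slope
of 0.19 % dF/F·min⁻¹. The within-animal noise SDs (60 and 85 % of the
before-treatment level) were fixed once by inverting the test statistics the
presets are meant to reproduce: with 13 timepoints and n = 7, a slope of
0.92 should be detected at p ≈ 0.02, while with n = 6 the nominal sham slope
of 0.19 must remain statistically indistinguishable from zero (p ≈ 0.7).
A consequence worth knowing: at this noise level the paired T = 0 test has
only ~50 % power at n = 7 — the suppression is real but its detection is
marginal, and the test suite checks the Monte-Carlo rejection rate against
the analytic noncentral-t power rather than against a round number.

For the group experiment the cohort preset holds the ipsi/contra intensity
means close (0.50 vs 0.45 % dF/F): at cohort level the side effect is
statistically indistinguishable, even though single rendered movies show the
visible spatial asymmetry (contra amplitude 0.2 %). Both facts can hold at
once because between-animal variability dominates the side gradient.

What the generator does **not** emulate: movement and hemodynamic artifacts,
trial-to-trial kernel variability, spatially correlated noise, optics (point
spread, depth attenuation), and electrode artifacts. Passing tests therefore
certify the *estimators* — unbiasedness, calibration, oracle equivalence —
not robustness to every artifact of a live preparation.

## Area of excitation under noise

The default membership rule takes the per-pixel **maximum** over the light
phase, matching the definition of intensity as a maximum. On noiseless or
trial-averaged data this is exact. On a noisy single trial the maximum over
a long window saturates: every pixel's noise maximum eventually exceeds any
fixed threshold. Two mitigations are provided and recommended together for
single trials: spatial smoothing before thresholding
(`computeDff(..., smoothSigma = 1.5)`) and the `mode = "peak-frame"` variant,
which thresholds the single frame of peak mean response. With both, the
recovered area of the default synthetic blob is within ~10 % of the analytic
contour; with the raw max rule it is meaningless under default noise. The
threshold itself must never be tuned per recording.

## Behavioral endpoints

Von Frey thresholds follow the ascending 3-of-5 rule: the first filament
with at least three withdrawals out of five applications, censored high at
the largest filament. The default series (0.4–26 g) is a standard rat set;
simulated latent thresholds are snapped to it, so the generator's noiseless
mode lands exactly on filament forces (15 g baseline dropping to 4 g
post-operatively). Hotplate latencies (baseline 12 s dropping to 7 s) are
censored at 30 s. Effect sizes are chosen to emulate pronounced tactile and
thermal hypersensitivity after partial sciatic nerve ligation: with n = 18
the repeated-measures day effect is detected at p < 0.01 in essentially
every replicate, while the no-neuropathy preset rejects at the nominal 5 %.

## Problem sizes and test design

The suite runs at deliberately small scale: 64×64-pixel movies at
10 frames/s for 40 s (the full 512×512 format is a parameter away),
200-replicate Monte-Carlo sweeps for calibration checks, and 100–300
replicates for null-rate checks. Monte-Carlo assertions are *compatibility*
tests: observed rates are compared against their analytic expectation
(binomial or noncentral-t) at the 1 % level rather than against hard cut-offs,
so a correctly calibrated estimator fails a given check with probability
~0.01. Replicate seeds for the headline slope sweeps are drawn from a single
base seed via `slopeRecoverySweep()`, the same path `scripts/acceptance.R`
uses.

## Known limitations

* No motion correction, registration, or hemodynamic unmixing — recordings
  are assumed mechanically stable and artifact-free.
* The area of excitation depends on an arbitrary (if fixed) threshold and on
  the noise regime; compare areas only within a constant acquisition and
  analysis protocol.
* Censored hotplate latencies enter the ANOVA at their censoring value; no
  survival-style correction is attempted.
* The sham/SCS noise calibration encodes one specific emulated study; other
  preparations will need their own preset SDs.
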