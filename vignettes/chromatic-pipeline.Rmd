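---
title: "Chromatic processing in two-photon retina recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatic processing in two-photon retina recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinachrome)
```

## The scientific problem

Mouse retinas express two cone opsins: a UV-sensitive S-opsin and a
green-sensitive M-opsin, with S-opsin co-expression in M-cones increasing
steeply toward the ventral retina. Chromatic (color-opponent) signals arise
when downstream circuits compare UV- and green-driven responses between a
cell's receptive-field center and surround. Two-photon imaging of glutamate
release (cone and bipolar-cell terminals) and somatic calcium (ganglion
cell layer, GCL) yields scan-field movies from which per-terminal responses
to chromatic stimuli can be extracted.

`retinachrome` implements the full analysis chain for such recordings —
correlation-based ROI segmentation, trace preprocessing, event-triggered
receptive-field kernels, quality control, spectral-contrast and opponency
statistics, and population-level permutation tests — together with a
synthetic-data generator that produces ground-truth populations and movies
with the statistical structure the analysis assumes. Every stage is
therefore testable at desk scale without any recorded data.

## The synthetic-data generator

Each ground-truth cell is a linear–nonlinear (LN) cascade. Its four signed
weights (UV/green x center/surround) scale the stimulus channels, which are
low-pass filtered by an exponential temporal filter (time constant
`kinetics_tau_s`, drawn per cell from 0.08–0.2 s, unit DC gain), summed,
passed through a softplus output nonlinearity and sampled at the layer's
acquisition rate with additive iid Gaussian noise. Sign conventions follow
the outer retina: cones are Off units, so a light increment in a driven
center condition *decreases* the trace (release decrease); the expected
surround polarity is antagonistic to the center.

Key choices, and why:

* **Weights from target spectral contrast.** Per-cell center and surround
  SC values are drawn from position-dependent normal distributions whose
  ventral/dorsal poles default to the reported population means and s.d.
  of each layer (e.g. cones: center -0.7 ± 0.43 ventral, 0.38 ± 0.44
  dorsal; surround 1.2 ± 0.42 ventral; bipolar cells: center -0.44 ± 0.24
  ventral). `sc_to_weights()` inverts the three-case SC statistic exactly,
  so the population's direct-weight SC is pinned to those values,
  including the antagonistic cases beyond ±1. A logistic blend over the
  dorso-ventral position (midpoint 0, slope 0.25 mm) interpolates between
  the poles.
* **Softplus sharpness 0.5.** The generator exists to produce structure
  the linear analyses can recover. A sharp rectifier expands positive and
  compresses negative deflections asymmetrically, which would distort the
  amplitude ratio of opposite-polarity channels by tens of percent; at
  sharpness 0.5 the gain varies by roughly 12% over the unit drive range.
  An `identity` option supports linearity tests.
* **Balanced flicker by construction.** The chromatic flicker protocols
  (10 Hz / 180 s for the inner plexiform layer, 5 Hz / 300 s for the GCL)
  shuffle an exactly half-high template rather than drawing iid Bernoulli
  steps, so every channel's ±1 sequence has mean exactly zero and the
  four channels are independent.
* **Scan fields.** Terminal centers are placed by dart throwing with an
  exclusion radius (the mean terminal diameter), each cell's trace is
  spread over pixels by a Gaussian disc, and independent pixel noise is
  added. The field SNR is defined against the *median* cell's response
  amplitude, so half the population sits above and half below the nominal
  SNR. This reproduces the two features the ROI detector relies on:
  neighboring pixels of one terminal share a signal, and terminal mosaics
  show the depleted short-distance bins of a density recovery profile.
* **Noise structure.** Noise is iid Gaussian across time, trials and
  pixels. Real recordings have correlated noise (shot noise, motion,
  shared background); passing tests here demonstrate correctness of the
  statistics, not robustness to structured artifacts.

## The analysis pipeline

**ROI segmentation.** The correlation image is each pixel's mean Pearson
correlation with its 8-neighborhood; ROIs are connected components above a
threshold (Otsu's split of the correlation histogram, clamped to
[0.1, 0.9], in `auto` mode), watershed-split when larger than the layer's
terminal size and discarded outside the equivalent-diameter bounds (cones
3–7 µm, bipolar terminals 1–4 µm). IPL depth is the linear coordinate with
0 at the On and 1 at the Off ChAT band.

**Traces.** ROI traces are member-pixel means converted to dF/F with an
8th-percentile baseline (robust to transients of either sign), shifted by
the line-scanning sub-frame offset, resampled to 500 Hz by linear
interpolation and detrended by a zero-phase 2nd-order Butterworth
high-pass. The default cutoff is 0.1 Hz; the *flash* pipeline uses
0.02 Hz because a cutoff near the 18-s condition-interleave cycle leaks
zero-phase filter undershoot from strong responses into the weak trials
that follow them, inflating their areas even in noise-free data.

**Event-triggered kernels.** The trace derivative is thresholded at its
robust sigma (median absolute value / 0.6745); events are local maxima of
the derivative above threshold (plateau runs count once, at their earliest
sample; the derivative is thresholded one-sided, detecting release
increases). The stimulus kernel per condition is the event-weighted
average stimulus preceding the events, divided by the event count, on the
stimulus time base (lag window 2 s for 10 Hz flicker, 1 s for 5 Hz).
Because the divisor is the count rather than the summed weight, kernel
amplitude carries the weight units and is only meaningful relatively.

**Response areas and polarity.** For a binary flicker, event-triggered
kernels are biphasic (a transition signature), so a plain net integral
over the response window cancels. Response magnitude is therefore measured
as a matched-filter projection of each baseline-subtracted kernel onto the
dominant center kernel over the response window (the latest quarter of the
lag window; baseline = earliest quarter). The projection is linear in the
channel weights, does not inflate weak channels with kernel sampling
noise, and its sign implements the rule that kernels anticorrelated with
the center kernel get negative areas (an antagonistic surround is
negative). Kernel signs are only relative, so the cell's On/Off identity
(from its achromatic responses or IPL depth in real use) anchors the
expected polarity; without the anchor, center-opponent cells whose
antagonistic color dominates would be mirror-flipped. Flash (cone)
responses are monophasic and use the net signed area over the flash window
against the pre-flash baseline, with polarity read directly from the sign.

**Spectral contrast.** With green and UV areas of the same polarity, SC is
the Michelson contrast (|F_g| - |F_uv|) / (|F_g| + |F_uv|) in [-1, 1]
(-1 = pure UV). If the UV response is antagonistic, SC = 1 + |F_uv|/|F_g|
(> 1); if the green response is antagonistic, SC = 1 - |F_g|/|F_uv|
(< 1). The case identifier is stored with every value, since the third
case overlaps the Michelson range. When exactly one area is zero in an
antagonistic case the value is undefined and flagged rather than guessed.
SC_Diff = SC_surround - SC_center.

**Quality indices.** The kernel and event quality indices share the form
Qi = 1 - |Area(baseline)| / |Area(signal)|, with areas computed as
rectified area per unit time; a signed-area ratio on a structureless
kernel is scale-free with heavy tails and cannot be calibrated, whereas
the rectified form concentrates near 0 for null kernels and near 1 for
clean ones. The trial signal-to-noise index is the variance over time of
the trial mean divided by the mean over trials of each trial's variance
(population variances): 1 for identical trials, about 1/R for noise.
Layer filters use the standard defaults (flash Qi > 0.25 with
hyperpolarizing center/full-field; kernel Qi > 0.6 for either color;
GCL grouping chirp Qi > 0.4 or bar Qi > 0.6; antagonistic surround area
above a tenth of the center magnitude; fields with under 50% of cells
passing are dropped), all exposed in a single config with an audit log of
every exclusion.

**Opponency.** Full-field opponency is the minimum over onset and offset
of the Pearson correlation between the UV and green stimulus-triggered
event kernels (each phase requiring event Qi > 0.25); a cell is
color-opponent when either correlation is below -0.3.

**Population statistics.** Density recovery profiles bin pairwise
distances at 2 µm and normalize by annulus area; annuli of points near
the field edge are truncated, so quantitative flatness checks should
restrict the reference points to the field interior (the `reference`
argument). Field entropy is the
Shannon entropy of SC values binned at 0.2 (edges anchored at 0); the bin
occupancies enter as proportions — raw counts would not define an entropy
— so a single occupied bin gives 0 and a uniform spread over k bins gives
log2(k). Direction selectivity takes the tuning curve from the first
right-singular vector of the time x direction response matrix
(sign-oriented along the mean response), computes the vector sum over the
eight directions, and assesses significance by shuffling direction labels
across single trials 1000 times; the normalized index (vector length /
total tuning magnitude, in [0, 1]) is reported alongside the raw length
used for the permutation. Functional group assignment uses the
quality-weighted match index Mi = Qi_c/(Qi_c+Qi_b) r_chirp +
Qi_b/(Qi_c+Qi_b) r_bar after the 40-ms shift and 5-point boxcar smoothing
of the chirp trace, restricted to the class-compatible templates
(direction-selective, alpha by soma area > 170 µm², or neither), with
assignment at Mi > 0.5.

**Group-level opponency test.** To ask whether a functional group has more
or fewer opponent cells than its chromatic preference predicts, each group
cell is replaced (10,000 times) by a random different cell from the same
SC_Diff bin (width 0.25, edges at 0) with a center SC within ±0.1, and the
observed percent opponent is ranked within the surrogate distribution.
Both the raw percentile (mid-ranked) and a two-sided
p = 2 min(percentile, 1 - percentile) are reported, since both enrichment
and depletion are of interest. Groups need more than 15 cells; cells with
no eligible partner are excluded from both the observed and surrogate sets
and counted. Same-group partners are allowed in the matching pool, which
keeps the null exchangeable.

## Numerical and degenerate-input choices

* Event detection on resampled traces: linear interpolation produces
  derivative plateaus; runs of equal derivative are collapsed and an event
  is placed at the earliest sample of a locally maximal run.
* Zero-variance pixels contribute correlation 0; zero-variance kernels get
  area 0 with an undefined polarity flag; a zero signal area makes the
  quality index -Inf so it fails every threshold.
* Empty event sets produce an explicitly flagged empty kernel; consumers
  return NA records rather than erroring.
* The Otsu threshold is clamped to [0.1, 0.9] so degenerate histograms
  cannot select a vacuous threshold.
* All simulation entry points take integer seeds and fan out per-cell
  child seeds, so runs are bit-reproducible and stages independently
  re-runnable.

## What the tests do and do not establish

The test suite verifies every statistic against closed forms or
independent oracles (a naive per-event loop for the kernels, Monte-Carlo
nulls for the quality and permutation machinery) and checks parameter
recovery end-to-end on populations pinned to the reported layer means:
with 500 synthetic ventral bipolar ROIs (180 s of 10 Hz flicker, SNR 5)
the kernel pipeline recovers the mean center SC within 0.05; with 500
synthetic cones (25-repeat flash protocol, SNR 5) the flash pipeline
recovers the ventral surround and dorsal center means within 0.1. Problem
sizes in the routine suite are smaller (tens of cells, 30–60 s stimuli,
64 x 64 px fields), chosen as the smallest instances at which the
statistical properties under test are unambiguous.

Two recovery limits are worth knowing. Event selection interacts with the
specific balanced binary sequence, leaving a per-cell wobble of up to
about 0.1 SC units that does not average out with longer stimulation;
population means are unbiased to well within the tolerances above.
Second, kernel-based SC is only identified up to the polarity anchor: for
a center-opponent cell whose antagonistic color dominates, flicker data
alone cannot distinguish the cell from its polarity mirror image.

## Known limitations

* The generator's iid noise and trial structure omit bleaching, motion,
  and correlated background; inter-trial variability is iid by assumption.
* Chirp and moving-bar templates are piecewise-analytic stand-ins; only
  relative correlations matter for the assignment machinery, and the
  packaged template library is synthetic.
* Downstream mixed-effects and additive-model analyses are out of scope;
  the pipeline exports the tidy per-ROI record table such models consume.
* Movies and results serialize as plain CSV/JSON; no HDF5 container is
  used.
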