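# retinachrome

Analysis of chromatic (UV vs. green) processing in two-photon functional
recordings of the mouse retina — from scan-field movies to per-cell
spectral-contrast and color-opponency statistics and group-level
permutation tests — together with a synthetic-data generator that emulates
cone, bipolar-cell and ganglion-cell-layer recordings so the entire chain
is testable without recorded data.

It is written for retinal physiologists analyzing glutamate or calcium
imaging of chromatic stimuli, and for methodologists who need a
ground-truth benchmark for correlation-based ROI detection or
event-triggered receptive-field estimation.

## What it computes

For each functional release unit (ROI) the pipeline estimates response
areas `F_Area` for the four conditions UV/green x center/surround (from
flash trial medians, or from event-triggered stimulus kernels
`F(τ) = (1/M) Σᵢ c(tᵢ) S(tᵢ + τ)` estimated from balanced binary flicker)
and summarizes chromatic preference as spectral contrast:

* same polarity: `SC = (|F_g| − |F_uv|) / (|F_g| + |F_uv|)` ∈ [−1, 1]
  (−1 pure UV, +1 pure green);
* antagonistic UV: `SC = 1 + |F_uv|/|F_g|` (> 1);
* antagonistic green: `SC = 1 − |F_g|/|F_uv|` (< 1);

plus `SC_Diff = SC_surround − SC_center`, full-field opponency
`min(ρ_onset, ρ_offset)` of the UV-green event-kernel correlations (a cell
is color-opponent when either ρ < −0.3), quality indices
(`Qi = 1 − |Area_baseline|/|Area_signal|`; trial SNR
`Var_t[mean_r C] / mean_r[Var_t C]`), robust event thresholds
`σ = median(|r|)/0.6745`, density recovery profiles, field entropy
`−Σ pᵢ log₂ pᵢ` of binned SC values, SVD-based direction selectivity with
a 1000-shuffle permutation test, match-index group assignment, and a
stratified 10,000-iteration permutation test for group-level opponency
enrichment.

## Worked example

Generate a ventral bipolar-cell population, simulate its responses to the
10 Hz balanced center-surround flicker at SNR 5, and recover chromatic
records through event detection, kernel estimation and spectral contrast:

```r
library(retinachrome)

cells    <- make_population(40, "IPL", dorsoventral_range_mm = c(-2, -0.5), seed = 1)
protocol <- make_flicker_protocol(rate_hz = 10, duration_s = 180, seed = 2)
records  <- recover_flicker_sc(cells, protocol, snr = 5, seed = 3, acq_rate_hz = 11.16)

mean(cells$sc_center_truth)                 # -0.413  ground-truth mean center SC
mean(records$sc_center, na.rm = TRUE)       # -0.440  pipeline-recovered mean
mean(records$sc_surround, na.rm = TRUE)     #  0.276  green-shifted surround

qc <- apply_layer_filters(transform(records, roi_id = cell_id), "IPL")
nrow(qc$records)                            # 33 of 40 pass kernel Qi > 0.6

field_entropy(records$sc_center[is.finite(records$sc_center)])  # 2.239 bits
```

The recovered population mean (−0.44) matches the generator's
ground-truth mean (−0.41) to within the per-cell recovery noise; the
surround mean near +0.28 reflects the green-shifted antagonistic surround
of ventral cells, the source of their color-opponency. The field entropy
(~2.2 bits) says the SC values spread over roughly five 0.2-wide bins.

`head(records)` shows one row per ROI with `sc_center`, `sc_surround`,
`sc_diff`, the SC case identifiers, signed areas and kernel quality
indices — the tidy table a downstream mixed-model analysis would consume
(`write_records_csv()`).

`run_pipeline(default_config("IPL"))` wires the same stages end-to-end
from a single config (seeds fan out per stage; reruns are bit-identical),
and `simulate_scan_field()` + `correlation_image()` + `segment_rois()`
cover the movie-level path.

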