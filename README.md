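# mirrorkit

An R toolkit for building and testing **virtual-mirror experiments** in
enfacement research — studies in which a screen avatar imitates the
participant's head pose and facial expressions in real time to induce a
sense of agency (SoA) over the avatar's face. The package implements the
computational core of such a system so that every experimental manipulation
and every analysis step can be developed, calibrated and regression-tested
on a desk, with no camera, markerless tracker or 3D renderer attached:

* a **feed-forward message-passing pipeline** with text-file pipeline
  specifications, per-module monotonic-clock timing, and latest-wins or
  queue-all back-pressure handling;
* a **synthetic face source**: motion scripts (piecewise hold/linear
  segments) sampled into timestamped streams of 6-DoF head pose and 17
  FACS action-unit (AU) intensities with optional Gaussian tracking jitter;
* the **condition manipulators** of a typical validation design — delay
  buffering for asynchrony, expression amplification (AU scaling with a
  [0, 5] clamp), pose/expression gating for conditions B / P / E / PE, and
  continuous replay of a prerecorded rest sequence for the baseline;
* a deterministic **schematic avatar renderer** (pure function of avatar,
  state and size) with four registered identities and a pluggable contract
  for external photoreal renderers;
* **end-to-end latency calibration**: the periodic calibration stimulus
  (frontal 1.5 s, then an abrupt 25° left turn held 0.5 s), yaw-track
  standardization and smoothing, and frame-shift estimation by maximizing
  the Pearson correlation of N sampled 3-s sub-sequences over all integer
  lags within one stimulus period, converted to milliseconds as
  `shift × 1000 / fps`;
* an **experiment session API** (background mirror, non-blocking image
  retrieval, live adjustment of delay/condition/avatar/amplification) and a
  **counterbalanced induction-schedule builder** (baseline first, the six
  orders of P/E/PE balanced across participants, 30/180/30-s phases,
  distinct avatars per participant);
* **weighted SoA scoring**: unidimensional PCA loadings of the item
  correlation matrix, weighted sum scores `Σⱼ λⱼ·responseⱼ` on raw 0–100
  visual-analogue ratings, and measurement-invariance checks via the Tucker
  congruence coefficient `φ(x, y) = Σxᵢyᵢ / √(Σxᵢ²·Σyᵢ²)` between
  condition-general and condition-specific loadings, plus a seeded
  one-factor response generator for parameter-recovery testing.

## Worked example

```r
library(mirrorkit)

# a virtual-mirror pipeline with a 200 ms artificial delay, defined as text
spec <- parse_pipeline_spec(
  "synth_source script=calibration fps=120
   delay delay_ms=200
   render width=64 height=64
   sink")

# calibrate its end-to-end latency with the periodic head-turn stimulus
report <- calibrate_end_to_end(spec, duration_s = 30, fps = 120,
                               n_sub = 50, seed = 1)
report
#> <latency_report>
#>   end-to-end: 200.00 ms (SD 0.00 ms) from 50 sub-sequences at 120 fps
#>   pipeline processing: mean 0.00 ms (SD 0.00 ms)
#>   note: software delay only: camera exposure and display response are not simulated
```

The estimate recovers the injected 200 ms delay exactly: the 120-fps
recorder resolves latency in 8.33-ms frame steps, and averaging 50
sub-sequence frame shifts of a noiseless simulated recording leaves no
residual spread. On real recordings the same estimator is applied to two
OpenFace-style yaw tracks read from CSV.

Scoring synthetic questionnaire data:

```r
rm <- synth_responses(n = 24, seed = 3)      # participants x items x conditions
loadings <- pca_loadings(rm)                 # condition-general PCA loadings
invariance_check(rm)
#>   condition       phi
#> 1         B 0.9946933
#> 2         P 0.9971732
#> 3         E 0.9954402
#> 4        PE 0.9938537
round(colMeans(weighted_sum_score(rm, loadings)), 2)
#>      B      P      E     PE
#> 118.63 168.14 224.03 238.85
```

All four per-condition congruence coefficients are near 1, so the
condition-general loadings are usable for the weighted sum score; the mean
scores reproduce the baseline-lowest ordering that the generator encodes.

A thin command-line front end ships in `inst/cli/mirrorkit.R`
(`run`, `calibrate`, `score` subcommands over the same functions).

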