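---
title: "Virtual-mirror methods: pipeline, latency calibration, and SoA scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-mirror methods: pipeline, latency calibration, and SoA scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirrorkit)
```

## The problem

A virtual mirror shows a participant an avatar that imitates their head
pose and facial expressions in real time. Two properties of such a system
decide whether it can induce a sense of agency (SoA) over the avatar's
face: *temporal congruence* — the end-to-end latency between a facial
movement and the avatar's imitation must stay below the critical 200–300 ms
range — and *semantic congruence* — the avatar must move like a face.
mirrorkit implements the computational machinery of such a system in a form
that runs entirely on synthetic data, so that the manipulations and the
analysis can be verified without a camera, tracker, or 3D renderer.

## Pipeline model

Messages (frame id, capture timestamp, optional image, flat key-value map
with `pose.*`, `au.*`, `camera.*`, `timing.*`, `avatar.*` keys) flow from a
source through transform modules to a sink. The contract is behavioural:
modules may overlap in time on different messages, messages leave every
module in arrival order, and `emitted = delivered + dropped` holds for
every run. The engine realises this contract as a deterministic
discrete-event simulation: each module has a simulated processing duration
(`proc_ms`, default 0), a message starts at a module as soon as it has
arrived and the module is free, and when a module cannot keep up the
pending slot on its input edge either queues everything (`queue`) or keeps
only the freshest message (`latest`, the default — a mirror should show the
newest frame). Real threads would add nondeterminism without changing any
observable property the package promises, so they are deliberately not
used; all timing rides on an injected monotonic millisecond clock, which in
tests is a simulated clock.

Timing instrumentation writes one `timing.<module>_ms` entry per module
into each message; these entries, once written, are never mutated
downstream. `module_timing()` summarises them as per-module mean/SD plus
the pipeline total per delivered message.

## Face state and synthetic motion

A face state is a 6-DoF head pose (translations in mm; intrinsic
pitch–yaw–roll Euler angles in degrees, positive yaw = subject's left
turn) plus 17 AU intensities on the conventional [0, 5] scale, with a
validity flag and tracker confidence. Every expression produced anywhere in
the package is clamped to [0, 5] per AU. The AU set is the standard
intensity set of a markerless tracker (AU01–AU45); translation units and
the Euler convention are fixed here by convention since trackers differ.

Motion scripts generate deterministic synthetic streams. The calibration
stimulus holds a frontal pose for 1.5 s and then switches — abruptly,
between consecutive frames, with no interpolation ramp — to yaw +25° held
for 0.5 s, looped (period 2 s). The rest script approximates breathing with
a piecewise-linear sinusoid (24 segments per cycle) modulating `tz` with
peak amplitude `breathing_amplitude` (default 0.5 mm, period 4 s) and AU25
with the non-negative offset form `a/2·(1+sin)`; yaw stays exactly zero.
`sample_states()` samples any script at a fixed frame rate, with optional
independent Gaussian jitter per channel (seeded, deterministic), standing
in for tracker noise.

What the synthetic streams do **not** emulate: tracker dropouts and
latency-dependent jitter, correlated pose/AU noise, illumination effects,
and the idiosyncratic AU cross-talk of real trackers. Tests passing on this
generator therefore validate the *pipeline and estimators*, not any
specific tracker's behaviour.

## Manipulators

* **Delay** (`delay delay_ms=2000`): timestamp-based nearest-older lookup —
  the emitted state is the newest buffered state captured at or before
  `now − d`. No interpolation, so outputs are exactly past inputs; the
  emitted age is ≥ d always and ≤ d + one frame interval in steady state.
  Before the buffer is old enough, a *flagged neutral state* is emitted
  (what the avatar should show while the delay line fills is a design
  choice; neutral avoids showing stale or future motion). A state captured
  exactly `d` ago counts as old enough; the comparison carries 1 ns of
  slack so frame-grid boundaries do not flip on floating-point error. The
  default asynchronous delay is 2000 ms ("in the order of seconds"),
  configurable.
* **AU scaling** (`au_scale factor=1.5`): multiplies all intensities and
  clamps to [0, 5]; scale-then-clamp keeps the AU range invariant while
  remaining multiplicative below the clamp.
* **Condition gate** (`gate mode=P|E|PE|B`): P passes pose and zeroes
  expression; E passes expression and pins pose to the rest pose; PE is the
  identity; B ignores the live input entirely and substitutes the replayed
  rest recording, decoupling avatar from participant.
* **Replay** (`replay file=rest.csv loop=true`): emits the recorded state
  with the greatest capture time ≤ t (mod duration when looping).

Invalid tracker states pass through all manipulators unchanged and
flagged.

## Renderer

The schematic renderer is a pure function of (avatar, state, size): a head
ellipse placed by an affine mapping of pose (yaw/pitch as horizontal and
vertical shifts, roll as in-plane rotation, `tz` as scale — no 3D
projection), with brows driven by AU01/02/04, eyes by AU05/07/45 and the
mouth by AU10/12/15/20/23/25/26, each deformation monotone in intensity.
Flat shading on a fixed background keeps renders byte-identical across
calls. Invalid states render as the neutral face with a red border. This
is sufficient for every pipeline and calibration test; photoreal rendering
plugs in through the callable contract `(state, avatar_id, size) → raster`.

## Latency calibration

The end-to-end procedure simulates the video-based measurement: the
stimulus and the pipeline's output are both "recorded" at `fps` (default
120), yielding two yaw tracks. Both are z-transformed and smoothed with a
centered moving average (default width 5 frames; partial windows at the
edges), then `n_sub = 50` sub-sequences of 1.5 stimulus periods (3 s) are
sampled uniformly without replacement over admissible starts, and for each
the integer lag in `[0, period·fps)` maximizing the Pearson correlation is
taken; ties break to the smallest lag. Periodicity means shifts are only
identifiable modulo one period (240 frames at 120 fps) — sufficient in
practice, since latencies beyond 2 s are not plausible measurement targets.
The mean shift converts to milliseconds as `shift × 1000 / fps`.

Numerical choices worth knowing: the recorder's tick times use the same
floating-point arithmetic as the source's emission times, so simultaneous
events compare equal; and the whole harness measures **software delay
only** — the camera-exposure and display-response shares of a physical
setup are outside the simulation, and the latency report labels itself
accordingly. Detrending before correlation was considered and not applied:
the standardized periodic stimulus has no trend by construction, and the
option would only matter for real recordings with tracker drift (the
smoothing window is config-exposed for that case).

Problem sizes in the test suite and acceptance script — 30-s tracks at
120 fps, 50 sub-sequences, 100 noise replicates, exhaustive shifts over
three periods — were chosen to exercise every code path at the same scale
as a realistic desk calibration.

## Sessions and schedules

A `mirror_session` wraps the manipulation chain behind the interface a
stimulus-presentation host needs: non-blocking retrieval of the newest
rendered frame (`NULL` before the first; identical frame between updates),
and live setters for delay, condition, avatar and amplification that take
effect on the next frame. An event log records every change with monotonic
timestamps.

`build_schedule()` emits the validation design: baseline B always first,
then P/E/PE in one of the six orders, each order used `n/6` times (exact
for multiples of 6; otherwise balanced to within one, with a warning — full
permutation balancing was chosen over a Latin square because three free
blocks make it feasible at typical sample sizes). Phases are 30 s
instruction, 180 s mirror, 30 s free (240 s per block); each participant
gets three distinct randomly assigned avatars for the synchronous blocks,
with the baseline avatar drawn freely from the pool. Breaks (5 min) are
metadata only.

## SoA scoring

Item responses (visual-analogue 0–100) are scored as a weighted sum,
`scoreᵢ𝚌 = Σⱼ λⱼ·responseᵢⱼ𝚌`, with loadings λ from a unidimensional PCA:
the leading eigenvector of the **item correlation matrix** scaled by the
square root of its eigenvalue (items share a scale but may differ in
variance, hence correlation rather than covariance), sign-fixed so the
loadings sum positive. The weighted sum is applied to raw responses, not
standardized ones. Measurement invariance across conditions is checked with
the Tucker congruence coefficient between condition-general loadings
(PCA on the data points of all conditions pooled) and each
condition-specific loading vector; the check is report-only by default,
with the conventional .85/.95 markers available as an optional benchmark.

The synthetic generator draws from a one-factor model,
`clamp(μ𝚌 + λⱼ·ηᵢ𝚌 + εᵢⱼ𝚌, 0, 100)` with η ~ N(0, 15) and ε ~ N(0, 10) in
VAS units by default — noise large enough to be realistic for single-item
VAS ratings while keeping the factor recoverable at n = 200. Default
condition means (B 35 < P 50 < E 58 < PE 65) encode the qualitative
baseline-lowest ordering such designs aim to detect; they are generator
parameters, not empirical claims. Pooling conditions inflates inter-item
correlations through between-condition mean differences, which slightly
homogenizes condition-general loadings — the same property the
condition-general PCA has on real data, and the reason the invariance check
exists.

## Known limitations

* Concurrency is simulated, not preemptive; real-thread scheduling jitter
  is outside the model.
* The schematic renderer's AU-to-geometry mapping is a stand-in with the
  right monotonicity properties, not a reproduction of any morphable-model
  mapping.
* The latency harness cannot observe hardware lag (camera, display); on
  real setups those shares must be measured with the two-camera video
  method the estimator is designed for, feeding recorded yaw tracks in as
  CSV.
* Shift estimates are quantized to the recorder's frame interval and
  identified only modulo the stimulus period.
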