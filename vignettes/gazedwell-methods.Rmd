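---
title: "Methods: ratio-based webcam gaze estimation and dwell selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratio-based webcam gaze estimation and dwell selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazedwell)
```

## The model

Webcam gaze interfaces cannot rely on the sub-degree accuracy of infrared
eye trackers. The approach implemented here sidesteps point-of-regard
estimation entirely: each frame is reduced to a pair of *pupil-position
ratios* — where the pupil center sits within the eye opening, horizontally
between the two eye corners and vertically between the eyelids — and the
interface is designed so that five coarse gaze zones suffice.

The per-frame pipeline is:

1. **Eye regions.** The 68-point facial landmark scheme places six points
   around each eye (36–41 and 42–47). `extract_eye_regions()` crops each
   eye's bounding box and records the reference coordinates: the corner
   x positions, and the eyelid y references taken as the mean y of the two
   upper-lid and the two lower-lid points.
2. **Iris segmentation.** Within a crop the iris is the dark region against
   the light sclera, with a sharp limbus boundary. `segment_iris()` runs a
   bilateral filter (edge-preserving smoothing), a grayscale erosion (min
   filter, consolidating and slightly growing the dark region), and a
   binary threshold. Foreground always means iris, regardless of display
   polarity.
3. **Pupil center.** The centroid of the mask by image moments
   (`pupil_center()`), real-valued, in full-frame coordinates.
4. **Ratios.** `raw_horizontal_ratio()` maps the pupil x linearly onto
   [0, 1] between the corners; the vertical analogue uses the eyelid
   references. Raw ratios are then re-normalized (`renormalize()`) against
   pilot extremes — 0.28/0.87 horizontally, 0.48/0.95 vertically — because
   the pupil cannot physically reach the landmark positions, and averaged
   across the two eyes (`combine_eyes()`). The printed convention is
   mirror-imaged: `h` near 1 means the user looks left; `v` near 1, down.
   The asymmetric vertical band (0.48–0.95) reflects upper-lid occlusion
   when looking up; the package takes the constants as configuration and
   does not model the asymmetry further.
5. **Calibration and zones.** A 2-s fixation on a screen-center point gives
   the user's center ratio `(h_c, v_c)` (`run_one_point_calibration()`).
   `classify_zone()` maps a ratio pair to one of
   {center, left, right, up, down} via a closed central rectangle of width
   `w` and height `l` around the center.
6. **Selection.** A dwell-based two-stage machine (`selection_step()`,
   `run_stream()`): four clusters of three items in the four directions;
   dwelling past the threshold confirms; the chosen cluster expands with
   its middle item moved down and a back control on top; 10 s without a
   confirm within a stage resets the interface as a missed selection.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `h_min`,`h_max` | 0.28, 0.87 | raw ratio | pilot extremes, rightmost/leftmost gaze |
| `v_min`,`v_max` | 0.48, 0.95 | raw ratio | pilot extremes, top/bottom gaze |
| `w`, `l` | 0.4, 0.2 | ratio | central dead zone; the study varied it over 0.16×0.09 / 0.2×0.12 / 0.24×0.16 |
| dwell threshold | 0.5–1.2 | s | per-condition in the study; any positive value accepted |
| stage timeout | 10 | s | restarts per stage, on every confirm |
| `grace_period` | 0 | s | blink tolerance during a dwell; 0 = any gap resets |
| bilateral diameter / sigmas | 10 / 15 / 15 | px / levels / px | no canonical values exist for webcam eye crops; chosen for crops tens of pixels across |
| erosion | 3×3, 3 iterations | px | grows the dark region by ~3 px; centroids are unbiased because growth is isotropic for a fully visible disc |
| threshold | `"auto"` | levels | midpoint of the 5th/95th intensity percentiles, which makes segmentation invariant to gray-level shifts |

The study's central-area factor is interpreted as the classification dead
zone (its stated motivation is the error rate, which only the dead zone
influences in this pipeline); the alternative reading — that it only scales
the on-screen item layout — would make the factor inert here. This choice
is deliberate and flagged rather than settled.

## Numerical and semantic choices

* **Coordinates** are 0-based, origin top-left, x rightward, y downward;
  centroids are never rounded.
* **Clamping to [0, 1]** happens at every normalization stage. Behavior
  outside the pilot bounds is otherwise undefined, and clamping keeps the
  zone geometry total.
* **Closed boundary, with float guard.** Points exactly on the rectangle
  edge are "center" (conservative against accidental triggers); a 1e-9
  epsilon keeps that rule stable under floating-point representation error.
* **Outside the rectangle** the label is the axis with the larger
  *normalized excess* — overshoot beyond the rectangle divided by the
  rectangle's half-extent on that axis — which is scale-free for the
  asymmetric rectangle; ties (within 1e-9) go to the horizontal axis.
* **Eq. for combining eyes.** The final ratio is the arithmetic mean of the
  two eyes; if one eye yields no pupil (blink, segmentation failure) the
  other is used alone, so single-eye occlusion degrades gracefully instead
  of dropping frames.
* **Calibration robustness.** Within the 2-s window, invalid samples are
  dropped and samples beyond 2.5 MAD from the per-axis median rejected
  before averaging; a constant stream is its own fixed point. Fewer than 10
  usable samples raise a `calibration_failed` condition. The window check
  counts each sample's coverage interval, so 60 samples at 30 Hz satisfy a
  2-s window.
* **Dwell accumulation is contiguous**: any excursion to another zone
  resets the timer (the strictest reading of "continuously focuses"). A
  configurable `grace_period` (default 0) lets short blink gaps pass
  without resetting; blink time is accumulated per gap, so the tolerance is
  sample-rate agnostic.
* **Timeout ordering.** A confirm occurring at the same event as a timeout
  wins; the timeout fires only when no confirm happened, and the stage
  clock restarts on every confirm.

## The synthetic generators

`eye_image_spec()`/`generate_eye_image()` draw a schematic eye: two
quadratic eyelid arcs through the corners, light sclera between them, a
dark filled iris disc, optional Gaussian pixel noise. This exercises
exactly the properties the pipeline consumes — the six-landmark geometry
and the dark/light contrast — and nothing else. It does not emulate
specular glints, eyelashes, makeup, eyeglass reflections, skin texture,
head pose, or color; a passing recovery test therefore shows correctness of
the segmentation-to-centroid chain, not robustness to real webcam imagery.

`gaze_scenario()`/`generate_gaze_stream()` simulate a user driving the
interface. Noise has three components, each with an independent seed
substream (so adding one source never perturbs another's draws):

* per-sample Gaussian **jitter** (`jitter_sd`, default 0.03 ratio units) —
  frame-to-frame estimator noise;
* an AR(1) fixation **drift** (`drift_sd` 0.08, `drift_tau` 0.3 s) — the
  autocorrelated wander of fixational eye position as seen through a
  webcam estimator. Autocorrelation matters: purely independent per-sample
  noise at 30 Hz essentially never produces the sustained wrong-zone
  excursions that break or misdirect a dwell, so an iid-only model makes
  the interface implausibly perfect at every threshold;
* **blink dropouts**: samples kept but flagged invalid, onsets from a
  Poisson process thinned to forbid overlap, 17/min (the resting human
  rate), 0.15 s each.

Closed-loop trials (`run_trial()`) add a behavioral element: after every
confirm the simulated user keeps gazing at the just-confirmed arrow for a
Gamma-distributed reaction latency (mean 0.3 s, sd 0.1 s) before
re-orienting. An occasional slow reaction past a short dwell threshold
confirms the arrow the user is still looking at — the classic Midas-touch
mechanism, and the model's source of false selections at 0.5 s. Drift that
keeps breaking long dwells within the 10-s stage budget is the source of
missed selections at 1.2 s. Viewing distance scales both noise sds by
`distance / 45` (farther faces are smaller on the sensor), an explicit
modeling assumption. These defaults are stand-ins chosen for behavioral
plausibility, not quantities calibrated to any human dataset; simulated
rates characterize the interface logic under this model, and human means
and SDs are deliberately not reproduction targets.

Setting `jitter_sd = 0, drift_sd = 0, blink_rate = 0, latency_sd = 0`
recovers a deterministic user, which underpins the closed-loop oracle: every
generated scenario must select exactly its target sequence.

## Problem sizes

The shipped checks use: 1000 random masks for the centroid/brute-force
equivalence; 100 noise-free synthetic eyes for iris recovery (tolerance
1.5 px; observed maximum ≈ 0.4 px); a 101×101 ratio grid for the zone
partition at all four rectangle sizes; 48 zero-noise closed-loop scenarios
(12 items × 4 thresholds); and 500 simulated trials per dwell threshold at
the medium area / 55 cm cell for the error-structure trends (the middle
distance exercises both error mechanisms). The acceptance script uses 250
trials per threshold.

## Known limitations

* No head-pose compensation; the ratios assume a roughly frontal,
  stationary face. No glint-based refinement, no eyeglass-reflection
  handling.
* The landmark detector itself is out of scope: tests and fixtures supply
  landmarks directly (`face_landmarks()`, JSON). The conventional naming
  is kept: "left eye" = points 36–41, which is the *image-left* eye, i.e.
  the subject's right — inherited from the annotation scheme.
* The displayed-size arithmetic (`pixels_per_degree()`) implements standard
  geometry only. The per-condition visual angles sometimes quoted for this
  class of setup are not always mutually consistent with a single
  pixels-per-degree figure; angles play no computational role in the
  pipeline and no reconciliation is attempted.
* Simulated error rates and completion times depend on the user model
  above; they reproduce qualitative structure (false ↓, missed ↑, time ↑
  with dwell threshold; error → 0 as noise → 0), not human magnitudes.
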