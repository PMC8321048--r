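---
title: "Silhouette-based fall detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Silhouette-based fall detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(fallhmm)
```

## The problem and the pipeline

`fallhmm` labels every frame of a fixed-camera indoor video as *abnormal*
(S1, the person is falling) or *normal* (S2, everything else: walking,
standing, sitting, lying, and the transitions between them).  The intended
user is a researcher prototyping vision-based monitoring for people living
alone, where a fall that goes unnoticed is the main risk.  The pipeline has
four stages, each exposed as ordinary functions:

1. **Silhouette detection** (`update_background()`, `refine_mask()`,
   `segment_sequence()`): a per-pixel mixture-of-Gaussians background
   model flags moving pixels; a graph cut over the 4-connected pixel
   lattice cleans the raw mask; the largest 8-connected component is kept
   (the method assumes a single monitored person).
2. **Feature extraction** (`frame_features()`,
   `extract_feature_series()`): each silhouette is summarised by its
   centroid, its *virtual grounding point* (VGP) — the point on the
   vertical line through the centroid at the bottom of the bounding box —
   and three scalars: the point distance `d = |y_vgp - y_c|`, the area
   `a` (foreground pixel count) and the aspect ratio `r = w/h`.  Standing
   gives large `d` and `r < 1`; lying gives small `d` and `r > 1`.
3. **Temporal analysis** (`moving_average()`, `modified_difference()`,
   `half_width()`, `learn_period_thresholds()`, `analyze_video()`): each
   feature series is smoothed by a centered moving average
   `MA(t) = mean(F[t-N .. t+N])` and differentiated by the *modified
   difference* `MD(t) = MA(t + N0 + N1) - MA(t - N0 - N1)`, a smoothed
   symmetric derivative.  A fall is an abrupt posture change, so it
   produces a dominant MD extremum — a minimum for `d`, a maximum for
   `r`, and either polarity for `a` depending on the fall direction
   (a forward fall spreads the silhouette, a sideways or backward fall
   foreshortens it), which is why both polarities are evaluated for `a`
   and the larger magnitude kept.  The full width at half maximum of the
   extremum, `v_hw = |f1 - f2|`, estimates the event period; per-feature
   thresholds `PD(F) = (alpha1(F) + alpha2(F))/2` — the midpoint between
   the smallest fall-video width (`alpha1`) and the largest normal-video
   width (`alpha2`) in a labelled training set — classify a video as
   containing a fall (`l1`, `v_hw >= PD`) or not (`l2`).
4. **Frame-level decision** (`symbolize()`, `fall_hmm()`,
   `predict.fall_hmm()`, `evaluate_states()`): each frame gets one of
   eight observation symbols from the three binary flags "is this frame
   inside feature F's detected interval with `v_hw >= PD(F)`", ordered as
   `o = 1 + 4(1-flag_d) + 2(1-flag_a) + (1-flag_r)`.  A two-state
   discrete-emission hidden Markov model `lambda = (A, B, pi)` is fitted
   by supervised counting (no EM) and decoded with the Viterbi algorithm
   in log space.

## Tunable parameters

All constants live in `fall_config()`; none are hard-coded.

| parameter | default | units | role |
|---|---|---|---|
| `fps` | 25 | frames/s | frame rate of the input video |
| `ma_window_half` (N) | 51 | frames | moving-average half-window, about 2 s per side at 25 fps |
| `md_offset0` (N0), `md_offset1` (N1) | 0, 51 | frames | modified-difference offsets; N1 is also the smoothing half-window |
| `reseed_interval` | 100 | frames | graph-cut seeds/appearance refreshed from the raw mask |
| `initial_probs` (pi) | (0.8, 0.2) | — | initial state probabilities of (S1, S2) |
| `interpolation_max_gap` | 12 | frames | longest empty-mask gap bridged by linear interpolation (~0.5 s) |
| `pseudocount` | 0 | counts | additive emission smoothing; 0 keeps exact empirical zeros |
| `mog_components`, `mog_learning_rate`, `mog_match_sd`, `mog_background_fraction` | 3, 0.02, 2.5, 0.7 | — | background-model shape, adaptation speed, match gate, background mass |
| `gc_lambda`, `gc_seed_erosion`, `morph_radius` | 10, 1, 1 | — | contrast-term weight, seed-core erosion passes, morphological cleanup passes |

The smoothing constants (N = N1 = 51 at 25 fps) are the method's
operating point and scale with the frame rate.  The learning rate 0.02
makes the background absorb static scene changes in roughly one second
while keeping a person who pauses briefly in the foreground; larger
values make slowly moving people vanish into the background.

## Design choices where the method description is open

**VGP geometry.** Read literally, "the crossing of the vertical line
through `x_c` and the horizontal line through `y_c`" is the centroid
itself, which would force `d = 0` identically.  We take the grounding
point to be where the vertical centre line meets the *ground side* of the
object — `(x_c, bottom bounding-box row)` — which matches the name, makes
`d` large for an upright posture and small for a lying one, and gives the
`d` series the fall signature the temporal analysis relies on.

**Boundary handling.** Moving-average windows at the series ends are
truncated to the available frames and renormalised by the actual count
(no padding, no phantom ramps); modified-difference lookups outside the
series are clamped to the ends.  Half-level crossings are found by
walking outward from the extremum and interpolating linearly between
frames; a side that never crosses (monotone to the boundary) clamps to
the series end with a warning.  Ties between equal extrema go to the
earliest frame; Viterbi ties go to the lower state index (S1).

**Graph-cut seeding.** The stored raw mask is refreshed every
`reseed_interval` frames.  Spatial hard constraints (eroded seed cores)
are only valid on the frame the seeds were taken from; between refreshes
the seeds contribute through the foreground/background *appearance*
models (Gaussian intensity fits stored at reseed time), and the cut is
driven by appearance plus the contrast term.  Pinning stale cores would
anchor the label to where the person used to be.

**Accuracy metric.** The natural frame-level accuracy
`(As1 + Ns1) / (As1 + As2 + Ns1 + Ns2)` is used alongside precision,
recall, specificity and NPV; undefined ratios (empty classes) are
reported as `NaN` with a warning rather than silently patched.

**Symbol tree order.** The eight leaves are ordered so that a frame
inside all three detected fall intervals is `o1` and a frame inside none
is `o8`.  This ordering makes the worked emission matrix internally
consistent: abnormal-state mass sits at `o1` and `o3` (fall detected on
`d` and `r`, with or without `a`), normal-state mass at `o8`.

**Background model.** The silhouette stage uses the standard online
per-pixel mixture-of-Gaussians update (match within 2.5 sd adapts the
component; no match replaces the weakest; components ranked by
weight/sd form the background set).  Subspace-learning background
models exist but the conventional online mixture satisfies the same
contract — a frame-by-frame foreground with a slowly adapting
background — and is fully testable.

## The synthetic study

`generate_scene()` renders a single actor as a filled ellipse whose
bounding box morphs linearly between posture keyframes (upright
`h = 3w`, sitting intermediate, lying `w = 3h`), translating during
walking with a small gait oscillation, at 320 x 240 and 25 fps — the
conditions of the public simulated fall corpora this method targets.
Fall actions interpolate upright to horizontal within at most 1.5 s,
with direction-dependent area profiles; ground-truth S1 labels cover
exactly the fall-action frames.  `scene_script()` draws the study's
scripts: fall scenes walk about and fall once; normal scenes only walk
and stand.  Scenes last 50 s — long enough that the 2 s smoothing
windows have ample context on both sides of the event and that
frame-level scores are dominated by steady-state behaviour rather than
boundary effects.  `synthetic_study()` runs 10 fall and 10 normal
scenes, learns thresholds and the HMM on half, and evaluates on the
held-out half; emissions are fitted there with `pseudocount = 1` so a
held-out scene whose interval edges produce a symbol unseen in training
remains decodable.

What the generator deliberately does *not* emulate: occlusions,
illumination changes, shadows, multiple people, textured clothing, or
non-elliptical body articulation.  Passing the synthetic study therefore
shows that the statistics and decision machinery behave as designed on
clean silhouettes; it does not certify performance on real video, where
segmentation quality dominates.

## Known limitations

* **The half-width floor.** With N0 = 0 and N1 = 51, MD is the raw
  series convolved with a kernel of ~205-frame support, so the full
  width at half maximum of *any* abrupt transition is at least about
  102 frames (~4 s at 25 fps) — regardless of how short the fall is.
  Two consequences: (i) the detected interval `[f1, f2]` around a
  genuine fall spills over the surrounding normal frames, which caps
  frame-level precision and specificity (decoded abnormal runs are
  several times longer than the true fall); and (ii) `v_hw` separates
  *abrupt* posture changes from ambulatory motion, but a slow sit-down
  produces an even wider low-amplitude bump, so normal scenes containing
  slow full posture transitions can exceed a fall-trained threshold.
  The study's normal scripts are ambulatory for this reason, and the
  limitation is stated rather than patched: shrinking the windows would
  change the method's operating point.
* **Single event per video.** Threshold learning uses the single
  dominant extremum per feature; multiple falls in one video contribute
  only their largest.
* **Single person, daylight.** The largest-component rule and the
  appearance models assume one actor and stable lighting.

## Problem sizes used by the checks

The bundled checks run entirely on synthetic data: the 20-scene study at
320 x 240 / 25 fps / 50 s per scene; estimator recovery on a 10^4-frame
sampled chain; Viterbi against exhaustive enumeration on 100 random
models with sequences up to length 12; and segmentation checks at
reduced resolution (120 x 90, ~5 s) where the graph cut runs per frame.
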