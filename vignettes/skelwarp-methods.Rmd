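---
title: "Methods: joint-angle features and DTW for skeletal behavior recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint-angle features and DTW for skeletal behavior recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelwarp)
```

## The recognition problem

A depth sensor with body tracking emits, at 30 frames per second, the 3-D
camera-space positions (millimetres) of 32 named joints of one person.
Given a library of *standard* recordings — one template per behavior of
interest (punch, one-armed call for help, arms for help, trip forward,
trip backwards) — the task is to score how similar a freshly captured
*test* sequence is to each template and to raise a warning when the best
similarity exceeds a threshold (default 75%). Safe behaviors (standing,
squatting) carry no template; they are recognized implicitly when every
similarity stays below the threshold.

The method is deliberately simple and training-free: geometry plus
dynamic programming. Its three stages are feature extraction, per-frame
cost aggregation, and dynamic-time-warping (DTW) alignment.

## Bone feature vectors: four selection schemes

Fifteen joints carry single-letter codes (pelvis `O`, right
shoulder/elbow/wrist `A/B/C`, left shoulder/elbow/wrist `D/E/F`, right
and left hips `G/H`, knees `I/J`, ankles `K/L`, clavicles `P/Q`); a bone
feature vector is the difference of two joint positions and is named by
its code pair (`OA` = pelvis to right shoulder). Two families:

* **Adjacent joint method** — vectors connect anatomically neighbouring
  joints (`AB`, `BC`, ...). Short segments (clavicle–shoulder is
  ~150 mm) make these directions sensitive to millimetre-level tracking
  noise.
* **Pelvis divergence method** — every vector starts at the pelvis `O`
  and points at a selected joint. These vectors are long (several
  hundred mm), so the same positional noise perturbs their direction
  less, and a common anchor removes sensitivity to where individual
  intermediate joints sit on differently proportioned bodies.

Each family has an **overall** variant (one shared whole-body set: 8
adjacent pairs or 12 pelvis-anchored vectors) and a **local** variant
(an action-specific set covering only that action's high-frequency
joints, e.g. `OA, OB, OC` for the punch). `vector_set_for()` returns
these sets verbatim; their sizes `V` are 8 and 12 (overall) and 2–6
(local).

## Angle differences and aggregation

For standard frame $s_i$ and test frame $t_j$, each same-named vector
pair contributes the cosine-rule angle
$\theta = \arccos\!\big(u \cdot v / (|u||v|)\big) \in [0, 180]$ degrees.
The $V$ angles of a frame pair are reduced to one scalar cost by an
*aggregation attribute*: their **sum** (group A), **mean** (group B) or
**maximum** (group C). Crossing the three attributes with the four
schemes gives the 12 model ids `A1`…`C4` of `model_grid()`; `C4`
(local pelvis + maximum) is the default model.

Angle features are invariant to translating either skeleton and to
uniform scaling (body size cancels exactly), but **not** to rotation:
the method assumes the tester faces the sensor from a fixed position, as
in the original capture protocol. No orientation normalization is
applied; the test suite asserts the invariances and the rotation
sensitivity explicitly.

## DTW alignment and the similarity score

With cost matrix $C(s_i, t_j)$ the accumulated matrix follows

$$D(i,j) = \min\{D(i-1,j-1),\ D(i-1,j),\ D(i,j-1)\} + C(s_i,t_j),$$

with $D(1,1) = C(s_1,t_1)$. The terminal entry is the DTW value; the
optimal warping path $P$ (length $l$ = number of matched index pairs) is
recovered by backtracking. Similarity is

$$\mathrm{sim} = 1 - \frac{\mathrm{DTW}(S,T)}{\text{normalizer}},$$

reported as a percentage. Two normalizers are implemented:

* `bounded` (default): $180 \cdot V \cdot l$ for the sum attribute and
  $180 \cdot l$ for mean/max — the per-step theoretical maximum of the
  aggregated cost times the path length, so the score always spans
  $[0, 1]$.
* `paper_literal`: $180 \cdot V \cdot l$ for every attribute, clamped to
  $[0,1]$. Under mean/max the per-step cost cannot exceed 180, so this
  normalizer floors the score at $1 - 1/V$; published safe-behavior
  scores well below that floor indicate the bounded form is what a
  max-attribute system must compute, which is why `bounded` is the
  default. Both modes are exposed and logged in every result.

Numerical choices:

* the cosine argument is clamped to $[-1, 1]$, and values within
  $10^{-12}$ of $\pm 1$ snap to exactly $\pm 1$ so that a self-match
  yields an exactly zero cost and exactly 100% similarity;
* ties in the DP minimum break diagonal, then vertical, then horizontal
  — the shortest path among equal-cost alternatives, making output
  deterministic;
* $l$ counts cells on the path (so $180 \cdot V \cdot l$ is the exact
  worst case for the sum attribute);
* zero-length bone vectors (coincident joints, which real trackers do
  produce): `lenient` mode (default) substitutes 0° with a warning,
  `strict` mode raises an error; the norm threshold is $10^{-6}$ mm;
* no warping window is applied — alignment is unconstrained, matching
  the source method.

An exhaustive path-enumeration oracle (`dtw_brute_force`, guarded to
small matrices) is kept in the package itself; the test suite checks the
dynamic program against it on hundreds of random matrices.

## Decision logic

`recognize()` scores a test sequence against every template — under
local schemes each action uses its own vector set; mixed $V$ across
actions is legitimate because each similarity is normalized by its own
$V$ and $l$. The best action is the arg-max (ties broken by template
declaration order), and the warning is **red** iff the best similarity
*strictly* exceeds the threshold ("exceeds 75%" is read as a strict
inequality). `evaluate()` wraps this over a labelled cohort and reports
per-action mean similarity, a confusion matrix, and accuracy (an unsafe
test is correct when flagged red *and* attributed to its own action; a
safe test is correct when green).

## The synthetic data generator

No public recordings accompany the source experiments, so the package
carries a forward-kinematic generator (`generate_action`,
`generate_cohort`) as first-class, tested code. It emulates the stated
capture world: 300 frames at 30 f/s (10 s), a template subject whose
noise-free recordings form the library, and six test subjects performing
each action ten times (60 test sequences per action).

* **Body**: a rigid segment model (`body_model()`; upper arm 280 mm,
  forearm 250 mm, thigh 440 mm, shank 420 mm, ...) scaled per subject by
  a factor drawn uniformly from 0.85–1.15. Noise-free frames conserve
  segment lengths to machine precision (asserted in tests).
* **Scripts**: each action is a keyframed joint-angle trajectory —
  punch: guard stance with three jab cycles; one-armed call for help:
  the right arm overhead with a wide lateral wave; arms for help: both
  arms held overhead in a V with a small wave; trips: whole-body pitch
  to ±80–88° reached early (phase 0.12–0.38) and held; squat: 340 mm
  pelvis drop with knee flexion and a 5° lean; stand: static with
  postural sway. The fall timing/pitch and the squat lean were
  calibrated once, at design time, so that the generator realizes the
  stated behavior of the modelled system — safe behaviors score below
  the 75% threshold against every template while same-action similarity
  stays high — and were then frozen.
* **Variation**: per-subject style offsets (Gaussian, σ = 4° on arm
  elevation/azimuth, 2° on trunk pitch), per-repetition tempo jitter
  (uniform ±15%, absorbed — by design of DTW — up to the held-pose
  boundary effects), and i.i.d. Gaussian joint-position noise
  (σ = 10 mm, a plausible consumer-depth-tracking error). All randomness
  derives from one base seed; cohort regeneration is byte-identical.

What the generator does **not** emulate: biomechanically valid fall
dynamics or balance, tracker-specific structured noise (occlusion runs,
joint swaps, depth-dependent error), camera orientation changes,
multi-person scenes, or the real inter-subject variability of motion
*strategy*. A green synthetic test therefore establishes the pipeline's
correctness and the qualitative separation structure — not field
accuracy on human data; the published headline accuracies are measured
on recordings that were never released and are not reproduced here.

One consequence worth stating: because angle features are exactly
scale-invariant, uniform body-scale variation does not degrade the
adjacent-joint schemes in simulation the way real body-shape and offset
effects do. The simulated advantage of the pelvis divergence method
(C4 over C3) is therefore real but small (~1–2 similarity points,
driven by bone-vector length vs angular noise), whereas the published
human experiments report larger gaps.

## Parameters that matter

| parameter | default | units | where | why |
|---|---|---|---|---|
| `threshold` | 0.75 | fraction | `model_config` | published warning threshold |
| `agg` | `max` | — | `model_config` | best-performing attribute (group C) |
| `scheme` | `local_pelvis` | — | `model_config` | best-performing scheme (model 4) |
| `mode` | `bounded` | — | `model_config` | score spans [0,1] for every attribute |
| `fps` / frames | 30 / 300 | s⁻¹ / count | capture, generator | stated capture protocol |
| `noise_mm` | 10 | mm | generator | plausible tracking error |
| tempo jitter | ±15% | — | generator | execution-speed variation |
| scale range | 0.85–1.15 | — | generator | adult body-size spread |
| `eps` | 1e-6 | mm | features | zero-length vector guard |

## Known limitations

* No orientation normalization: a rotated subject scores low against
  every template (by design, but a deployment would need a fixed
  station or an alignment pre-step; a hook exists in the feature layer
  only as documented sensitivity, not as an implemented corrector).
* Unconstrained DTW with the path length $l$ in the denominator can
  inflate similarity slightly by dwelling in cheap regions; this is
  inherent to the published score and left as specified.
* The local schemes are defined only for the five unsafe actions;
  requesting a local set for a safe action is an error rather than a
  fallback.
* Missing-joint handling is interpolation-then-strict-failure; runs of
  missing data touching either end of a sequence are unrecoverable.
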