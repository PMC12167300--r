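---
title: "Planning artifact-avoiding C-arm tilts from ellipsoidal implant surrogates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning artifact-avoiding C-arm tilts from ellipsoidal implant surrogates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmaa)
```

## The problem

Metallic implants — pedicle screws above all — cause streaking and blooming
artifacts in intraoperative cone-beam CT (CBCT). The dominant driver for
screws is photon starvation: views in which an X-ray travels a long path
through metal contribute heavily biased line integrals to the
reconstruction. Because a mobile C-arm can acquire its circular orbit in a
*tilted* plane, there is a free parameter — the tilt $\delta$ — that can be
chosen so that no view of the orbit looks down the shaft of a screw.

`pmaa` implements a parametric planning pipeline for that choice:

1. **Localize.** Head and tip keypoints of each screw, observed in two
   calibrated scout views (anterior–posterior and lateral), are
   back-projected into rays and triangulated into 3D endpoints.
2. **Model.** Each screw becomes an ellipsoid $(\mu_m, \Sigma_m)$: centroid
   at the endpoint midpoint, major full axis equal to the head–tip
   distance, minor full axes 5 mm (a typical screw diameter).
3. **Score.** Every candidate pose $(\theta', \delta)$ receives the metric
   $q_{\mathrm{atten}}(\theta',\delta) = \max_{u,v,m}\, p(u,v,\mathcal{E}_m
   \mid \theta',\delta)$, the maximum path length of any detector ray
   through any single ellipsoid.
4. **Optimize.** The trajectory objective
   $Q_{\mathrm{atten}}(\delta) = \max_{\theta'} q_{\mathrm{atten}}(\theta',
   \delta)$ is the worst view of the orbit at tilt $\delta$; the selected
   tilt $\delta^*$ is the smallest tilt achieving 95% of the possible
   reduction from $\max_\delta Q$ to $\min_\delta Q$.

The analytic shortcut that makes this interactive: among all chords of an
ellipsoid parallel to a direction $d$, the longest passes through the
centroid and has length $2/\sqrt{d^\top \Sigma^{-1} d}$. Scoring a pose
therefore needs one chord evaluation per ellipsoid — along
$d = \mathrm{unit}(\mu - \mathrm{source})$ — and no rendered image. The
package keeps counters (`path_counters()`) that make this cost structure
observable: an analytic metric map costs exactly
$M \times |\theta'\text{-grid}| \times |\delta\text{-grid}|$ chord
evaluations regardless of detector resolution, while the per-pixel
reference scorer casts one ray per sampled detector position.

## Assumptions, and how good the centroid shortcut is

The analytic score is exact for parallel beams. Under cone-beam divergence
the maximizing ray need not pass through the centroid, so the analytic and
rendered scores differ by a term of order the angle subtended by the
implant at the source. Two consequences, both verified by the test suite:

* For scenes within ±60 mm of the isocenter at a 622 mm source–isocenter
  distance, the analytic score stays within 2% of the per-pixel rendered
  maximum (typically within 0.2%) for poses where all implants project
  inside the detector.
* The approach to the parallel-beam limit is *not* uniform from clinical
  distances: for a screw nearly aligned with a finite-distance ray the
  chord shrinks with misalignment amplified by the squared axis ratio
  $(a/b)^2 \approx 100$, so scores at the clinical geometry can sit tens of
  percent above their parallel-beam limit — this is real cone-beam physics,
  not error. Once distances are scaled 100×, a further 100× changes scores
  by well under 0.1%; the suite tests convergence in that regime.

Overlap between implants is deliberately ignored (per-object maximum, not
sum): screw shafts are thin and their major axes well separated, so
coincident projections add little to the worst path. The diagnostic
`q_atten_summed()` quantifies exactly what this assumption discards.

Field-of-view semantics differ by design between scorers: the analytic
scorer evaluates the centroid chord whether or not the centroid projects
onto the physical detector, while the rendered and voxel scorers are
detector-limited. All cross-method comparisons in the tests are therefore
restricted to in-field poses (`all_in_field()`).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `match_tolerance` | 5 | mm | gate on head-ray and tip-ray closest approach for cross-view matching |
| `minor_full_axis` | 5 | mm | minor ellipsoid axes; typical screw diameters are 4–7.5 mm |
| `fraction` | 0.95 | — | required share of the achievable $Q$ reduction; 1 recovers the pure min–max argmin |
| `sampling` | 1 | mm | detector sampling for rendered/voxel scoring |
| `voxel_size` | 1 | mm | voxelization of the baseline mask |
| `theta_range` | [−100, 100] | deg | candidate orbit arc (a 200° short scan) |
| `delta_range` | [−30, 30] | deg | candidate tilts |
| SID / SDD | 622 / 1164 | mm | conventional mobile-C-arm distances; fully configurable |

The 5 mm minor axis is read as a *full* axis (diameter), the only reading
consistent with representing 4–7.5 mm screw diameters; it is exposed as a
parameter rather than hard-coded, and `scene_to_ellipsoids(...,
minor_from_diameter = TRUE)` uses each synthetic screw's true diameter
instead.

The preference for the *smallest* $|\delta^*|$ meeting the threshold (ties
toward positive tilt) encodes the practical costs of large tilts — table
collision risk and degraded geometric calibration — as a deterministic
rule. A curve that is flat to floating-point noise (range below $10^{-12}$
relative) selects the grid tilt nearest 0: the standard untilted procedure.

## Triangulation and correspondence

Keypoints are matched across the two scout views by a hard geometric gate —
head rays and tip rays must each pass within the tolerance of one another,
with closest approach in front of both sources — followed by a min-cost
one-to-one assignment on the summed gaps (a compact Hungarian solver,
unit-tested against permutation enumeration). The closest-point primitive
returns the unconstrained line–line solution together with both ray
parameters; the forward-half-line requirement is enforced at the gate, so
physically meaningless behind-the-source intersections are inadmissible
rather than silently clamped. When several screws lie near a common
epipolar plane the 5 mm gate can admit several candidates; the assignment
then minimizes total gap, which is deterministic and degrades gracefully
but is a documented design choice, not a uniquely correct rule.

## The synthetic scene generator

`generate_scene()` emulates instrumented surgical fields: screw lengths
uniform on 35–65 mm, shaft diameters uniform on 4–7.5 mm, centroids uniform
in a 120 mm cube about the isocenter (rejection sampling enforces
containment and a 20 mm minimum centroid separation; sizes are drawn
*outside* the rejection loop so their marginals stay exactly uniform).
Orientations are uniform on the sphere by default; a `"clinical"` preset
biases axes to within ~30° of the anterior–posterior direction, and a
`"paired"` placement arranges bilateral screws at successive levels along
the cranio-caudal axis, mimicking lumbar pedicle instrumentation (~32 mm
level spacing, ±14 mm lateral offset). `observe_scene()` emulates a 2D
keypoint detector: exact projections plus isotropic Gaussian pixel noise,
whole-object dropouts, spurious head/tip *pairs* (so decoys must pass the
matching gate), and per-view shuffled object identifiers so correspondence
is genuinely unknown.

What this does **not** emulate: real radiographic images (no DRR synthesis
— the keypoint detector itself is out of scope), anatomy and its occlusions,
detector distortion or calibration error, tulip-shaped screw heads, or
non-implant metal such as retractors. Passing tests therefore demonstrate
the geometry and optimization machinery, not detector robustness on
clinical images; keypoint noise is the interface where detector error
enters, and 1 px noise at this geometry propagates to sub-millimeter
endpoint error.

## Numerical choices

* **Ray–ellipsoid intersection** solves the quadratic in closed form and
  clips to the forward half-line; tangency (zero discriminant) counts as a
  miss. Rendering samples pixel centers without anti-aliasing, since only
  maxima are consumed.
* **Voxel baseline** uses exact grid traversal (radiological path), not
  step sampling. A voxel is occupied when its center is inside any
  ellipsoid. At 1 mm voxels the mask's surface jitter is ±½ voxel, so
  agreement with the analytic chord is only meaningful for long paths: the
  cross-method tests compare at metric-map peaks (paths of ~35–65 mm),
  where both the test suite and the acceptance script find tilt selections
  within 0–1 grid steps of each other.
* **Metric-map peak comparison** treats all entries within 0.5% of a map's
  maximum as its peak plateau, and requires the analytic and rendered
  plateaus to come within one grid step; a strict single-argmax comparison
  would be ill-posed whenever two poses score within the 2% approximation
  margin of each other.
* **Max-chord sampling.** The sampled maximum chord over $10^4$ uniform
  directions has an error of about $(\varepsilon^2/2)((a/b)^2-1)$ with
  $\varepsilon \approx 0.012$ rad the nearest-sample angle, so the 0.1%
  agreement check uses a moderate-anisotropy ellipsoid ($a/b = 1.5$); for
  10:1 screw shapes the same samples verify the dominance bound and reach
  the major axis only to a few percent.
* **Degenerate inputs** fail loudly with typed conditions: screws shorter
  than 1 mm, empty scenes (the metric is undefined with no objects),
  parallel rays, non-PD shape matrices, head-only keypoint objects (named
  by id). The CLI maps condition classes to exit codes (2 validation,
  3 computation, 4 I/O).
* **Problem sizes.** The shipped tests and the acceptance script use 50
  scenes × 15 probe poses for the centroid-approximation study, 6–8 scene
  metric maps at 25°/10° steps, two 6-screw scenes at 10°/5° steps for the
  voxel comparison, and 100 + 200 scenes for triangulation — sizes chosen
  so the whole suite runs in a few minutes on one CPU while keeping every
  estimate comfortably away from its tolerance.

## Known limitations

Single ellipsoids cannot represent tulip heads, plates, or rods; composite
primitives would be needed. Two-view triangulation assumes keypoints are
view-invariant and can mis-assign screws lying in a common epipolar plane.
Only tilted circular orbits are considered — no non-circular trajectories,
no collision model with the operating table, and no alternative artifact
predictors (spectral shift, scatter fraction). The tilt grid is discrete;
$\delta^*$ is never interpolated between grid points.
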