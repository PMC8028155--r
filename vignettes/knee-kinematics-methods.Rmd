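---
title: "Methods: marker repair, landmark calibration and knee angle extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker repair, landmark calibration and knee angle extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneemocap)
```

## The measurement problem

Optical motion-capture systems track small markers fixed to the skin of a
moving subject. To describe how the knee moves, one needs the pose of the
femur and the tibia — but bones cannot be marked directly. The standard
workaround, which this package implements end to end, is the
cluster-plus-probe technique:

1. Four surface markers per segment (a *cluster* on the thigh, another on
   the calf) are tracked throughout the movement. Each cluster is treated
   as rigid.
2. Seven bony landmarks (greater trochanter, medial/lateral femoral
   epicondyles, medial/lateral tibial plateau edges, medial/lateral
   malleoli) are digitised once with a stylus *probe* whose tip position
   follows from its own four-marker geometry.
3. Each landmark is expressed in the coordinates of its segment's cluster
   and then reconstructed in every motion frame as a *virtual marker*.
4. Anatomical coordinate systems are built from the reconstructed
   landmarks, and the relative femur–tibia rotation is decomposed into
   three clinical angles.

Raw recordings additionally contain occlusion gaps (a camera loses sight
of a marker) and single-sample "bounce" spikes; a repair stage (the Patch
Program) precedes everything else.

## Rigid registration

Every geometric step — probe-tip solution, landmark calibration, virtual
marker reconstruction, dropout repair — reduces to one primitive: the
least-squares rigid transform between corresponding point sets,

$$\min_{R,\,t}\; \sum_i \lVert R\,s_i + t - d_i \rVert^2,
\qquad R^\top R = I,\ \det R = +1,$$

solved in closed form by centroid subtraction and the SVD of the
cross-covariance matrix (the Kabsch solution). When noise or near-planar
geometry makes the unconstrained optimum a reflection, the sign of the
smallest singular direction is flipped, so the result is always a proper
rotation. The suite verifies the closed form against a brute-force
numeric minimiser over axis-angle parameters, and checks noiseless
recovery of random poses to below $10^{-9}$ elementwise.

Degeneracy is policed at the source: point sets whose second principal
extent is below $10^{-8}$ of the first (collinear or coincident markers)
are rejected rather than silently producing an ill-conditioned pose.
Every fit also reports its residual RMS in mm, which propagates into the
QC report so that a loose probe or a deformed cluster is visible.

## The Patch Program

Repair operates per 4-marker cluster, in a fixed order:

1. **Spike detection.** A sample is a bounce when both displacement legs
   into and out of it exceed $k$ times the marker's median inter-frame
   displacement *and* the direct step between its neighbours is shorter
   than either leg (the trajectory "returns"). Flagged samples are
   invalidated. The criterion and its default $k = 5$ are this package's
   own definition — bounce artifacts are recognisable in plots but have no
   standard formula — and $k$ is exposed in the session configuration.
2. **Rigid completion.** A frame missing exactly one marker borrows the
   nearest complete frame (ties broken toward the earlier frame, which
   also covers the "previous frame" reading): the transform fitted on the
   three shared markers carries the donor's fourth marker into the gap.
   On genuinely rigid clusters this is exact, which is why it runs before
   any interpolation.
3. **Discard rule.** A frame still missing two or more of its four
   markers after rigid completion has lost its cluster geometry; no
   per-marker interpolation can restore a pose that two trajectories must
   agree on. All four samples of such frames are invalidated and counted
   as discarded. Discarding is implemented as mask invalidation, never row
   deletion, so frame indices stay aligned across clusters. The rule runs
   *before* the spline stage deliberately: otherwise a coordinate-wise
   spline would happily bridge a simultaneous two-marker dropout and
   fabricate a pose.
4. **Spline fill.** Remaining interior gaps no longer than
   `max_gap_frames` (default 50 frames, 0.5 s at 100 Hz) are filled per
   coordinate by a natural cubic spline through all valid samples of that
   marker. Natural boundary conditions (zero second derivative at the end
   knots) are the conventional choice when no derivative information
   exists. Edge gaps are never extrapolated, and gaps longer than the
   limit are treated as motion loss, not noise.

Every repaired, discarded or still-missing sample is logged with its
method and donor frame; the per-marker counts satisfy the conservation
identity kept + rigid + spline + discarded + missing = total, which the
suite asserts over seeded random corruption draws. Patching its own
output performs zero further repairs.

## Landmark calibration and virtual markers

With the probe's local marker geometry (tip at the origin), registering
those local points onto the measured probe markers places the tip at the
translation of the fitted transform. For each calibration frame the tip
gives the landmark's global position; registering the cluster's reference
geometry onto its observed markers, then applying the inverse pose, gives
the landmark in cluster-local coordinates. The final local position is
the mean over all usable frames, and the RMS spread about that mean is
reported as the calibration residual (a warning is raised above 1 mm).
Averaging across frames is the natural noise reducer when a static
calibration recording has many frames; the frame count is a configuration
choice, not a constant.

The cluster's reference geometry defaults to the mean observed marker
positions in the first calibration recording of that cluster; a dedicated
reference recording may be supplied instead and simply re-bases the
template — since the calibration chain is a composition of rigid
transforms, the choice of reference pose cancels out of the reconstructed
landmarks.

During motion, each frame's cluster pose maps the calibrated local
landmarks back to global coordinates. All four markers are used when
available; three suffice (a plane fixes a rigid body), and frames with
fewer than three valid markers yield invalid landmark samples rather than
errors.

## Anatomical frames and the X-Y-Z angle decomposition

The femoral frame: the epicondyle line is the mediolateral X axis
(pointing laterally; mirrored for a left leg), its midpoint is the
origin, the cross product of X with the direction from the greater
trochanter to the origin gives the anterior Y axis, and Z = X × Y points
superiorly. The tibial frame is built the same way from the plateau line
and the inter-malleolar midpoint. Both constructions are exactly
orthonormal and right-handed by construction, and rigidly moving all
landmarks rigidly moves the frames (an equivariance the suite checks to
$10^{-9}$).

With F and T holding the femoral and tibial unit axes as columns, the
relative rotation is $R = F^\top T$ — the tibial axes expressed in the
femoral frame. Angles follow the X-Y-Z (Cardan) convention: the package
defines $(\alpha, \beta, \gamma)$ by

$$R^\top = R_x(\alpha)\, R_y(\beta)\, R_z(\gamma),$$

i.e. the femoral frame is carried onto the tibial frame by rotating
$\alpha$ about X (flexion/extension), then $\beta$ about Y
(adduction/abduction), then $\gamma$ about Z (internal/external
rotation). Extraction uses the two-argument arctangent:

$$\alpha = \operatorname{atan2}(-R_{32}, R_{33}), \quad
\beta = \operatorname{atan2}\!\big(R_{31}, \sqrt{R_{11}^2 + R_{21}^2}\big), \quad
\gamma = \operatorname{atan2}(-R_{21}, R_{11}).$$

A variant of the $\beta$ formula with $R_{12}$ instead of $R_{21}$ under
the square root circulates in print; it is not self-consistent with the
X-Y-Z factorization — the compose-then-extract round-trip fails by tens
of degrees away from the axes — so the $R_{21}$ form is the default and
the other is available as `strict_printed = TRUE` for comparison. The
round-trip property (all three angles recovered to $10^{-9}$ degrees over
a $17^3$ grid spanning ±80°) is asserted in the suite and demonstrably
fails for the printed variant.

At gimbal lock ($|\beta| = 90°$, $R_{31} = \pm 1$) only $\alpha \mp
\gamma$ is determined; the package sets $\gamma = 0$, lets $\alpha$
absorb the free angle and raises a per-frame gimbal flag. Human knees do
not approach $\beta = 90°$, so the flag marks data problems rather than
physiology.

Sign conventions: with these frame definitions $\alpha$ is negative in
flexion, so the clinical `flexion_deg` column applies a configurable
`flexion_sign` (default −1). Raw $\alpha, \beta, \gamma$ are always
reported alongside, because published curves use both sign senses and a
reader should be able to match either. Left legs are handled by
mirroring the lateral X direction.

Angle series are reported per frame and, in the style of coupled-rotation
curves, binned by flexion angle (default 2° bins, per-bin means of the
other two angles).

## The synthetic session generator

`generate_session()` builds a complete session a scientist could have
recorded: probe file, seven calibration recordings, a motion recording of
two rigid 4-marker clusters, the ground-truth angles and a ready-to-run
YAML configuration. Its defaults are the study conditions the rest of the
package is tested under:

* 500 frames at 100 Hz — one squat cycle of 5 s;
* squat profile: half-cosine flexion 0 → 100° → 0; abduction rising to
  5° until flexion passes 40°, then reversing into adduction (−5° at peak
  flexion); external rotation growing with flexion to 30° — the coupled
  pattern reported for healthy squatting knees;
* adult right-leg geometry: 100 mm epicondyle spacing, 80 mm plateau
  spacing, 400/380 mm segment lengths, clusters on the lateral thigh and
  calf (configuration values, not anatomical claims);
* lab frame with Y vertical; the femur receives a smooth global pelvis
  drop and pitch so the scene is not statically trivial, while the tibia
  is posed relative to it through the exact inverse of the angle
  convention the analysis extracts — prescribed angles are therefore the
  exact ground truth of the relative motion;
* i.i.d. Gaussian coordinate noise of configurable σ (mm), applied after
  posing; occlusion gaps and bounce spikes applied to the observations
  only, with every random draw flowing from one explicit seed (identical
  seeds give byte-identical bundles).

What the generator deliberately does **not** model is soft-tissue
artifact: the correlated, motion-phase-locked sliding of skin-mounted
markers over bone, which in real captures is the dominant error source
and is not reducible by the geometry alone. Passing recovery tests on
synthetic sessions therefore demonstrates the correctness of the
*processing chain* — registration, calibration, repair, frames, angle
extraction — not the in-vivo accuracy of skin-marker kinematics.
Noiseless sessions are recovered to numerical precision (RMSE ≤ 10⁻⁶°);
at σ = 0.2 mm marker noise the per-angle RMSE stays below 0.5° and grows
monotonically with σ, which is the behaviour the suite asserts.

## Numerical choices

* Frames are 1-based with inclusive gap bounds, matching both R indexing
  and the way capture operators quote frame ranges.
* Wide-CSV output prints doubles with 17 significant digits and encodes
  missing samples as empty cells, so a write/read cycle is bit-for-bit
  lossless; the sampling rate travels in a `# frame_rate=` comment line.
* Tolerances live in one table: stored rotations are orthonormal within
  $10^{-9}$; inverse round-trips hold within $10^{-12}$; user-supplied
  matrices are accepted up to $10^{-6}$ before validation fails; rank
  degeneracy cuts at a $10^{-8}$ relative second singular value.
* Donor ties in rigid completion break toward the earlier frame;
  bucketing ties in flexion binning follow `floor`, with bin centres
  reported.
* Problem sizes in the suite follow the study conditions (500-frame
  sessions, 200 registration poses, $17^3$ Euler grid, 50 corruption
  draws); these are the sizes at which the properties are claimed.

## Limitations

* Joint translations are not computed — the decomposition is purely
  rotational, and anterior/posterior drawer or compression are out of
  scope.
* The angle convention is a fixed-axis Cardan sequence, not a
  floating-axis joint coordinate system; the two agree at small coupled
  angles but diverge at large flexion. The convention here is declared
  and internally validated rather than claimed clinically superior.
* Real capture exports vary; the readers cover wide CSV (canonical,
  lossless) and TRC (read-only). The binary C3D container is not parsed;
  export to text first.
* The spike detector is a heuristic; pathological trajectories (true
  50 mm single-frame motion) would be flagged. Its threshold is
  configurable per session.
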