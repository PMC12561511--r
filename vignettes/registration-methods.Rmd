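---
title: "Coarse-to-fine registration of cross-source spinal surfaces: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine registration of cross-source spinal surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spinereg)
```

## The problem

In navigation-assisted pedicle screw fixation, a pre-operative surface
model of the spine (reconstructed from CT) must be rigidly aligned with
an intra-operative surface scan of the surgically exposed anatomy. The
two clouds come from different sensors and therefore differ in point
density and sampling pattern; the exposed area is a small patch
(typically only 1--4 % of the pre-operative surface has a counterpart
in the scan); and the initial poses can differ by rotations approaching
180 degrees per axis and translations beyond 100 mm. Classical
descriptor pipelines degrade badly in this regime, which motivates a
coarse stage built on learned point matching over candidate local
regions, followed by standard ICP refinement.

`spinereg` implements that pipeline end to end, together with a
parametric vertebra phantom so that training, registration and
noise-robustness experiments are fully reproducible without any
external data.

## Pipeline overview

Given a pre-operative cloud $Q$ and an intra-operative cloud $P$ (mm
coordinates throughout):

1. **Density equalization.** $P$ is voxel-down-sampled until its median
   nearest-neighbor spacing is within 20 % of $Q$'s
   (`equalize_density()`), removing the cross-source density mismatch
   that would otherwise distort the learned descriptors. The fine stage
   later uses the *full* $P$: refinement benefits from every measured
   point.
2. **Curvature.** Each point gets the surface-variation feature
   $\sigma = \lambda_3 / (\lambda_1 + \lambda_2 + \lambda_3)$, from the
   eigenvalues of the covariance of its 5 mm neighborhood
   (`compute_curvature()`). $\sigma \in [0, 1/3]$, zero on planes, and
   is invariant under rigid motion and uniform scaling — the natural
   1-D input feature for cross-pose matching.
3. **Candidate regions.** $Q$ is farthest-point-sampled into $k = 25$
   sample points whose closed balls of radius $r$ form overlapping
   candidate regions (`extract_regions()`). Only one of them contains
   the true overlap; the matcher has to find out which.
4. **Matching.** The intra-operative cloud and each region are encoded
   into keypoints with descriptors, contextualized by self/cross
   attention, matched by a temperature-scaled softmax over descriptor
   similarities, and reduced to mutual-argmax correspondences.
5. **Pose per region.** RANSAC over the correspondences (minimal
   3-point hypotheses, least-squares refit on the consensus set).
6. **Region selection.** In *oracle* mode (the evaluation protocol)
   regions are ranked by the rotation error of their pose against the
   known ground truth; in *blind* mode (deployment) by RANSAC inlier
   count, then trimmed RMS residual. Ties break to the lowest region
   index.
7. **Refinement.** Point-to-point ICP of the full intra-operative
   cloud against the full pre-operative cloud from the coarse pose.

Errors against a ground-truth transform $T_G$ are reported as
$e_r = \arccos((\operatorname{tr}\Delta R - 1)/2)$ (degrees, the
argument clamped to $[-1,1]$ against floating-point drift) and
$e_t = \lVert \Delta t \rVert$ (mm), where
$\Delta T = T\,T_G^{-1}$. A coarse result with $e_r > 60^\circ$ or
$e_t > 60$ mm counts as a registration failure and is excluded from
mean-error summaries; the same rule is applied per stage.

## The matcher

**Architecture.** Three set-abstraction (SA) layers each
farthest-point-sample their input, group neighbors inside a radius
(nearest 32 kept), push each neighbor through a small perceptron and
max-pool per group; one feature-propagation (FP) layer
inverse-distance-interpolates the deepest features back onto the
first-layer keypoints and projects to the descriptor dimension. A
self/cross multi-head attention block then conditions each cloud's
descriptors on the other cloud, and descriptors are centered across
keypoints and L2-normalized.

Two design choices deserve emphasis:

* **Pose-invariant inputs.** Every local neighborhood is encoded by
  rotation-invariant quantities only — the radial offset to the SA
  center plus the previous layer's features (curvature at the bottom).
  Attention is feature-only. Descriptors therefore cannot depend on
  the initial pose, which is what makes matching feasible when
  per-axis rotations reach $\pm 170^\circ$; raw-coordinate encodings
  would have to learn that invariance from data volumes this package
  does not assume.
* **Centered descriptors.** The matching loss has an exact stationary
  point where all descriptors of a cloud collapse to a single vector
  (all rows of the similarity gradient then cancel); small models
  started near that regime die there. Centering the descriptor matrix
  across keypoints before row normalization removes the collapsed mode
  entirely.

**Matching.** $\phi = \mathrm{softmax}(\hat f_X \hat f_Y^\top / T)$,
each row a distribution of one source keypoint over all target
keypoints. $T$ is a learnable scalar (log-parameterized). The two
keypoint sets may differ in size when a candidate region is small, so
$\phi$ is allowed to be rectangular; rows still sum to one.
Correspondences are mutual argmaxes above a probability floor.

**Loss and training.** Ground-truth correspondences of a training pair
are keypoint pairs within a correspondence radius under the true
transform; the loss is the symmetric negative log-likelihood of those
pairs under $\phi$ (both softmax directions averaged), scaled by a
constant. The radius matters: it must be on the order of twice the
keypoint spacing (2.5 mm here). Much larger values label nearly every
keypoint pair in a small patch as "true", at which point the optimal
$\phi$ is uniform and nothing can be learned. Optimization is Adam
with the learning rate halved every 5 epochs, one shared seed driving
weight initialization, batch order and resampling; two runs with the
same seed produce bit-identical loss curves.

The package's reduced-scale protocol (used by its validation
experiment and tests) trains for 20 epochs at learning rate $10^{-2}$,
batch size 2, temperature initialized at 0.1, clouds resampled to at
most 512 points by FPS. This is a deliberate desk-scale schedule:
roughly 800 optimizer steps in total, so the step size must be far
larger than one would use for thousands of steps on a GPU-scale run.
Training examples are built by `training_pairs_from_synthetic()`,
which crops the pre-operative cloud to balls around the true overlap
at two radii (1.3 and 2.2 times the patch bounding radius) — at 1--4 %
overlap an uncropped pair leaves almost no ground-truth keypoint
correspondences after resampling, and the two crop scales expose the
matcher to both tight and region-sized context, matching what it faces
at test time.

## Candidate regions, RANSAC, ICP

The region radius defaults to $0.75\times$ the intra-operative cloud's
bounding-sphere radius, floored at $1.1\times$ the FPS coverage
distance of the pre-operative cloud (the largest distance from any
point to its nearest sample). The floor guarantees the union of the 25
regions covers the whole surface; without it a small exposed patch can
fall between sample points and no candidate region contains the true
overlap.

RANSAC uses 5000 minimal hypotheses, an inlier threshold of twice the
median keypoint spacing of the region, degenerate (near-collinear)
samples rejected, and a single least-squares refit on the consensus
set; it is deterministic given its seed.

ICP is the point-to-point variant: nearest neighbors within a 10 mm
cutoff, cumulative re-estimation by orthogonal superposition, stop
when the mean matched residual changes by less than $10^{-6}$ mm.
By default each re-estimation is Welsch-weighted with the scale set
from the median residual ("robust"); this softens the bias that
boundary points and cross-source sampling exert on the fit while
remaining a point-to-point method. Optional variants: trimming (keep
the closest fraction of matches) and a symmetric correspondence pass
(target points matched back to the source, gated by the forward
residual scale, useful as a final polish). If no point matches at the
initial pose, the initial transform is returned with a flag rather
than an error.

## The synthetic phantom

`make_phantom()` samples a single star-shaped radial surface
$r(u)$ over the unit sphere: an ellipsoidal body (semi-axes
20/14/11 mm) modulated by smooth directional bumps — a long blade-like,
azimuthally asymmetric "spinous process" reaching ~36 mm from the
center, two small tubercles on its tip, one below it, and two lateral
"transverse processes" — plus a deterministic relief (~1 mm amplitude,
3--4 mm wavelength) tied to spatial position. Directions are drawn
uniformly (or uniformly within a spherical cap when sampling the small
exposed patch) and accepted proportionally to $r(u)^2$, the dominant
term of the area element.

Three properties of this construction are load-bearing:

* A *single implicit sheet* has no seams or double layers, so two
  independent samplings are geometrically consistent — exactly the
  assumption cross-source registration rests on.
* The blade anisotropy, tip tubercles and relief *break the rotational
  symmetry* of the exposed patch. A smooth protrusion leaves the patch
  pose underdetermined about the process axis and no registration
  method could pin it; real vertebral anatomy is never that smooth.
* The relief amplitude sits near the sampling resolution, so the
  achievable fine-stage rotation accuracy is governed by cloud density
  — as it is for real scanner data.

`make_pair()` turns the phantom into a registration pair: the
pre-operative cloud is a fresh sampling of the whole surface (default
16384 points, ~0.45 mm spacing, a realistic CT-surface budget); the
intra-operative cloud independently re-samples a patch anchored near
the process tip, keeps front-facing points (emulating line-of-sight
exposure), at twice the pre-operative density by default. The patch
radius is calibrated so the overlap ratio — the fraction of
pre-operative points with a transformed intra-operative point within
$\tau = 2\times$ the pre-operative median spacing — hits a target
drawn from 1.3--4.3 %. The patch is then moved by a pose drawn
uniformly within $\pm 170^\circ$ per axis and $\pm 115$ mm per
component, and optionally perturbed with isotropic Gaussian noise
($\sigma \in \{0.25, 0.5, 0.75, 1\}$ mm in the robustness sweep). The
stored ground truth maps the intra-operative cloud back into the
pre-operative frame exactly (pre-noise). With `density_ratio = 1` the
patch is an exact subset of the pre-operative samples instead — a
single-source sanity regime.

What the phantom does **not** emulate: real vertebral anatomy (it is
parametric by design), soft-tissue occlusion beyond the crop,
scanner-specific noise structure (speckle, outlier blobs), or
multi-vertebra articulation. Passing tests on this generator
demonstrates the statistical machinery — cross-source density
handling, tiny-overlap region search, pose-invariant matching, noise
robustness — not anatomical generality.

## Numerical choices and degenerate inputs

* Rotation validity is checked to $10^{-6}$; invalid matrices are
  rejected, never re-orthonormalized.
* $\arccos$ arguments are clamped to $[-1, 1]$.
* FPS breaks distance ties by lowest index, making every sampling
  deterministic; argmax ties in correspondence extraction likewise.
* Curvature neighborhoods below `min_neighbors` (default 5) points get
  $\sigma = 0$ (flat prior) and are counted on the returned cloud.
* Clouds smaller than the deepest SA layer's output cannot be encoded
  (error); candidate regions that small are skipped and logged.
* The temperature, loss scale and correspondence radius live in
  `training_config()`; the matching loss guards $\log \phi$ away from
  $-\infty$ with a floor at `1e-300`.

## Validation protocol and problem sizes

The packaged validation experiment (`validation_experiment()`, also
run by `scripts/acceptance.R` and the acceptance tests) uses 40 pairs
at 16384 pre-operative points, density ratio 2, no noise, the 20-epoch
training schedule above, oracle-mode selection over 25 regions, and
robust ICP; the noise sweep re-noises pairs at
$\sigma \in \{0, 0.25, 0.5, 0.75, 1\}$ mm with fresh seeded draws.
These sizes are the package's reference configuration; every knob is
exposed for larger runs.

## Known limitations

* The fine-stage rotation error on noise-free pairs is limited by
  nearest-neighbor quantization of point-to-point ICP at the patch
  scale: with a ~6 mm patch radius and ~0.45 mm point spacing the
  minimum of the ICP cost sits a fraction of a degree to a degree away
  from the exact simulated pose, and this floor shrinks only slowly
  with density. Studies that derive their reference transforms *from*
  an ICP fit cannot observe this bias by construction; against an
  exact analytic ground truth it is visible and reported honestly.
* Blind-mode region selection (inlier count, then residual) is a
  deployment surrogate; the evaluation protocol's oracle ranking needs
  the ground truth and is only available in simulation or phantom
  studies.
* Training is CPU-bound and deliberately small; the architecture
  defaults trade capacity for determinism and runtime.
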