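---
title: "Landmark-based registration and docking for volume CLEM: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based registration and docking for volume CLEM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clemdock)
```

## Overview

`clemdock` targets one concrete problem in correlative light–electron
microscopy: a structure of interest has been followed by intravital
two-photon microscopy (2PEM) deep inside skin tissue, the tissue has been
fixed, embedded and serially sectioned for EM, and the structure must be
found again inside the resin block. The package treats this as a 3D
point-set registration problem between two coordinate frames:

1. **Correlation** — identify the same anatomical features in both
   volumes: vessel bifurcations, collagen-fiber cross-points, and
   near-infrared-branding (NIRB) marks burned into the skin surface.
   These become paired landmark sets.
2. **Registration** — fit a spatial transform that carries the in-vivo
   (LM) frame into the block (EM) frame.
3. **Docking** — push the region of interest (ROI) through that
   transform, attach an accuracy estimate, and translate the predicted
   depth window into serial-section indices.

All coordinates are physical micrometres, right-handed, with the origin
at a stack corner on the skin surface and z increasing with depth. Voxel
indices are 0-based and refer to voxel centres; they exist only inside
the conversion routines (`to_physical()`, `to_voxel()`), because the two
modalities are sampled anisotropically and at different scales (the 2PEM
stack is typically stretched in z relative to the EM reconstruction), so
per-modality spacing must always be supplied explicitly and is never
inferred from image files.

## The transform family

Four nested least-squares fits are exposed, in increasing flexibility:
rigid (rotation + translation, the orthogonal-Procrustes/Kabsch
solution), similarity (Umeyama's one-scale extension — the scale absorbs
the global shrinkage of fixation, around 5% for glutaraldehyde, or
swelling for osmium), affine (anisotropic stretch/shear), and the
Bookstein thin-plate spline. Nesting guarantees
`RMS(rigid) >= RMS(similarity) >= RMS(affine) >= RMS(TPS, lambda = 0) = 0`
on any pairing, which the test suite asserts on random problems. The
rigid fit is deliberately scale-free: a shrinking specimen should show up
as residual structure in the rigid report, not be silently absorbed.

If the unconstrained Procrustes optimum is a reflection, the smallest
singular direction is flipped to give a proper rotation and a warning is
raised — a reflection-optimal pairing means one modality's axes are
flipped and should be fixed upstream, not papered over. Collinear (for
rigid/similarity) and coplanar (for affine/TPS) source configurations are
rejected, detected by a singular-value ratio below 1e-8 of the centred
coordinate matrix.

### Thin-plate spline details

The 3D spline uses the biharmonic fundamental solution `U(r) = r` in its
sign-positive convention:

`f(x) = A x + t + sum_i w_i * |x - x_i|`

subject to the side conditions `sum_i w_i = 0` and
`sum_i w_i x_i' = 0` per output axis, which bound the warp at infinity.
The 2D `r^2 log r` kernel does not apply in 3D. Two numerical choices
matter here:

* **Regularization sign.** With the sign-positive kernel, the quadratic
  form `W' K W` is conditionally *negative* on the side-condition
  subspace — the bending energy is `-W' K W`. The smoothing system is
  therefore `(K - lambda I) W + P B = Y`, which is the classical
  `(K~ + lambda I)` smoothing spline rewritten from the `K~ = -r`
  convention. With this sign, increasing `lambda` monotonically
  decreases bending energy and increases control-point residual (the
  trade-off the tests assert over a `lambda` grid); the opposite sign
  would anti-regularize. `lambda = 0` (the default) gives exact
  interpolation — the mode used to force paired landmarks to overlap —
  and `lambda > 0` is available for noisy pairings.
* **Conditioning.** The system is solved per output axis via a QR
  null-space reduction of the polynomial block (which enforces the side
  conditions to machine precision), followed by one step of iterative
  refinement against the full system. Inter-landmark distances are
  computed from coordinate differences rather than the expanded
  inner-product form; at micrometre coordinate scales the expanded form
  loses about half the significant digits for nearby points, which is
  observable as 1e-7-level coefficient errors. The test suite checks the
  solver against an independently coded dense solve of the full
  `(n+4) x (n+4)` system to 1e-8.

Coincident source control points make the kernel singular and are
rejected by id; a condition estimate above 1e12 triggers a warning
suggesting a larger `lambda`.

## Accuracy: leave-one-out docking error

No external ground truth exists when docking real data, so accuracy is
estimated by leave-one-out cross-validation over the landmark pairs:
refit without pair *i*, predict the held-out source point, record the
distance to its true target. The median of these errors is attached to
every `dock_roi()` result; the boolean `within_claimed_accuracy` compares
it against a fixed 20 µm reference line — the order of magnitude at which
a structure's position inside an EM-processed block can reasonably be
predicted. The median (not the mean or max) is used because with ~10
landmarks a single poorly localized landmark would otherwise dominate the
estimate of typical targeting error; the per-landmark list and maximum
are also returned.

ROI points far outside the landmark cloud (beyond 25% of the landmark
bounding-box diagonal) set an extrapolation flag: a thin-plate spline is
an interpolant, and its behaviour degrades outside its control points.
Docking still runs — the operator may genuinely need an extrapolated
guess — but the accuracy estimate is then optimistic.

The NIRB coarse alignment (`coarse_align_nirb()`) fits translation and
rotation about z only, with z translation pinned to 0, because surface
branding is xy-precise but depth-blind; any systematic z offset between
the mark sets is reported, never corrected. Its role is to initialize
automated pair suggestion (`suggest_pairs()`, mutual nearest neighbours
with a distance gate and feature-class matching), never to set docking
depth.

## Feature detection

Vessel bifurcations are proposed automatically from a binary vessel mask:
3D topological thinning (sequential simple-point peeling with endpoint
preservation, implemented in C++) reduces the mask to a 1-voxel-wide
centerline graph; nodes of degree ≥ 3 are bifurcation candidates, merged
within 3 µm. Thinning displaces a junction voxel by up to roughly the
vessel radius toward the parent branch, so each merged candidate is then
refined to the least-squares intersection of 3D lines fitted (by PCA) to
the incident skeleton branches, using skeleton nodes between 5 and 20 µm
from the raw junction — far enough to escape the distorted junction
neighbourhood, close enough that vessel curvature is negligible. On
rasterized simulator trees (1.5 µm voxels) this lifts localization from
~3 µm errors to sub-micrometre in most cases, with recall 0.94 at a 2 µm
tolerance over 20 seeds.

Collagen cross-points are the closest-approach midpoints between fiber
centerline pairs: fibers rarely intersect exactly in 3D, so a "crossing"
is emitted when the minimum segment-to-segment distance between two
fibers falls below a 2 µm gate (about the fiber bundle radius), one
candidate per fiber pair at the global minimum. A bounding-box prefilter
skips distant pairs; the result is identical to the brute-force
all-segment-pairs scan, which the tests assert.

## The synthetic test bed

`generate_tissue()` emulates the imaged volumes this workflow is used on:
mouse ear skin fields of 270–440 µm in xy imaged 60–200 µm deep (the
default scenario uses 400 × 400 × 150 µm). It contains:

* a recursive binary vessel tree (3 split levels by default, hence
  2³ − 1 = 7 bifurcations, root radius 5 µm tapering by the Murray's-law
  ratio 2^(−1/3));
* 30 collagen fibers modelled as long, gently curving polylines running
  mostly parallel to the skin surface — dermal collagen bundles traverse
  the field in layered sheets, which is also what makes gate-level
  cross-points common (roughly 7–16 per volume);
* 6 cells placed 8–25 µm off vessel walls, mimicking perivascular tumor
  cells;
* a 4-corner NIRB frame at the surface, inset 15% from the volume edge.

`apply_em_processing()` then applies the deformation model: a global
anisotropic scaling about the volume centroid plus a sum of Gaussian
displacement bumps,

`q = c + S (p - c) + sum_k a_k exp(-|p - c_k|^2 / (2 w_k^2))`.

The default scenario (`s1-default`) uses isotropic scales 0.95 — the
reported magnitude of glutaraldehyde shrinkage — and 3 bumps of up to
8 µm per-axis amplitude and 120 µm width. The bump magnitudes are not
measured quantities; they are chosen so that the deformation is smooth
but clearly non-homogeneous, reproducing the qualitative finding that
rigid registration cannot overlay the landmark sets while the
interpolating spline can (the tests require rigid RMS > TPS RMS in 20 of
20 seeds). Landmark observation adds isotropic Gaussian localization
noise (sd 2 µm per axis) and a 10% per-landmark dropout per modality; 12
bifurcation/crossing landmarks, selected for spatial spread (all
bifurcations first, then greedy farthest-point among crossings), are
retained for pairing. Identity bookkeeping survives noise and dropout, so
the ground-truth correspondence is always known to the tests — pairing in
the simulator is by id, sidestepping the correspondence problem that
`suggest_pairs()` addresses for real data.

What the simulator does **not** emulate: image formation (no PSF, no
noise textures, no segmentation errors beyond point noise), anisotropic
z-stretch between modalities (representable via `volume_geometry`, but
not part of the default scenario), correspondence mistakes (the paired
ids are always correct), lost or folded sections, and any systematic
section-compression error (section thickness is treated as nominal, with
a calibration scale factor exposed). Passing tests therefore validate the
geometry and statistics of the method, not its robustness to
segmentation or pairing blunders on real micrographs.

Everything is reproducible: a scenario is a pure function of its seed
(the deformation and observation draws use a stream offset from the
tissue seed so the two stages do not replay the same numbers).

## Sectioning planner

Sectioning schemes are ordered blocks of (count, thickness, kind) with an
optional repeated trailing unit, covering the three modes used in
practice: 500 nm thick sections for light-microscopy overview, 60 nm thin
sections for TEM, and 240–300 nm semi-thick sections for tomography.
`alternating_scheme()` encodes the screening strategy (an approach run of
thick sections, then repeated series of 10 thin + 2 thick); with its
default 180 approach sections the approach depth is 90 µm and each series
unit adds 1.6 µm. Section intervals are half-open `(z_start, z_end]`,
1-based from the block face, tiling the block exactly; a point prediction
landing exactly on a boundary is assigned to the deeper section (the
conservative choice when deciding where to start collecting).
`sections_covering()` is the plain ceiling rule — e.g. spanning a 50 µm
window at 300 nm takes 167 sections — and reports the mathematical
minimum; operators add margin on top. `depth_to_sections()` widens the
docking window by the accuracy estimate on both sides before converting
to indices, so the section range is monotone in the accuracy margin.

## Validation problem sizes

The test suite and acceptance script run the full pipeline at the sizes
the package is designed for: 20 independent scenario replicates for the
stochastic checks (docking error, shrinkage recovery, rigid-vs-spline
contrast, bifurcation recall), TPS-oracle comparisons at up to 20
landmarks, 100 random pairings for the nested-residual property, and
1.5 µm voxels for rasterization/thinning (finer than half the smallest
vessel radius, coarse enough to keep a 400 µm field tractable). The
scenario's 12-landmark pairings are small by point-registration
standards but faithful to practice, where each landmark is found by eye
in two modalities.

## Known limitations

* The thin-plate spline has no closed-form inverse; mapping EM → LM
  requires refitting with the pairing direction swapped.
* With ~10 landmarks the leave-one-out estimate is itself noisy; it
  estimates typical error near the landmark cloud, not worst-case error
  at the ROI.
* Junction refinement assumes locally straight vessels within 20 µm of a
  branch point; tortuous vasculature (e.g. tumor-associated vessels) will
  reduce localization accuracy, and densely packed junctions closer than
  the merge radius are reported as one.
* The fiber-crossing detector emits one candidate per fiber pair; two
  fibers that genuinely cross twice yield only the closer crossing.
* Automated pair suggestion requires a reasonable coarse alignment and
  degrades when spurious detections outnumber true landmarks; proposals
  are explicitly marked as requiring review.
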