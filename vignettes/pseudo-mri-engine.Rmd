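---
title: "Individualizing MRI templates from head-shape digitization"
author: "pseudomri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualizing MRI templates from head-shape digitization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudomri)
```

## The problem

MEG/EEG source imaging needs a structural head model: scalp, skull and
brain surfaces for the volume conductor, and a cortical/volumetric frame
to place and display sources. When a subject's own MRI is unavailable,
a population template (e.g. MNI152) can stand in — but a fixed template
ignores the subject's head shape and size. This package individualizes a
segmented template using the one piece of head geometry that every
MEG/EEG session already collects: the digitized scalp points and
fiducial landmarks. The deliverable is a *pseudo-MRI*: the complete
template bundle, surfaces and volumes alike, warped to the subject's
head.

## The warp model

With `N` control-point pairs — digitized scalp points `q_i` and their
radial projections `p_i` onto the template scalp — the warp is a 3-D
thin-plate spline

```
f(x) = a0 + a1*x + a2*y + a3*z + sum_i w_i * phi(||x - p_i||)
```

whose `N x 3` nonlinear coefficients `w_i` and `4 x 3` affine block come
from one linear solve `L W = Q`, with

```
L = | K + lambda*I   P |      K_ij = phi(||p_i - p_j||),  P_i = (x_i, y_i, z_i, 1)
    | P'             0 |
```

The zero block enforces the moment conditions `sum w_i = 0`,
`sum w_i p_i' = 0`, which make the kernel far field decay and leave the
affine part to carry global motion. The default kernel is `phi(r) = r`,
the standard 3-D biharmonic choice; `r^2 log r` and `r^3` are available
through `tps_fit(kernel = ...)`. `phi(r) = r` is only *conditionally*
positive definite — in fact conditionally negative definite, so the
classical quadratic form `trace(W' K W)` is negative for nontrivial
warps. `bending_energy()` therefore reports both conventions explicitly:
`E_classic = trace(W' K W)` (sign included, can be negative with this
kernel) and `E_residual = sum ||f(p_i) - q_i||^2`, the summed squared
control-point mismatch. Neither is silently substituted for the other.

### Adaptive regularization

`lambda` trades interpolation exactness for smoothness. Rather than
fixing it, the solver starts at `1e-10` and multiplies by 10 until the
system is *stable*, operationalized as: the solution is finite, the
condition-number estimate of `L` is at most `1e12`, and the relative
solve residual is at most `1e-8`. Two steps of iterative refinement
follow every LU solve; without them the attainable residual at `N = 300`
is limited to roughly `kappa(L) * eps`, visibly above the interpolation
tolerance. Well-posed pairings therefore keep `lambda = 1e-10` and
interpolate exactly; degenerate pairings (near-duplicate sources,
rank-deficient geometry) escalate finitely, and escalation past `1e-2`
is an error rather than a silent smooth-out.

### Control-point pairing

Digitization points lie *outside* the scalp, so each point is paired
with the outermost intersection of the ray from the head-frame origin
through the point with the template scalp. Rays that miss the surface
fall back to the nearest surface point and are flagged in the report.
The three digitized fiducials are always appended as pairs, anchoring
the warp at the landmarks. Pairing observes only the *radial* component
of whatever deformation separates subject from template; this is
intrinsic to the scalp-matching problem (any correspondence chosen on a
featureless surface is a convention) and shapes what the synthetic
experiments can claim — see below.

## Digitization conditioning

Defaults in `conditioning_config()`, all in millimeters:

| parameter | default | role |
|---|---|---|
| `plane_margin_mm` | 10 | keep points above a plane ~1 cm below the fiducial plane; below it lies face/neck geometry that destabilizes the warp |
| `min_reject_frac` | 0.02 | outlier-rejection floor: the 2 % most scalp-distant points are always dropped |
| `max_reject_frac` | 0.10 | rejection ceiling |
| `densify_threshold` | 50 | clouds smaller than this are mirrored across the sagittal plane |
| `n_max` | 300 | density cap, enforced by farthest-point downsampling |
| `inward_shift_mm` | 1.5 | stylus-standoff compensation, radially toward the head-frame origin (range 1–2 in practice) |
| `dedupe_tol_mm` | 1.0 | mirrored points closer than this to an existing point are dropped; below digitizer noise (0.94 mm) so true duplicates, not structure, are merged |

The outlier statistic is a robust fence — distance beyond
`median + 3 * 1.4826 * MAD` of the scalp-distance distribution — with
the 2 %/10 % band enforced unconditionally; the band, not the fence, is
the contract. The inward shift is radial rather than along local surface
normals because normals estimated from sparse noisy clouds are
unreliable; on head-sized ellipsoids the angle between the two choices
costs only a few percent of the shift. Points labeled as HPI coils are
never used as scalp evidence.

## The synthetic head generator

`make_template()` builds nested ellipsoidal surfaces (scalp semi-axes
95/80/100 mm; outer skull, inner skull and brain offset 6/10/14 mm
inward) as subdivided icospheres, with fiducials snapped onto the
faceted scalp (nasion front, LPA/RPA lateral — so the bundle is already
in its head frame), an intensity volume with one value per tissue shell,
and a matching integer label volume. `make_subject()` applies a known,
exactly invertible deformation; `sample_digitization()` draws
approximately area-uniform scalp points above the fiducial plane,
offsets them along outward normals (stylus standoff, default 2 mm), adds
isotropic Gaussian noise (default STD 0.94 mm, the digitizer-accuracy
figure for electromagnetic trackers), and optionally removes a
spherical-cap patch or injects outward outliers. Everything is
deterministic per seed.

### Design of the ground-truth deformation

The `"harmonic"` mode used by the recovery experiments is a *radial*
field: each point moves along its ray from the head center by a smooth
spherical-harmonic function of direction, scaled so the largest
scalp-vertex displacement equals `deform_amplitude_mm`. Three deliberate
choices:

* **Radial, not tangential.** Radial-projection pairing cannot observe
  tangential motion of a smooth surface; a ground truth with tangential
  components would make vertex-wise recovery error measure the
  generator's null space rather than the engine. Global linear motion is
  exercised separately by `deform_mode = "affine"`, generic smooth warps
  by `"tps"`.
* **Supported where digitization reaches.** The field tapers smoothly to
  zero at the fiducial-plane latitude: no digitization point can ever
  constrain the head below the plane, so deformation placed there is
  unrecoverable *by construction* and would only add a constant floor to
  every experiment. The cost of missing coverage is probed explicitly by
  the masked-patch experiment instead.
* **Dominantly left–right symmetric.** Sagittal-mirror densification
  rests on approximate bilateral head symmetry; the field's x-odd
  harmonics are kept at 15 % of the even ones so that mirroring is
  approximately valid (as for real heads) yet not exact.

What the phantom does **not** emulate: real scalp geometry (ears, nose,
neck truncation), digitizer error fields that vary over the head,
hair-induced bias patterns, template-to-population anatomical mismatch,
or any intensity texture inside tissue shells. Passing the synthetic
experiments shows the algorithmic chain is correct and well-conditioned
at head scale; it does not certify millimeter accuracy on real heads.

## Volume resampling

Volumes are warped by pull-back: the output voxel at world position `x`
takes the input intensity at `f_inv(x)`, where `f_inv` is a second
thin-plate spline fitted to reversed pairs (forward-warped seed points
back to the seeds; seeds are the control sources plus a coarse lattice
over their bounding box). Pull-back avoids the holes that forward
splatting creates; the median round-trip error `||f_inv(f(x)) - x||`
over a 10-mm validation lattice is attached to the inverse and written
to the run report so the approximation is never invisible. Intensity
volumes are interpolated trilinearly; integer label volumes use nearest
neighbor and keep integer storage, so no new label ever appears.

## Numerical choices

* Kernel distances are computed difference-first; the usual
  `|a|^2 + |b|^2 - 2ab'` expansion loses ~`sqrt(eps)`·scale near zero to
  cancellation, which corrupts `phi(r) = r` exactly at the control
  points. The kernel diagonal is set to zero analytically.
* Farthest-point downsampling is anchored at the point nearest the
  cloud centroid (the anchor seeds the distance field but is kept only
  if re-selected); exact ties break by a seeded shuffle, making the
  result deterministic per seed.
* Boxplot statistics use linear interpolation between order statistics
  (R type 7); the "outliers (Q3 x 1.5)" convention is read as the
  standard fence `Q3 + 1.5 * IQR` (a literal product is dimensionally
  meaningless as a fence), with the multiplier configurable.
* Cortical-envelope comparison uses a convex hull (incremental
  quickhull); a concave/alpha hull would need an alpha parameter that
  has no principled default here, so the convex envelope is the
  documented substitute.
* Quartile, fence and hull conventions are fixed in code and tested,
  not left to dependency defaults.

## Problem sizes

The test suite and the acceptance script run on icosphere levels 2–4
(162–2562 vertices per surface), volumes of 24³–64³ voxels, and
digitizations of 25–5000 points; the end-to-end recovery experiment uses
the generator defaults (level 4, 64³ at 3 mm, 200 points). The density
experiment fixes one synthetic subject and averages five digitization
draws per density level (25–300 points). These sizes were chosen so the
full chain — including volume resampling through the inverse warp —
exercises the same code paths as head-sized problems.

## Limitations

* The rigid co-registration uses fiducials only; with no subject MRI
  there is no surface to refine against, so fiducial placement error
  propagates directly into the warp (as in any MRI-free workflow).
* Regions without digitization are extrapolated, not estimated: below
  the fiducial plane the pseudo-MRI inherits template geometry deformed
  by the warp's smooth continuation, and a missing patch demonstrably
  degrades the local fit.
* With `lambda` at its floor the warp interpolates measurement noise
  exactly; beyond ~200 points the surface error saturates at the noise
  level rather than continuing to fall.
* Only the sagittal-mirroring densifier is implemented; database-backed
  densification against a scalp-surface library is out of scope.
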