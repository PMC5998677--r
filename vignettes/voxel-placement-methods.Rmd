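---
title: "Methods: template-driven voxel placement and overlap quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: template-driven voxel placement and overlap quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxplace)
```

## The problem

Single-voxel MR spectroscopy (SVS) quantifies neurochemistry inside one
cuboid volume — the *voxel* — placed in a target brain region at scan time.
When that placement is done by hand from anatomical landmarks, the voxel
lands somewhere slightly different in every subject and every session, and
because metabolite concentrations differ strongly between grey matter,
white matter and CSF, placement scatter turns directly into measurement
noise. `voxplace` implements a template-driven alternative: the voxel is
authored once on a template anatomical image, mapped automatically onto
each subject's T1-weighted scan, and the achieved placements are audited
afterwards with partial-volume-aware 3D overlap metrics.

## The prescription model

A voxel prescription is exactly what a scanner console asks for: dimensions
$(d_x, d_y, d_z)$ in mm, a centre coordinate in the image's world frame
(mm), and three angulation angles — rotations about the x, y and z axes,
labelled T>S, T>C and Rotation on the console. The package fixes one Euler
convention for both construction and decomposition,

$$R = R_z(\mathrm{rot}) \, R_y(t_c) \, R_x(t_s),$$

applied about the voxel centre, with angles canonicalized to
$(-180^\circ, 180^\circ]$. The console labels give the axis order but not
the composition order; because every downstream quantity (masks, overlap)
depends only on the pair of maps being mutual inverses, the choice is
validated by round-trip identities rather than by an external convention,
and decomposition refuses gimbal lock ($|t_c|$ within $0.01^\circ$ of
$90^\circ$) instead of guessing. All coordinates are mm in the world frame
defined by the image's NIfTI header affine; voxel indices are 0-based and
grids use the half-open extent $[\mathrm{origin}, \mathrm{origin} +
\mathrm{shape} \cdot \mathrm{spacing})$.

## Coregistration

Mapping a template voxel onto a subject uses two intensity-based
registrations of the anatomical images, both maximizing the correlation
ratio under trilinear interpolation:

* a **rigid (6-dof)** fit, whose rotation part $R_{reg}$ re-angulates the
  voxel: the subject-frame angulation is the decomposition of
  $R_{reg} R_{voxel}$;
* a **9-dof (rotation + anisotropic scale, no shear)** fit, which maps the
  voxel *centre* into subject space, calibrating for head-size differences.

Voxel dimensions are never scaled — an SVS voxel has a fixed physical
size — so only the centre placement absorbs anatomical size differences.
The prescription carries both full-precision parameters and a copy
quantized to 0.1 mm / 0.1°, the precision a console accepts.

The built-in optimizer is deliberately simple and fully deterministic: a
multi-resolution pyramid (4x, 2x block averages, then full resolution
sampled at stride 2), translation initialized from intensity centroids, a
coarse rotation-grid scan (±30° in 15° steps per axis) at the coarsest
level, and Nelder-Mead refinement at every level (up to 150 iterations,
32-bin correlation ratio). For 9-dof fits the log-scales are seeded from
the ratio of intensity-weighted coordinate variances — a closed-form
anisotropic size estimate — because Nelder-Mead alone moves off a unit-scale
start too slowly. Any external registry can be substituted through the
`backend` argument (a function of `moving, fixed, dof, control, init`
returning a world-to-world transform); the built-in one keeps the pipeline
self-contained and testable.

Two numerical details matter more than they look:

* **Background masking with a dilated band.** The correlation-ratio cost is
  evaluated only on pixels where the reference image shows tissue (above 5%
  of the maximum), *dilated by two pixels*. Pure background carries only
  noise, and trilinear interpolation smooths that noise, so including all
  of it biases the optimum a few tenths of a degree away from identity.
  But cutting the mask exactly at the head boundary is worse for 9-dof
  fits: scale inflation then goes almost unpenalized (the moving image's
  edges protrude into pixels the cost never sees), and the ~3% scale bias
  this causes does not cancel between the forward and reverse
  registrations of the pipeline. The dilated band keeps just enough
  background in the cost to anchor the head outline.
* **Pre-smoothing.** Both images receive one separable 1-2-1 smoothing
  pass before optimization, so the extra smoothing the moving image picks
  up from interpolation no longer makes slightly-off-grid poses artificially
  attractive.

## Rasterization and the threshold table

Overlap metrics operate on partial-volume masks: the voxel rasterized on a
0.5 mm isotropic grid where each pixel's value is the fraction of its
volume inside the rotated cuboid. The estimator is regular subdivision
supersampling — 5×5×5 subsample points per pixel, so values are multiples
of 1/125 — with an analytic fast path classifying pixels wholly inside or
outside (rotation-invariant half-pixel-diagonal bound), leaving only the
boundary shell to supersample. This conserves volume to well under 1% and
is checked against an exact polygon-clipping oracle in 2D. Grid origins
snap to multiples of the spacing so masks built for different voxels share
one world lattice. Voxels are assumed perfectly rectangular; real RF
excitation profiles round the edges, and nothing here models that.

A rotated cuboid's superlevel sets at different thresholds bracket its true
volume, so the package tabulates, for thresholds 0.05–0.95 in 0.05 steps,
the pixel count above each threshold and that volume as a percentage of
the nominal (unrotated) voxel volume — "Percent Total Voxel". The working
threshold is the one whose percentage is closest to, without exceeding,
100%; an unrotated voxel covers whole pixels only, every threshold gives
exactly 100%, and the highest candidate (0.95) is used. Superlevel
membership is strict (`value > t`), so 0.95 excludes edge pixels that land
exactly on 0.95. Note that the supersampling estimator is nearly unbiased,
so the selected threshold tends to sit near 0.5; pipelines reproducing a
published figure can pass a fixed `threshold = 0.65` instead, and the
Percent Total Voxel at 0.65 is itself one of the audited quantities.

## Overlap metrics

All metrics share one construction: masks are averaged pixelwise,
thresholded at the working threshold $t$, and counted against the template
voxel's own count above $t$:

* **accuracy** (placement): average of one subject mask and the template
  mask — $100 \cdot \#\{(s + \mathrm{tmpl})/2 > t\} / \#\{\mathrm{tmpl} > t\}$;
* **between-subject overlap**: average of all subject masks at one
  timepoint (the template voxel is *not* part of the average, only the
  denominator);
* **within-subject overlap**: average of one subject's masks across
  timepoints. The denominator here is genuinely underdetermined by the
  construction; the package defaults to the template-voxel count so all
  three metrics share one denominator semantics, with
  `within_denominator = "first_timepoint"` as the alternative.

Group summaries are means, SDs and the coefficient of variation
($100 \cdot \mathrm{sd}/\mathrm{mean}$, sample SD). Tissue composition
sums each GM/WM/CSF partial-volume map (resampled to the mask grid by
trilinear interpolation) over the thresholded voxel and normalizes to
100%.

Acquired-voxel geometry always comes from acquisition metadata — a
spectroscopy DICOM header (standard volume-localization fields) or the
package's JSON sidecar — never from the prescription pipeline's own
matrices, so the audit measures where spectra were actually acquired. The
reconstruction of an acquired voxel in template space mirrors the
prescription procedure run in reverse (rigid fit for angles, 9-dof fit for
the centre, dimensions preserved).

## The phantom

`make_phantom()` builds the synthetic validation world: a triaxial
ellipsoidal head (semi-axes 0.36/0.44/0.40 of the field of view) with a WM
core, GM ribbon and CSF shell at normalized radii 0.78/0.92/1.0, T1-like
mean intensities (WM 1.0, GM 0.7, CSF 0.3), compartment boundaries
softened over about one pixel, and additive Gaussian noise with SD 2% of
the WM intensity. Two asymmetric internal structures — an off-centre CSF
"ventricle" and a deep grey-matter nodule — break the ellipsoids'
rotational symmetry, without which orientation would not be identifiable
by any intensity-based registration. PVE maps are built from the same
geometry, so tissue composition is known analytically.
`perturb_subject()` resamples the template through a known rigid or
rotation+scale transform with fresh noise, emulating repositioned
subjects; `make_phantom_study()` draws whole multi-subject,
multi-timepoint studies reproducibly from one seed.

What the phantom does *not* emulate: cortical folding, intensity
inhomogeneity, pathology, or any real anatomical variability beyond a
global 9-dof size change. Passing phantom tests therefore demonstrates
that the geometry, registration and bookkeeping chain is correct at
realistic perturbation magnitudes — not that registration will achieve the
same accuracy on arbitrary clinical scans.

## Problem sizes and defaults

The phantom default is 128³ at 1.5 mm; the test suite and validation
properties run a quick profile of 48³ at 4 mm (192 mm field of view, with
head semi-axes at 0.85 of the default so extreme repositioning does not
clip the head), and 64³ at 3 mm where sub-millimetre registration claims
are asserted. At the quick profile one rigid registration takes a couple
of seconds and the full authoring → prescription → reconstruction → overlap
loop runs in about seven seconds, which is what makes ten-seed end-to-end
robustness checks routine. Under those conditions the loop recovers
placements at 97–100% overlap with the template voxel for repositioning up
to ±15 mm and ±15° per axis, the magnitude of deliberately extreme head
positions in a head coil.

## Known limitations

* The registration backend is a reference implementation tuned for smooth
  synthetic volumes; on real MPRAGE data a dedicated registry (plugged in
  through the backend contract) is expected to be both faster and more
  robust.
* Transforms are limited to 6- and 9-dof; shear and nonlinear warps are out
  of scope, so morphology far from the template (atrophy, lesions) will
  degrade placement.
* Sign conventions of the console angles (whether T>S tilts toward or away
  from the scanner bore) are not recoverable from geometry alone; the
  package guarantees internal consistency, and a site should verify sign
  once against its own console before trusting exported angles.
* DICOM support reads the standard MR spectroscopy volume-localization
  module only; vendor-private headers are not interpreted (the JSON
  sidecar is the portable path).
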