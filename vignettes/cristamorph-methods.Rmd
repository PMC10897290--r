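---
title: "Quantifying mitochondrial cristae architecture in cryo-ET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial cristae architecture in cryo-ET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cristamorph)
```

## The measurement problem

In situ cryo-electron tomography of cryo-FIB-milled cells resolves both
mitochondrial membranes — the outer membrane (OMM) and the inner membrane
with its boundary region (IBM) and cristae folds — at nanometre scale and in
a close-to-native state.  Turning such tomograms into numbers requires a
pipeline of small, well-defined measurements: projected areas and densities,
junction widths and angles, compartment volumes, crista lengths, a shape
taxonomy, and, at the core, the membrane-to-membrane width of each crista
lumen.  `cristamorph` implements that quantification layer together with a
phantom simulator that provides exact ground truth, so every stage can be
validated without any microscope data.

## Phantom tomograms

`generate_phantom()` renders a mitochondrion as a set of implicit surfaces
evaluated on the voxel grid:

* the OMM midsurface is an ellipsoid (exact signed distance for spheres,
  first-order-exact near the surface otherwise);
* the IBM follows at an inward offset of `ibm_gap_nm` (default 10 nm, the
  intermembrane spacing), with both membranes `membrane_thickness_nm` thick
  (default 5 nm, a bilayer);
* each crista is a membrane shell of constant thickness around a "core"
  solid whose boundary marks the membrane *centre* surfaces — a box for
  lamellar sheets, a capsule for tubules, a sphere for globular cristae, a
  torus for rings, an extruded arc for loops, and a pair of joined slabs for
  split cristae.  The crista width parameter is therefore the distance
  between the two membrane centres across the lumen, which is exactly what
  the template estimator reports.

Contrast follows cryo-ET convention: membranes are dark
(`membrane_density < solvent_density`).  Interfaces are anti-aliased
analytically over one voxel.  We deliberately use partial-volume
anti-aliasing rather than a global Gaussian blur: it equally prevents
aliasing artifacts in cross-correlation, but keeps the noiseless volume
two-valued away from interfaces, which gives sharper oracles for the test
suite (an optional `smooth_sigma_vox` adds extra blur when wanted).

Corruption mirrors real reconstruction order: geometry, then additive
Gaussian noise, then the missing wedge.  The wedge is applied directly in 3D
Fourier space — components whose `(k_x, k_z)` direction lies within the half
angle of the beam axis are zeroed, invariant along the tilt axis `k_y`.  A
±70° tilt range, the default acquisition geometry, leaves a 20° half-angle
wedge, and that is the default.  `noise_sigma_for_snr()` converts a target
SNR, defined here as squared membrane–solvent contrast over noise variance,
into the noise standard deviation; the tomograms the phantom emulates carry
no published SNR figure, so phantom SNR is a free parameter and our tests
state the level they use (0.5 for recovery experiments, a deliberately
unfavourable setting).

Arrays are 1-based `[x, y, z]` with x fastest — the native R layout, which
is also MRC's on-disk order — with the beam along z and the tilt axis along
y.  All metric inputs and outputs are in nm or µm.

Ground truth is closed form: compartment volumes come from the offset
geometry (exact for spherical phantoms and for detached box / capsule /
sphere / torus cristae; loop and split displaced volumes use first-order
approximations and are flagged `exact = FALSE`).  The voxel-count volumes of
`compartment_volumes()` agree with the closed forms to within 2% once the
mitochondrion radius exceeds ~20 voxels; thin single slabs quantize more
coarsely, which is why the volume oracle in the tests uses a spherical
phantom with a globular crista.

What the phantoms do *not* emulate: contrast transfer function effects,
dose-dependent noise correlations, denoising artifacts, membrane-bound
protein densities, crowding by other organelles, and segmentation errors —
real label volumes come from semi-automatic segmentation, whereas phantom
labels are perfect.  Passing recovery tests on phantoms therefore validates
the estimator logic and its noise behaviour, not the segmentation or picking
steps of a real pipeline.

## Crista width by template-bank cross-correlation

The central bespoke computation follows the subtomogram-based
membrane-separation estimator: a bank of 40 templates, each two parallel
membrane slabs separated by 1–40 pixels at 2.2 nm/pixel (2.2–88 nm), is
cross-correlated against each particle; the separation of the best-matching
template is the crista width.  The default box is 48 voxels (105.6 nm),
matching the published subvolume edge of ~1059 Å.  We note a bookkeeping
tension in the published acquisition parameters: 4×-binned 2.758 Å pixels
would give 1.10 nm, not 2.2 nm; the printed nm range is the quantity that
defines the width scale, so the package fixes 2.2 nm/px and exposes it as a
parameter.

Scores are masked zero-mean normalized cross-correlations under a soft
spherical mask (radius 0.45 × box).  Because templates are laterally
constant, the 3D masked NCC against a template reduces *exactly* to a
weighted 1D correlation of mask-reduced axial profiles; `estimate_width()`
computes that reduction (verified against brute-force 3D NCC in the tests)
and searches a small axial shift range.  Ties between templates resolve to
the smaller separation, a conservative choice.  Widths are reported at the
argmax template with no sub-template interpolation, so the estimator's
resolution is one template step (2.2 nm); the planted-width experiments ask
the median estimate to land within that step.

Orientation handling: particles sampled from phantoms carry their membrane
normal, and extraction (`extract_subtomograms()`) brings axis-aligned
normals into the template frame by exact axis permutation (oblique normals
by trilinear rotation).  For particles of unknown orientation,
`refine_orientation = TRUE` searches a 15° hemisphere grid with 3° local
refinement, scoring orientations by the axial variance of the mask-reduced
profile.

## Subtomogram alignment and averaging

`align_and_average()` is a miniature reference-based aligner: the initial
reference is the unaligned average of a seeded random half of the particles;
each iteration shifts every particle to maximize its masked NCC against the
reference (the per-shift normalization is computed exactly by FFT), the
ensemble's net drift is removed so the common frame stays anchored, and the
reference is re-averaged.  Iterations stop when no particle's alignment
changes or at `n_iter` (default 12, the study's iteration budget); the mean
cross-correlation per iteration is recorded and is non-decreasing in
practice.  Shifts are integer-voxel; an orientation search over a hemisphere
grid is available via `angular_step_deg` but defaults off, because particles
extracted with known normals are already in frame and a full rotational
search at interpreted-R speed would dominate runtime at realistic particle
counts.  The rotational path is exercised on small boxes in the unit tests.

## Projection-plane morphometrics

These functions mirror measurements made by hand on summed projection
images, so localization (outlines, probe lines, junction endpoints) is
always an input:

* `summed_projection()` sums a slice window (10 central slices by default,
  per the junction-measurement protocol).
* `normalize_contrast()` interprets the published "equalize histogram set at
  0.35%" step as saturated linear contrast stretching — 0.35% of pixels
  clipped, split between the tails, then linear rescaling to [0, 1].  True
  rank-equalization would destroy the comparability of mean gray values
  across images, which is precisely what the matrix-density comparison
  needs, so the saturation reading is the one consistent with the analysis
  that follows it.
* `matrix_density()` averages three probe lines (bilinear interpolation at
  ≤ 0.5 px steps) and then averages the three values into a single density
  per mitochondrion.
* `polygon_area()` is the shoelace formula scaled to µm²;
  `mito_coverage()` and `cristae_density()` are the corresponding ratios.
* `junction_width()` and `junction_angle()` implement the line and angle
  tools, with the convention that a crista perpendicular to the IBM scores
  90°; `aggregate_junction()` averages repeated per-section measurements of
  one junction.

## 3D shape taxonomy

Crista components (membrane + lumen voxels) are classified by an explicit
rule cascade (`classify_shape()`).  The study classified shapes by visual
inspection, so every threshold here is a package parameter
(`shape_control()`) chosen once so that canonical geometric exemplars
classify unambiguously; they are explicit stand-ins for qualitative visual
criteria, not inferred values.

The descriptors come from two 2D projections of the component:

* the projection along the thinnest principal axis detects *ring* topology
  as an enclosed hole (flood fill from the border);
* the minimum-area projection over all three principal axes yields a curve
  cross-section; Zhang–Suen thinning turns it into a skeleton whose graph
  (with redundant staircase diagonals removed and spur chains up to 4 px
  pruned) supplies endpoints, branch points, the longest geodesic path, its
  straightness (end-to-end over arc length), and a lumen-width profile
  sampled perpendicular to the path.  Footprints are binned at 2-voxel cells
  so that rotated-lattice rasterization cannot punch spurious holes.

The cascade: ring (cycle, no junctions) → loop (two junctions, straightness
< 0.8) → straight-across (two junctions, straightness ≥ 0.95) → split
(skeleton branch point) → zipped (a collapsed-lumen stretch ≥ 20 nm below
the 2.2 nm resolvable floor) → pinched (shorter interior collapses) →
vesicular (lumen density contrast below 0.6, i.e. electron-dense material in
the lumen) → canonical geometry by principal extents (lamellar when two
extents each ≥ 3× the third; tubular when one extent ≥ 3× the second and the
cross-section is round; globular when max/min < 2; otherwise amorphous,
which counts as unusual).  Junction counts and angles are inputs from ground
truth or manual picks — junction auto-detection would be a new method, and
deliberately is not one of ours.  The boundary between "amorphous" and
"globular", and between "pinched" and "zipped", is genuinely qualitative in
visual classification; our thresholds make it reproducible but should not be
read as recovering the original annotators' intent.

`classify_directionality()` maps junction angles to straight/tilted (±20°
around perpendicular) with NAO (no attachment observed) when no junction was
captured.  `detect_stacking()` flags the stacking phenotype — three or more
lamellar cristae with pairwise sheet-normal angles within 15° and mutual
footprint overlap ≥ 50% along the common normal.  `classify_multijunction()`
reuses the straightness ratio to split multi-junction cristae into straight
and loop.  `classify_mito_shape()` handles the 2D outline classes
(ellipsoidal / round / polygon / partial) via fitted-ellipse aspect ratio
(1.3) and solidity (0.95); the published category list names the concave
class "heart-shaped" in one place and "polygon" in another — the package
uses "polygon" for both.

`skeletonize_crista()` returns a centerline as the longest geodesic through
the component's 26-connected voxel graph (Euclidean edge weights, lightly
smoothed), with rings reported as cycles.  A full 3D medial-axis transform
is not available in any installed dependency and is not needed at the
accuracy the length measurements require: on narrow planted slabs the
geodesic length lands within 5% of the planted length (the membrane caps and
lattice metric contribute a few percent upward bias; components larger than
~30k voxels are strided down first).

## Statistics policy

Group comparisons follow the study's policy: two-sided Mann–Whitney by
default, Welch's t only when both samples pass Shapiro–Wilk normality at
0.05 (`choose_test()`).  `mann_whitney()` uses the exact distribution when
both samples have ≤ 8 observations and no ties, otherwise the normal
approximation with tie and continuity corrections; the branch taken is
recorded in every result.  Pairwise tests run against the reference group
(wild type) without multiple-testing correction, matching the original
reporting; a Holm adjustment and an IQR-based outlier-sensitivity re-run are
available but off by default.  The test suite checks the exact branch
against full enumeration over all labelings and verifies the nominal type-I
error over 200 null simulations.

## Pipeline and reproducibility

`run_pipeline()` chains everything: phantom groups → projection
measurements → volumes → classifications → per-particle widths → group
table → tests → CSV/JSON bundle.  One master seed drives every stream
(per-group seeds are derived deterministically), all randomness is scoped so
no global RNG state leaks, and re-running with the same config and seed
reproduces the report byte for byte.  A thin command-line wrapper
(`inst/cli/cristamorph`) exposes `simulate` and `all` subcommands; every
other stage is an ordinary exported function.

## Problem sizes used in validation

The packaged experiments run at desk scale by design: phantoms of 120³
voxels (≈ 264 nm cubes) with one to three cristae, 100 particles per width
level for the seven-level recovery ladder (widths 6.6–66 nm at SNR 0.5 under
a 20° wedge), 20 noiseless particles for planted-shift recovery, and 200
replicates for the null-calibration check.  The published per-cell-line
numbers derive from ~100 tomograms and thousands of manually picked
measurements; reproducing them would require the deposited raw data and the
original manual annotation, which is outside this package's scope.  What the
package establishes is that each measurement, given its inputs, returns the
quantity it claims — with known accuracy under known corruption.

## Known limitations

* The width estimator reports argmax-template separations; widths between
  template steps are quantized, and widths below the membrane thickness
  (merged templates) are not separable from the narrowest templates except
  by score.
* The ellipsoid distance is first-order near the surface; strongly
  eccentric phantoms push compartment-volume errors toward the 2% bound.
* Classification thresholds are calibrated to canonical exemplars;
  borderline real shapes will land on whichever side of an explicit
  threshold they fall, which is reproducible but not guaranteed to match a
  human annotator.
* Alignment searches integer shifts only, and its default skips the
  orientation search; both are adequate for frame-extracted phantom
  particles but would need extension for heterogeneous real data.
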