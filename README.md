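# cristamorph

Quantitative morphometry of mitochondrial cristae in cryo-electron
tomograms.

Mitochondrial function tracks the state of the inner-membrane folds — the
cristae — and in situ cryo-ET of cryo-FIB-milled cells resolves them at
nanometre scale without fixation artifacts.  `cristamorph` implements the
measurement layer such studies need, for structural cell biologists and
image-analysis developers who want each step testable against known ground
truth:

* **Phantom tomograms** with exact ground truth: dark double membranes
  (OMM, IBM), cristae of prescribed shape and lumen width, additive
  Gaussian noise at configurable SNR, and the missing wedge of a ±70° tilt
  range applied in 3D Fourier space.
* **Crista width** by template-bank cross-correlation: a bank of
  two-membrane templates at integer-pixel separations (default 40 templates
  at 2.2 nm/px, spanning 2.2–88 nm in a 48³ box); each particle's width is
  the separation of the template with the maximal masked zero-mean
  normalized cross-correlation,

  `width(p) = s(argmax_k max_shift NCC_mask(p, T_k))`.

* **Subtomogram alignment/averaging**: seeded random initial reference,
  per-iteration masked-NCC shift (and optional orientation) refinement,
  drift-anchored averaging, ≤ 12 iterations.
* **Morphometrics**: summed projections, saturated contrast normalization,
  polygon areas and coverage, matrix gray density from three probe lines,
  junction width/angle with multi-section averaging, compartment volumes
  (matrix + IMS + cristae lumen = total, exactly), centerline lengths.
* **Shape taxonomy**: rule-based classification into lamellar / tubular /
  globular / unusual, with the unusual subclasses (loop, split,
  straight-across, amorphous, ring, pinched, zipped, vesicular),
  straight/tilted/NAO directionality, multijunction straight vs loop, the
  three-parallel-sheet stacking phenotype, and 2D mitochondrion outlines
  (ellipsoidal / round / polygon / partial).
* **Statistics policy**: two-sided Mann–Whitney by default, Welch's *t*
  only when both samples pass Shapiro–Wilk normality; exact Mann–Whitney
  p-values by enumeration for small tie-free samples; pairwise tests
  against a reference group.

## Worked example

Simulate one mitochondrion with a 15-nm lamellar crista at SNR 0.5 under a
20° missing wedge, then measure the crista width from 100 particles:

```r
library(cristamorph)

ctr <- c(132, 132, 132)
crista <- crista_spec("lamellar", width_nm = 15, length_nm = 100,
                      depth_nm = 100, center_nm = ctr, orientation = c(1, 0, 0))
spec <- phantom_spec(box_shape = c(120, 120, 120), voxel_size_nm = 2.2,
                     omm_semi_axes_nm = c(110, 110, 110), center_nm = ctr,
                     cristae = list(crista),
                     noise_sigma = noise_sigma_for_snr(1, 0.5),
                     wedge_half_angle_deg = 20, seed = 1)
ph <- generate_phantom(spec)

bank <- template_bank()
pos <- sample_particles(ph$labels, ph$truth, n = 100, seed = 2)
particles <- extract_subtomograms(ph$tomogram, pos, box = bank$box)
particles <- estimate_widths(particles, bank)
particles
#> <particle_set> 100 particles, box 48^3 @ 2.2 nm/px (0 dropped at boundary)
#>   widths estimated: median 15.4 nm
```

The median estimate, 15.4 nm, is the planted 15 nm called at the nearest
template step (templates step in 2.2-nm increments, so 15.4 nm is the
closest representable width).  Compartment volumes and the shape classifier
read the label volume directly:

```r
compartment_volumes(ph$labels)
#> <volume_report> total 0.0044801 um^3 = matrix 0.0030739 + IMS 0.0013237 + CL 8.2458e-05
#>   fractions: CL 0.018, IMS 0.295, matrix 0.686

cl <- classify_shape(crista_components(ph$labels)[[1]])
cl$shape_class
#> [1] "lamellar"
```

The totals are exact sums of the three compartments; against the phantom's
closed-form geometry the voxel counts agree to better than 2%.  Group
comparisons follow the normality-gated policy; for example, the exact
Mann–Whitney branch:

```r
mann_whitney(c(1, 2, 3), c(4, 5, 6))
#> <mann_whitney> statistic 0, p = 0.1 (n = 3 vs 3, exact)
```

`run_pipeline()` chains phantom generation, measurement, classification,
width estimation and statistics for several groups from one config and one
seed, writing `mito.csv`, `cristae.csv`, `junctions.csv`, `widths.csv`,
`tests.csv` and `report.json`; reports are byte-identical under the same
config and seed.  A thin CLI wrapper lives at `inst/cli/cristamorph`.

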