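---
title: "Methods: radial and longitudinal topology of telomeres and centromeres in sperm nuclei"
author: "spermtopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radial and longitudinal topology of telomeres and centromeres in sperm nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Sperm nuclei are small, protamine-compacted ellipsoids. FISH signals for
telomeres, centromeres, nucleolar organizing regions (NORs) and individual
centromeres (1, 5, 19) are imaged in deconvolved 3D widefield stacks
(0.2 µm optical sections) together with a DAPI counterstain, or in single
2D epifluorescence frames. The questions this package answers are
positional: where does each locus sit relative to the nuclear border
(*radial* organization), where along the tail-to-head axis (*longitudinal*
organization), how do loci aggregate into clusters and chromocenters, and
do specific loci join the same chromocenter more often than chance?

Because the underlying microscopy data are not deposited anywhere, every
stage is driven by a synthetic image generator whose defaults encode the
study conditions; all quantitative claims of this package are claims about
recovering what the generator planted, not about new biology.

## The pipeline

1. **Segmentation** (`segment_nucleus`): the DAPI stack is Gaussian-smoothed
   (default σ = 0.15 µm), thresholded (Otsu on the smoothed histogram by
   default; a fixed threshold reproduces manual intervention), reduced to
   its largest connected component, and hole-filled. Volume = voxel count ×
   voxel volume.
2. **Landmarks** (`measure_axes`): the tail attachment point is supplied
   per cell (in simulation it is ground-truth metadata; automatic tail
   detection is out of scope since tails are identified visually). The head
   apex is the surface point farthest from the tail; `L` is that distance
   and `D` the maximum caliper extent of the surface in the plane
   orthogonal to the tail-to-head axis — the widest "radial" diameter at
   90° to the tail.
3. **Detection** (`detect_signals`): each FISH channel is masked to the
   nucleus, lightly smoothed (σ = 0.1 µm), and connected components above
   the rendering threshold (default 60 intensity units, ≥ 2 voxels) become
   *rendered* signals with intensity-weighted centroids. Components holding
   several intensity maxima at least 0.4 µm apart are declumped by
   nearest-maximum assignment. Local maxima above a lower *presence*
   threshold (default 12) that belong to no rendered component are counted
   as detected-but-not-rendered: they enter longitudinal counts but cannot
   be placed radially, mirroring the study's exclusion of dim,
   tail-proximal telomeres from the distance-transform analysis.
4. **Radial topology** (`distance_map`, `assign_radial`): the exact
   anisotropic Euclidean distance transform of the nuclear mask gives each
   rendered centroid its shortest 3D distance *d* to the border
   (trilinear-interpolated at the centroid). With `R = D/2`, signals fall
   in the periphery (`d < R/3`), intermediate (`R/3 ≤ d < 2R/3`) or
   interior (`d ≥ 2R/3`). These thirds-of-the-radius regions are *not* of
   equal volume; that is why the package always reports two nulls (below).
5. **Longitudinal topology** (`assign_longitudinal`): the scalar projection
   of each centroid onto the tail→head axis, normalized by `L`, binned into
   tail / mid / head thirds. Identical code serves the 2D mode, where only
   in-plane centroids and manually measured landmarks exist.
6. **Clusters and colocalization** (`count_clusters`,
   `associate_with_chromocenters`, `null_colocalization_pmf`):
   single-linkage agglomeration at a merge radius (default 0.3 µm,
   approximately the lateral resolution limit) counts telomere clusters and
   chromocenters; probe signals associate with their nearest chromocenter
   within a proximity (default 0.5 µm). The "by chance alone" reference is
   made explicit: the exact distribution of the number of distinct
   chromocenters hit by *n* independent uniform signals over *k*
   chromocenters, `P(j) = C(k,j) S(n,j) j! / k^n`, cross-checked against
   full enumeration.
7. **Statistics** (`chisq_gof`, `monte_carlo_region_null`,
   `subject_homogeneity`, `paired_method_comparison`): Pearson χ² goodness
   of fit per target (df = 2), per subject and pooled; χ² homogeneity
   across subjects; two-tailed paired t-tests for the 3D-versus-2D
   comparison.

## The two randomness nulls

The study's "random" expectation is not stated explicitly. Its p-values are
consistent only with the *equal-thirds* null (each region expected to hold
1/3 of signals), so that is the default. Because the three radial shells
are far from equal in volume (for a sphere the closed form is 19/27, 7/27,
1/27 ≈ 0.70 / 0.26 / 0.04), the package always offers a second,
geometry-honest null: `monte_carlo_region_null` drops uniform points into
the actual segmented mask and tabulates them with the very same
distance-transform rule. Both nulls are reported side by side in every
pipeline run. No multiple-testing correction is applied by default,
matching the original analysis; `p.adjust` can be applied to the tidy
output table when desired.

## What the generator emulates

`synthetic_spec()` holds every free parameter. Defaults are the study
conditions:

* **Geometry**: axis-aligned (optionally rotated) prolate ellipsoids.
  Semi-axes (4.08, 3.00, 3.00) µm give the printed mean DTT-decondensed
  volume 153.9 µm³; (3.03, 2.23, 2.23) µm give the untreated 62.83 µm³ and
  the 2.4-fold swelling. Only volumes are printed, so the axis ratio is a
  design choice (sperm heads are ≈ 1.4:1 prolate after swelling). Voxels
  default to (0.2, 0.1, 0.1) µm (dz, dy, dx): the 0.2 µm Z step is the
  acquisition value, the lateral pitch a realistic 60×/1.4 NA CCD scale.
  The DAPI body has a logistic edge falloff (width 0.1 µm) whose
  half-maximum lies exactly on the analytic surface, so a half-height
  threshold reproduces the true surface; Gaussian read noise (σ = 5 on a
  200-amplitude nucleus) is added last. All cells in a cohort share the
  default geometry; real between-cell size variation is not modelled (the
  normalization by `D` and `L` removes it from the analysis anyway).
* **Telomeres**: 92 units per cell aggregating into dimers and tetramers.
  With sizes capped at 4, 92 units cannot form fewer than 23 clusters, so
  the observed average of ≈ 20.8 signals per cell is approached from
  above: the default mix (dimer 0.2 / tetramer 0.8 by cluster) plants
  ≈ 25.6 clusters, and optical merging at detection brings the observed
  count to the low 20s. The emulation tolerance for the observed mean is
  ± 5 clusters.
* **Placement**: telomere cluster radial fractions default to
  (0.42, 0.45, 0.13) — back-derived from the printed sensitivity argument
  (26.4% of telomeres non-rendered; if all of them were peripheral the
  totals would read 57/33/10) — and longitudinal fractions to the printed
  3D values (0.2481, 0.5042, 0.2477). Cluster positions are drawn by
  rejection sampling from the uniform distribution over the ellipsoid.
  Because the radial and longitudinal marginals are geometrically coupled
  (deep-interior points are necessarily mid-axis), the acceptance weights
  remain factorized per marginal but are balanced by iterative
  proportional fitting on the natural joint table, so both achieved
  marginals converge to their targets; the joint dependence itself is not
  a modelling target. Accepted positions are exact cluster centroids:
  member spots scatter within a 0.15 µm jitter ball whose per-cluster mean
  is removed, so the quantity the detector measures (the cluster centroid)
  carries the planted label.
* **Chromocenters and probes**: 23 centromere units spread over 7
  chromocenters (each at least one unit). The 5 NOR and 3
  centromere-1/5/19 loci attach uniformly at random to chromocenters and
  scatter within 0.25 µm — uniform attachment makes the colocalization
  null exactly recoverable; preferential attachment is deliberately *not*
  built in, so any "more often than chance" signal in the synthetic cohort
  would be a bug, not a discovery.
* **Non-renderability**: whole telomere clusters are flagged with
  probability 0.264 and rendered at a low peak (≈ 40 against a rendering
  threshold of 60 but above the presence threshold of 12), embedded in an
  additive tail-proximal background gradient (amplitude 8, e-folding
  1.5 µm). Detection therefore genuinely fails to render them — the flag
  is an intensity mechanism, not bookkeeping — and the detector recovers
  the exclusion rate from the images.
* **PSF and noise**: isotropic Gaussian PSF σ = 0.2 µm (a realistic
  post-deconvolution width; blobs are added analytically, so no separate
  optics simulation), read noise σ = 5. Spectral bleed-through,
  illumination gradients other than the tail background, irregular nuclear
  contours and curved (hooked) tail axes are not modelled.

Passing tests on this generator demonstrate that the measurement chain is
unbiased and correctly calibrated *for data of this structure*; they
cannot validate deconvolution quality, segmentation of irregular nuclei,
or any biological claim.

## Numerical choices

* Distances are computed by the exact separable Euclidean distance
  transform with per-axis spacings ("quasi-Euclidean" in the original
  toolchain approximates this; exact is strictly better and testable).
  Distance values are voxel-centre-to-voxel-centre and sampled by
  trilinear interpolation. Calibration against the analytic sphere shell
  fractions showed that subtracting a half-voxel "surface correction"
  overcorrects (the minimum over many border voxels keeps the typical
  overshoot well under half a pitch), so no constant correction is
  applied; at 0.1 µm voxels the residual boundary bias is ≈ 0.01 µm.
  Caliper extents are likewise centre-to-centre; `L` adds half a pitch
  because the head surface voxel centre sits strictly inside the surface.
  Grids are forced to odd dimensions so the nucleus centre coincides with
  a voxel centre.
* Region bins are half-open with the interior closed above
  (`d ≥ 2R/3`); edge handling is a measure-zero choice made for
  determinism. Distances exceeding `R` are clamped to `normalized_r = 1`
  with a warning, since they indicate axis mis-measurement.
* Whether the original analysis interpolated the distance transform or
  read the centroid voxel is unstated; interpolation is used. How the
  widest diameter was measured is likewise unstated; a caliper on the
  surface point set orthogonal to the measured axis is used.
* Ties in single-linkage clustering follow `stats::hclust`; a merge radius
  of exactly 0 returns one cluster per signal by definition.
* Degenerate inputs: empty masks, multiple comparable components,
  constant images, tail points off the surface, zero-signal channels and
  empty spot tables all raise typed errors (or flagged records) rather
  than propagating nonsense; a paired t-test on identical vectors returns
  p = 1 by convention, and zero-variance nonzero differences are reported
  as a degenerate case.

## Problem sizes

The shipped analysis (`analysis/01…05`) and the heaviest test use the
study design of 10 subjects × 30 cells (300 cells, four channels in the
analysis scripts, telomere channel only in the recovery test); the
emulation check uses 10 × 10 cells, and the sphere null 10⁵ Monte-Carlo
points at 0.05 µm voxels. These sizes were chosen so the whole suite
re-runs from scratch in a few minutes on one core while keeping
Monte-Carlo standard errors well below the tolerances being asserted
(e.g. SE ≈ 0.007 on recovered fractions against a ± 0.03 band).

## Known limitations

* The 2D arm re-analyzes projections of the *same* synthetic cells rather
  than simulating an independent 2D acquisition, so paired 3D-versus-2D
  tests on fractions have unrealistically small within-pair variance:
  tiny projection-induced shifts can reach significance at n = 10 even
  though the fractions differ by < 0.015. The study's conclusion of "no
  difference" concerns independent acquisitions; the emulation's
  signal-count comparison (2D undercounts because overlapping signals
  fuse) is the robust part.
* Non-renderability is independent of position by default. The study
  describes a tail-proximity correlation for dim telomeres; the additive
  tail background exists in the images, but the dim flag itself is
  spatially unbiased so that longitudinal recovery stays interpretable.
* With 3 loci per cell, per-subject χ² tests for the centromere-1/5/19
  channel are underpowered at 30 cells per subject; the shipped analysis
  reports 6/10 subjects rejecting, pooled tests rejecting throughout.
* The generator plants no joint radial × longitudinal dependence beyond
  what the ellipsoid geometry forces.
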