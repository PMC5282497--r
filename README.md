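# spermtopo

Radial and longitudinal organization of telomeres, centromeres, NORs and
chromocenters in human sperm nuclei, re-implemented as a tested R pipeline.

Sperm heads are compact ellipsoids whose chromatin layout has been argued to
follow a "hairpin-loop" model: one interior chromocenter with all telomeres
at the extreme periphery. Testing that model requires measuring, for every
FISH-labelled locus in a 3D DAPI-stained nucleus, (i) its shortest distance
*d* to the nuclear border and (ii) its position *s* along the tail-to-head
axis, then asking whether the resulting region occupancies are non-random
and reproducible across subjects, and whether specific loci share
chromocenters more often than chance. This package implements that entire
measurement chain for people who analyze 3D/2D sperm-FISH images — and,
because the original microscopy data are not deposited, a synthetic image
generator that reproduces the study's conditions so every stage is
verifiable end to end.

## The measurements

For a nucleus with binary mask *M*, widest radial diameter *D* (caliper at
90° to the tail axis) and tail-to-head length *L*:

* **Radial**: *d* = EDT(*M*) sampled at the signal centroid, where EDT is
  the exact anisotropic Euclidean distance transform (µm). With
  *R* = *D*/2, a signal is peripheral if *d* < *R*/3, intermediate if
  *R*/3 ≤ *d* < 2*R*/3, interior if *d* ≥ 2*R*/3.
* **Longitudinal**: *s* = projection of the centroid on the tail→head unit
  vector; tail / mid / head thirds of *L*. Non-rendered (dim) signals are
  included here but excluded from the radial arm.
* **Randomness**: Pearson χ² goodness of fit (df = 2) against the
  equal-thirds null, plus a volume-weighted Monte-Carlo null computed by
  dropping uniform points into the actual mask (for a sphere the closed
  form is 19/27, 7/27, 1/27).
* **Clusters / colocalization**: single-linkage clustering at 0.3 µm;
  probe-to-chromocenter association within 0.5 µm; exact null for the
  number of distinct chromocenters hit by *n* uniform signals over *k*
  chromocenters, `P(j) = C(k,j) · S(n,j) · j! / k^n` (Stirling numbers,
  cross-checked by enumeration).

## Worked example

```r
library(spermtopo)
spec <- synthetic_spec()                     # study defaults
cell <- simulate_cell(spec, cell_seed = 101, channels = "pantelomere")
nucleus <- segment_nucleus(cell$images$DAPI,
                           tail_point = cell$nucleus$tail_point)
nucleus
#> <nucleus_model> volume 154.5 um^3, L = 8.17 um, D = 6.02 um
```

The segmented volume sits within 0.4% of the 153.9 µm³ the generator's
default DTT-swollen ellipsoid encodes, and the measured axis lengths match
the analytic landmarks (L = 8.16, D = 6.00 µm) to within a voxel.

```r
signals <- detect_signals(cell$images$pantelomere, nucleus)
table(signals$rendered)
#> FALSE  TRUE
#>     7    17
```

Of 24 detected telomere signals, 7 are too dim to render (the generator
plants non-renderable clusters at the study's 26.4% rate; this cell drew
29%). Rendered signals get radial positions, all detected signals get
longitudinal ones:

```r
counts <- cell_region_counts(signals, nucleus)
counts[, c("periphery", "intermediate", "interior", "tail", "mid", "head")]
#>   periphery intermediate interior tail mid head
#> 1         7            8        2    7  11    6

chisq_gof(as.numeric(counts[, c("tail", "mid", "head")]))
#> chi-squared GOF (equal_thirds): chi2 = 1.750, df = 2, p = 0.417
```

One cell has no power; pooling the default 10 × 30-cell cohort (see
`analysis/`) rejects randomness for every target (p < 10⁻¹⁶) while
between-subject homogeneity holds (p > 0.05). The exact colocalization
null for 3 centromere signals over 7 chromocenters:

```r
null_colocalization_pmf(3, 7)
#>          1          2          3
#> 0.02040816 0.36734694 0.61224490
```

## Analysis workflow

The numbered drivers under `analysis/` reproduce the study's analyses on
the synthetic cohort and write tables under `results/`:

1. `01_simulate.R` — ground-truth cohort (10 subjects × 30 cells) and
   planted-structure summary.
2. `02_image_analysis.R` — full imaging chain on all four channels;
   per-cell counts, signals, clusters, colocalization, tidy test table.
3. `03_randomness_stats.R` — pooled, per-subject and homogeneity χ² tests
   under both nulls.
4. `04_clusters_colocalization.R` — cluster-count histograms, discrete
   NOR / cen-1/5/19 signals, observed versus exact uniform null.
5. `05_method_comparison.R` — paired 3D-versus-2D comparison (projected
   re-analysis): region fractions agree to < 0.015 while 2D undercounts
   signals.

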