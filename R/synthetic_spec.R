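#' Specification of a synthetic sperm-FISH cohort
#'
#' Collects every free parameter of the synthetic-data generator. The defaults
#' encode the study conditions this package emulates: DTT-decondensed
#' ("treated") nuclei with a mean volume of 153.9 um^3 against untreated
#' nuclei at 62.83 um^3 (a 2.4-fold swelling), 92 telomere units aggregating
#' into dimers and tetramers, about 7 chromocenters per cell, telomere radial
#' placement fractions (periphery, intermediate, interior) =
#' (0.42, 0.45, 0.13) and longitudinal fractions (tail, mid, head) =
#' (0.2481, 0.5042, 0.2477), and a 26.4% rate of telomere clusters too dim to
#' be rendered as 3D objects.
#'
#' Only the printed volumes, not the semi-axes, are known; the default
#' semi-axes are chosen to reproduce those volumes for prolate ellipsoids
#' (`4/3*pi*a*b*c`). The voxel grid defaults to the acquisition geometry
#' (0.2 um optical sections, 0.1 um lateral pixels).
#'
#' @param n_subjects number of subjects in the cohort.
#' @param cells_per_subject cells imaged per subject.
#' @param semi_axes_treated,semi_axes_untreated ellipsoid semi-axes
#'   `(a, b, c)` in micrometres, `a` along the tail-to-head axis.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param radial_fractions target placement probabilities
#'   `(periphery, intermediate, interior)`; must sum to 1.
#' @param longitudinal_fractions target placement probabilities
#'   `(tail, mid, head)`; must sum to 1.
#' @param n_telomere_units telomere units per nucleus (default 92 = 2 x 2 x 23).
#' @param telomere_cluster_sizes named probability vector over cluster sizes
#'   `{1, 2, 4}` (probability that a telomere cluster is a singleton, dimer,
#'   or tetramer).
#' @param n_chromocenters chromocenters (centromere aggregates) per cell.
#' @param n_centromere_units centromere units distributed over chromocenters.
#' @param n_nor_units discrete NOR loci per (haploid) cell.
#' @param n_cen_probe_units loci carried by the centromere-1/5/19 probe.
#' @param cluster_jitter radius (um) of the uniform ball within which cluster
#'   members scatter around their cluster seed.
#' @param anchor_jitter radius (um) for probe loci scattered around the
#'   chromocenter they associate with.
#' @param psf_sigma Gaussian PSF sigma in micrometres.
#' @param noise_sd standard deviation of additive Gaussian read noise.
#' @param dapi_amplitude peak DAPI intensity of the nucleus body.
#' @param signal_amplitude peak intensity of a renderable FISH cluster.
#' @param nonrender_amplitude peak intensity of a non-renderable cluster
#'   (below the rendering threshold, above the presence threshold).
#' @param tail_background_amplitude amplitude of the tail-proximal additive
#'   background gradient.
#' @param tail_background_scale e-folding length (um) of that gradient along
#'   the tail-to-head axis.
#' @param nonrender_fraction_target probability that a telomere cluster is
#'   non-renderable.
#' @param edge_width width (um) of the smooth DAPI edge falloff; the
#'   half-maximum sits exactly on the ellipsoid surface.
#' @param seed master integer seed; all per-cell seeds derive from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 10L,
                           cells_per_subject = 30L,
                           semi_axes_treated = c(4.08, 3.00, 3.00),
                           semi_axes_untreated = c(3.03, 2.23, 2.23),
                           voxel_size = c(0.2, 0.1, 0.1),
                           radial_fractions = c(periphery = 0.42,
                                                intermediate = 0.45,
                                                interior = 0.13),
                           longitudinal_fractions = c(tail = 0.2481,
                                                      mid = 0.5042,
                                                      head = 0.2477),
                           n_telomere_units = 92L,
                           telomere_cluster_sizes = c("1" = 0, "2" = 0.2,
                                                      "4" = 0.8),
                           n_chromocenters = 7L,
                           n_centromere_units = 23L,
                           n_nor_units = 5L,
                           n_cen_probe_units = 3L,
                           cluster_jitter = 0.15,
                           anchor_jitter = 0.25,
                           psf_sigma = 0.2,
                           noise_sd = 5,
                           dapi_amplitude = 200,
                           signal_amplitude = 150,
                           nonrender_amplitude = 40,
                           tail_background_amplitude = 8,
                           tail_background_scale = 1.5,
                           nonrender_fraction_target = 0.264,
                           edge_width = 0.1,
                           seed = 1L) {
  spec <- list(
    n_subjects = as.integer(n_subjects),
    cells_per_subject = as.integer(cells_per_subject),
    semi_axes_treated = as.numeric(semi_axes_treated),
    semi_axes_untreated = as.numeric(semi_axes_untreated),
    voxel_size = as.numeric(voxel_size),
    radial_fractions = radial_fractions,
    longitudinal_fractions = longitudinal_fractions,
    n_telomere_units = as.integer(n_telomere_units),
    telomere_cluster_sizes = telomere_cluster_sizes,
    n_chromocenters = as.integer(n_chromocenters),
    n_centromere_units = as.integer(n_centromere_units),
    n_nor_units = as.integer(n_nor_units),
    n_cen_probe_units = as.integer(n_cen_probe_units),
    cluster_jitter = cluster_jitter,
    anchor_jitter = anchor_jitter,
    psf_sigma = psf_sigma,
    noise_sd = noise_sd,
    dapi_amplitude = dapi_amplitude,
    signal_amplitude = signal_amplitude,
    nonrender_amplitude = nonrender_amplitude,
    tail_background_amplitude = tail_background_amplitude,
    tail_background_scale = tail_background_scale,
    nonrender_fraction_target = nonrender_fraction_target,
    edge_width = edge_width,
    seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  stopifnot(is.list(spec))
  counts <- c(spec$n_subjects, spec$cells_per_subject, spec$n_telomere_units,
              spec$n_chromocenters, spec$n_centromere_units, spec$n_nor_units,
              spec$n_cen_probe_units)
  if (any(counts <= 0L)) stop("all counts must be > 0")
  if (any(spec$semi_axes_treated <= 0) || any(spec$semi_axes_untreated <= 0))
    stop("semi-axes must be > 0")
  if (any(spec$voxel_size <= 0)) stop("voxel sizes must be > 0")
  if (abs(sum(spec$radial_fractions) - 1) > 1e-9)
    stop("radial_fractions must sum to 1")
  if (abs(sum(spec$longitudinal_fractions) - 1) > 1e-9)
    stop("longitudinal_fractions must sum to 1")
  if (any(spec$radial_fractions < 0) || any(spec$longitudinal_fractions < 0))
    stop("placement fractions must be non-negative")
  if (abs(sum(spec$telomere_cluster_sizes) - 1) > 1e-9)
    stop("telomere_cluster_sizes must sum to 1")
  if (!all(names(spec$telomere_cluster_sizes) %in% c("1", "2", "4")))
    stop("telomere cluster sizes must be among {1, 2, 4}")
  if (spec$nonrender_fraction_target < 0 || spec$nonrender_fraction_target > 1)
    stop("nonrender_fraction_target must be a probability")
  if (spec$psf_sigma <= 0) stop("psf_sigma must be > 0")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  invisible(spec)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %d subjects x %d cells\n",
              x$n_subjects, x$cells_per_subject))
  cat(sprintf("  treated semi-axes (%.2f, %.2f, %.2f) um -> V = %.1f um^3\n",
              x$semi_axes_treated[1], x$semi_axes_treated[2],
              x$semi_axes_treated[3], ellipsoid_volume(x$semi_axes_treated)))
  cat(sprintf("  untreated semi-axes (%.2f, %.2f, %.2f) um -> V = %.1f um^3\n",
              x$semi_axes_untreated[1], x$semi_axes_untreated[2],
              x$semi_axes_untreated[3],
              ellipsoid_volume(x$semi_axes_untreated)))
  cat(sprintf("  radial targets (%.3f, %.3f, %.3f); longitudinal (%.3f, %.3f, %.3f)\n",
              x$radial_fractions[1], x$radial_fractions[2],
              x$radial_fractions[3], x$longitudinal_fractions[1],
              x$longitudinal_fractions[2], x$longitudinal_fractions[3]))
  invisible(x)
}

#' Analytic ellipsoid volume
#' @param semi_axes `(a, b, c)` in micrometres.
#' @return Volume in cubic micrometres, `4/3 * pi * a * b * c`.
#' @export
ellipsoid_volume <- function(semi_axes) 4 / 3 * pi * prod(semi_axes)
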