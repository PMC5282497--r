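# ground-truth spot sampling and rendering for the synthetic generator

# uniform point in a ball of given radius
runif_ball <- function(n, radius) {
  g <- matrix(rnorm(3 * n), n, 3)
  g <- g / sqrt(rowSums(g^2))
  g * radius * runif(n)^(1 / 3)
}

# is a physical (x,y,z) point strictly inside the analytic ellipsoid?
inside_ellipsoid <- function(points, nucleus) {
  body <- sweep(points, 2, nucleus$center, "-") %*% rot_z(nucleus$rotation)
  rowSums(sweep(body, 2, nucleus$semi_axes, "/")^2) < 1
}

# region labels of points, via the same distance map / axis rule the
# analysis modules use (label/assigner consistency by construction)
true_regions <- function(points, nucleus) {
  dmap <- distance_map(nucleus)
  d <- sample_distance(dmap, points)
  rad <- .radial_bin(d, nucleus$widest_diameter_D / 2)
  u <- (nucleus$head_point - nucleus$tail_point) / nucleus$length_L
  s <- as.numeric(sweep(points, 2, nucleus$tail_point, "-") %*% u)
  lng <- .longitudinal_bin(pmin(pmax(s / nucleus$length_L, 0), 1))
  list(radial = rad, longitudinal = lng)
}

# Rejection-sample n seed positions whose radial and longitudinal marginal
# region distributions hit the targets. Proposals are uniform in the
# ellipsoid; each proposal is accepted with probability proportional to
# (target/natural) on each marginal independently.
sample_target_positions <- function(n, nucleus, radial_fractions,
                                    longitudinal_fractions,
                                    n_natural = 4000L, max_batches = 200L) {
  nat_pts <- uniform_in_ellipsoid(n_natural, nucleus)
  nat <- true_regions(nat_pts, nucleus)
  nat_rad <- prop.table(table(factor(nat$radial, levels = RADIAL_REGIONS)))
  nat_lng <- prop.table(table(factor(nat$longitudinal,
                                     levels = LONGITUDINAL_REGIONS)))
  tr <- as.numeric(radial_fractions); tl <- as.numeric(longitudinal_fractions)
  if (any(tr > 0 & as.numeric(nat_rad) == 0) ||
      any(tl > 0 & as.numeric(nat_lng) == 0))
    stop(sprintf(
      "unattainable placement targets: natural radial fractions (%s), longitudinal (%s)",
      paste(sprintf("%.3f", nat_rad), collapse = ", "),
      paste(sprintf("%.3f", nat_lng), collapse = ", ")))
  # The two marginals are geometrically coupled (deep-interior points are
  # necessarily mid-axis), so raw target/natural ratios on each marginal
  # would distort the other. Keep the weights factorized (one per marginal)
  # but balance them on the natural joint table by iterative proportional
  # fitting so both achieved marginals converge to their targets.
  J <- prop.table(table(factor(nat$radial, levels = RADIAL_REGIONS),
                        factor(nat$longitudinal,
                               levels = LONGITUDINAL_REGIONS)))
  wr <- rep(1, 3); wl <- rep(1, 3)
  for (it in seq_len(200)) {
    mr <- as.numeric((J * outer(wr, wl)) %*% rep(1, 3))
    wr <- ifelse(mr > 0, wr * tr / mr, 0)
    ml <- as.numeric(rep(1, 3) %*% (J * outer(wr, wl)))
    wl <- ifelse(ml > 0, wl * tl / ml, 0)
    if (max(abs(mr - tr)) + max(abs(ml - tl)) < 1e-10) break
  }
  sc <- max(outer(wr, wl)[J > 0])
  if (!is.finite(sc) || sc <= 0)
    stop(sprintf(
      "unattainable placement targets (joint support empty): natural radial fractions (%s), longitudinal (%s)",
      paste(sprintf("%.3f", nat_rad), collapse = ", "),
      paste(sprintf("%.3f", nat_lng), collapse = ", ")))
  wr <- wr / sc^(1 / 2); wl <- wl / sc^(1 / 2)
  wr <- pmin(wr, 1e6); wl <- pmin(wl, 1e6)

  out <- matrix(numeric(0), 0, 3)
  rad_lab <- character(0); lng_lab <- character(0)
  batch <- max(2L * n, 500L)
  proposed <- 0L; accepted <- 0L
  for (b in seq_len(max_batches)) {
    pts <- uniform_in_ellipsoid(batch, nucleus)
    reg <- true_regions(pts, nucleus)
    ir <- match(reg$radial, RADIAL_REGIONS)
    il <- match(reg$longitudinal, LONGITUDINAL_REGIONS)
    keep <- runif(batch) < wr[ir] * wl[il]
    proposed <- proposed + batch; accepted <- accepted + sum(keep)
    out <- rbind(out, pts[keep, , drop = FALSE])
    rad_lab <- c(rad_lab, reg$radial[keep])
    lng_lab <- c(lng_lab, reg$longitudinal[keep])
    if (nrow(out) >= n) break
    if (b >= 10L && accepted / proposed < 0.005) {
      ach_r <- prop.table(table(factor(rad_lab, levels = RADIAL_REGIONS)))
      ach_l <- prop.table(table(factor(lng_lab,
                                       levels = LONGITUDINAL_REGIONS)))
      stop(sprintf(
        "placement acceptance rate below floor (%.4f); achieved radial fractions (%s), longitudinal (%s)",
        accepted / proposed,
        paste(sprintf("%.3f", ach_r), collapse = ", "),
        paste(sprintf("%.3f", ach_l), collapse = ", ")))
    }
  }
  if (nrow(out) < n)
    stop("could not place the requested number of spots (acceptance too low)")
  list(points = out[seq_len(n), , drop = FALSE],
       radial = rad_lab[seq_len(n)], longitudinal = lng_lab[seq_len(n)])
}

# Scatter cluster members around accepted positions. Jitters are centred
# per cluster so the accepted position is exactly the cluster centroid --
# the quantity the detector later measures -- keeping the placed region
# fractions faithful to the rejection targets. Members falling outside the
# ellipsoid are resampled (the centring then becomes approximate).
scatter_members <- function(seeds, sizes, jitter, nucleus) {
  idx <- rep(seq_along(sizes), sizes)
  off <- runif_ball(length(idx), jitter)
  off <- off - apply(off, 2, function(v) ave(v, idx))
  pts <- seeds[idx, , drop = FALSE] + off
  bad <- which(!inside_ellipsoid(pts, nucleus))
  tries <- 0L
  while (length(bad) > 0 && tries < 100L) {
    pts[bad, ] <- seeds[idx[bad], , drop = FALSE] +
      runif_ball(length(bad), jitter)
    bad <- bad[!inside_ellipsoid(pts[bad, , drop = FALSE], nucleus)]
    tries <- tries + 1L
  }
  if (length(bad) > 0) pts[bad, ] <- seeds[idx[bad], , drop = FALSE]
  list(points = pts, cluster_id = idx)
}

# telomere cluster sizes summing exactly to n_units
draw_telomere_sizes <- function(n_units, size_probs) {
  sizes_avail <- as.integer(names(size_probs))
  sizes <- integer(0)
  while (sum(sizes) < n_units) {
    k <- sample(sizes_avail, 1, prob = size_probs)
    sizes <- c(sizes, k)
  }
  excess <- sum(sizes) - n_units
  if (excess > 0) sizes[length(sizes)] <- sizes[length(sizes)] - excess
  sizes[sizes > 0]
}

#' Sample ground-truth FISH spot positions
#'
#' Places spots for one channel inside the nucleus by rejection sampling so
#' the empirical radial-region and longitudinal-region marginal fractions
#' converge to the spec's targets. Cluster structure is imposed by placing
#' cluster seeds first and scattering members within `cluster_jitter`;
#' telomere clusters draw their sizes from the spec's dimer/tetramer mix,
#' centromere units spread over `n_chromocenters` chromocenters (each at
#' least one unit), and NOR / centromere-1/5/19 probe loci attach uniformly
#' at random to supplied chromocenter anchors. Each spot carries the true
#' region labels recomputed through the same distance-transform/axis rules
#' the analysis uses. Telomere clusters are flagged non-renderable with
#' probability `nonrender_fraction_target`.
#'
#' @param nucleus a [nucleus_model] from [make_nucleus()].
#' @param spec a [synthetic_spec].
#' @param channel one of `"pantelomere"`, `"pancentromere"`, `"NOR"`,
#'   `"cen_1_5_19"`.
#' @param seed optional integer seed.
#' @param anchors matrix of chromocenter seed positions, required for the
#'   probe channels (`"NOR"`, `"cen_1_5_19"`); the `"pancentromere"` result
#'   carries its seeds as `attr(, "seeds")`.
#' @return A data.frame of ground-truth spots: `channel`, `x`, `y`, `z`,
#'   `cluster_id`, `anchor_id`, `true_radial_region`,
#'   `true_longitudinal_region`, `renderable`.
#' @export
sample_spot_positions <- function(nucleus, spec, channel = "pantelomere",
                                  seed = NULL, anchors = NULL) {
  channel <- match.arg(channel, FISH_CHANNELS)
  if (!is.null(seed)) set.seed(seed)
  validate_synthetic_spec(spec)
  seeds_attr <- NULL

  if (channel %in% c("pantelomere", "pancentromere")) {
    if (channel == "pantelomere") {
      sizes <- draw_telomere_sizes(spec$n_telomere_units,
                                   spec$telomere_cluster_sizes)
    } else {
      k <- spec$n_chromocenters
      extra <- spec$n_centromere_units - k
      if (extra < 0) stop("n_centromere_units must be >= n_chromocenters")
      sizes <- rep(1L, k) +
        as.integer(rmultinom(1, extra, rep(1 / k, k)))
    }
    sp <- sample_target_positions(length(sizes), nucleus,
                                  spec$radial_fractions,
                                  spec$longitudinal_fractions)
    mem <- scatter_members(sp$points, sizes, spec$cluster_jitter, nucleus)
    pts <- mem$points
    cluster_id <- mem$cluster_id
    anchor_id <- rep(NA_integer_, nrow(pts))
    if (channel == "pantelomere") {
      rend_cluster <- runif(length(sizes)) >= spec$nonrender_fraction_target
      renderable <- rend_cluster[cluster_id]
    } else {
      renderable <- rep(TRUE, nrow(pts))
      seeds_attr <- sp$points
    }
  } else {
    if (is.null(anchors))
      stop(sprintf("channel %s requires chromocenter `anchors`", channel))
    n_units <- if (channel == "NOR") spec$n_nor_units else
      spec$n_cen_probe_units
    anchor_id <- sample.int(nrow(anchors), n_units, replace = TRUE)
    pts <- anchors[anchor_id, , drop = FALSE] +
      runif_ball(n_units, spec$anchor_jitter)
    bad <- which(!inside_ellipsoid(pts, nucleus))
    tries <- 0L
    while (length(bad) > 0 && tries < 100L) {
      pts[bad, ] <- anchors[anchor_id[bad], , drop = FALSE] +
        runif_ball(length(bad), spec$anchor_jitter)
      bad <- bad[!inside_ellipsoid(pts[bad, , drop = FALSE], nucleus)]
      tries <- tries + 1L
    }
    if (length(bad) > 0) pts[bad, ] <- anchors[anchor_id[bad], , drop = FALSE]
    cluster_id <- seq_len(n_units)
    renderable <- rep(TRUE, n_units)
  }

  reg <- true_regions(pts, nucleus)
  out <- data.frame(
    channel = channel,
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    cluster_id = cluster_id,
    anchor_id = anchor_id,
    true_radial_region = reg$radial,
    true_longitudinal_region = reg$longitudinal,
    renderable = renderable)
  if (!is.null(seeds_attr)) attr(out, "seeds") <- seeds_attr
  out
}

#' Render FISH spots into a voxel image
#'
#' Adds a Gaussian PSF blob for every spot. Renderable clusters receive a
#' cluster peak near `signal_amplitude`; non-renderable clusters a peak near
#' `nonrender_amplitude`, below the rendering threshold but above the
#' presence threshold, so detection genuinely fails to render them (the blob
#' amplitude is split over cluster members). An additive tail-proximal
#' background gradient emulates the higher background fluorescence near the
#' sperm tail, and Gaussian read noise is added last.
#'
#' @param image a [voxel_image] to add onto, or `NULL` to start from a zero
#'   grid matching the nucleus mask.
#' @param spots data.frame from [sample_spot_positions()].
#' @param spec a [synthetic_spec].
#' @param nucleus the [nucleus_model] (for grid shape and the tail axis).
#' @return A [voxel_image] of the rendered channel.
#' @export
render_spots <- function(image = NULL, spots, spec, nucleus) {
  vs <- spec$voxel_size
  if (is.null(image)) {
    arr <- array(0, dim(nucleus$mask))
  } else {
    arr <- image$intensities
    vs <- image$voxel_size
  }
  dim3 <- dim(arr)
  if (spec$psf_sigma < max(vs) / 2)
    warning("psf_sigma is smaller than half a voxel: the PSF is undersampled")
  cz <- axis_centers(dim3, vs)

  if (nrow(spots) > 0) {
    if (any(spots$x < 0 | spots$x > dim3[3] * vs[3] |
            spots$y < 0 | spots$y > dim3[2] * vs[2] |
            spots$z < 0 | spots$z > dim3[1] * vs[1]))
      stop("spot positions must lie inside the image grid")
    csize <- table(spots$cluster_id)
    rad <- 4 * spec$psf_sigma
    for (i in seq_len(nrow(spots))) {
      peak <- if (spots$renderable[i]) spec$signal_amplitude else
        spec$nonrender_amplitude
      amp <- peak / as.numeric(csize[as.character(spots$cluster_id[i])])
      zr <- which(abs(cz$z - spots$z[i]) <= rad)
      yr <- which(abs(cz$y - spots$y[i]) <= rad)
      xr <- which(abs(cz$x - spots$x[i]) <= rad)
      if (!length(zr) || !length(yr) || !length(xr)) next
      gz <- exp(-0.5 * ((cz$z[zr] - spots$z[i]) / spec$psf_sigma)^2)
      gy <- exp(-0.5 * ((cz$y[yr] - spots$y[i]) / spec$psf_sigma)^2)
      gx <- exp(-0.5 * ((cz$x[xr] - spots$x[i]) / spec$psf_sigma)^2)
      arr[zr, yr, xr] <- arr[zr, yr, xr] +
        amp * outer(outer(gz, gy), gx)
    }
  }

  if (spec$tail_background_amplitude > 0 && !is.null(nucleus$tail_point)) {
    u <- (nucleus$head_point - nucleus$tail_point) / nucleus$length_L
    tz <- u[3] * (cz$z - nucleus$tail_point[3])
    ty <- u[2] * (cz$y - nucleus$tail_point[2])
    tx <- u[1] * (cz$x - nucleus$tail_point[1])
    s <- outer(outer(tz, ty, "+"), tx, "+")
    arr <- arr + spec$tail_background_amplitude *
      exp(-pmax(s, 0) / spec$tail_background_scale)
  }

  if (spec$noise_sd > 0) {
    arr <- arr + rnorm(length(arr), sd = spec$noise_sd)
    arr[arr < 0] <- 0
    dim(arr) <- dim3
  }
  voxel_image(arr, vs, spots$channel[1] %||% "FISH")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a
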