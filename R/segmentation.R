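# nucleus segmentation, signal detection and axis measurement

#' Segment the nucleus from the DAPI channel
#'
#' Reproduces the iso-surface chain: Gaussian smoothing, intensity
#' threshold (Otsu on the smoothed histogram by default, or a fixed value),
#' retention of the largest connected component, and hole filling. The
#' volume is the voxel count times the voxel volume. When a tail attachment
#' point is supplied, the tail-to-head axis and widest radial diameter are
#' measured with [measure_axes()] and attached as landmarks.
#'
#' @param dapi a [voxel_image] of the DAPI channel.
#' @param gaussian_sigma smoothing sigma in micrometres.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param threshold_value intensity threshold when `threshold_method =
#'   "fixed"`.
#' @param tail_point optional physical `(x, y, z)` tail attachment landmark.
#' @return A [nucleus_model].
#' @export
segment_nucleus <- function(dapi, gaussian_sigma = 0.15,
                            threshold_method = c("otsu", "fixed"),
                            threshold_value = NULL, tail_point = NULL) {
  stopifnot(inherits(dapi, "voxel_image"), gaussian_sigma >= 0)
  threshold_method <- match.arg(threshold_method)
  arr <- dapi$intensities
  vs <- dapi$voxel_size
  if (gaussian_sigma > 0)
    arr <- .blur3d(arr, dim(arr), gaussian_sigma / vs)
  thr <- switch(threshold_method,
                otsu = otsu_threshold(as.numeric(arr)),
                fixed = {
                  if (is.null(threshold_value))
                    stop("threshold_value required for fixed thresholding")
                  threshold_value
                })
  bw <- arr >= thr
  if (!any(bw)) stop("empty mask: no voxels above the threshold")
  lab <- .label3d(bw, dim(bw), 6L)
  sizes <- tabulate(lab[lab > 0L])
  ord <- order(sizes, decreasing = TRUE)
  if (length(sizes) > 1L && sizes[ord[2]] >= 0.25 * sizes[ord[1]])
    stop(sprintf("multiple comparable components after threshold (sizes: %s)",
                 paste(sort(sizes, decreasing = TRUE), collapse = ", ")))
  mask <- lab == ord[1]
  mask <- fill_holes3d(mask)
  nm <- nucleus_model(mask, vs, volume = sum(mask) * prod(vs))
  nm$threshold <- thr
  if (!is.null(tail_point)) {
    ax <- measure_axes(mask, vs, tail_point)
    nm$tail_point <- tail_point
    nm$head_point <- ax$head_point
    nm$length_L <- ax$length_L
    nm$widest_diameter_D <- ax$widest_diameter_D
  }
  nm
}

# Relabel components that contain several well-separated local intensity
# maxima: voxels are reassigned to the nearest maximum (physical distance).
# Maxima are found within each component and greedily thinned so that kept
# maxima are at least `min_sep` apart (brightest first).
split_components <- function(arr, lab, vs, min_sep) {
  d3 <- dim(arr)
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0) return(lab)
  next_id <- max(ids)
  for (id in ids) {
    idx <- which(lab == id)
    if (length(idx) < 4L) next
    ai <- arrayInd(idx, d3)
    vals <- arr[idx]
    is_max <- vapply(seq_along(idx), function(i) {
      zr <- max(ai[i, 1] - 1, 1):min(ai[i, 1] + 1, d3[1])
      yr <- max(ai[i, 2] - 1, 1):min(ai[i, 2] + 1, d3[2])
      xr <- max(ai[i, 3] - 1, 1):min(ai[i, 3] + 1, d3[3])
      vals[i] >= max(arr[zr, yr, xr])
    }, logical(1))
    mx <- which(is_max)
    if (length(mx) <= 1) next
    pos <- cbind((ai[mx, 3] - 0.5) * vs[3], (ai[mx, 2] - 0.5) * vs[2],
                 (ai[mx, 1] - 0.5) * vs[1])
    ord <- mx[order(vals[mx], decreasing = TRUE)]
    pos <- pos[order(vals[mx], decreasing = TRUE), , drop = FALSE]
    keep <- 1L
    for (j in seq_along(ord)[-1]) {
      dj <- sqrt(colSums((t(pos[keep, , drop = FALSE]) - pos[j, ])^2))
      if (min(dj) >= min_sep) keep <- c(keep, j)
    }
    if (length(keep) <= 1) next
    kp <- pos[keep, , drop = FALSE]
    vox_pos <- cbind((ai[, 3] - 0.5) * vs[3], (ai[, 2] - 0.5) * vs[2],
                     (ai[, 1] - 0.5) * vs[1])
    nearest <- max.col(-vapply(seq_len(nrow(kp)), function(k)
      rowSums(sweep(vox_pos, 2, kp[k, ])^2), numeric(nrow(vox_pos))))
    # first part keeps the original id, the rest get fresh labels
    for (k in seq_len(nrow(kp))[-1]) {
      next_id <- next_id + 1L
      lab[idx[nearest == k]] <- next_id
    }
  }
  lab
}

# physical (x,y,z) coordinates of surface voxels (foreground voxels with a
# 6-neighbour in the background or on the array border)
surface_points <- function(mask, voxel_size) {
  d <- dim(mask)
  # a voxel is interior iff all six face neighbours are foreground
  pad <- function(along, side) {
    m <- array(FALSE, d)
    if (along == 1) {
      if (side > 0) m[-d[1], , ] <- mask[-1, , ] else m[-1, , ] <- mask[-d[1], , ]
    } else if (along == 2) {
      if (side > 0) m[, -d[2], ] <- mask[, -1, ] else m[, -1, ] <- mask[, -d[2], ]
    } else {
      if (side > 0) m[, , -d[3]] <- mask[, , -1] else m[, , -1] <- mask[, , -d[3]]
    }
    m
  }
  nb_all <- pad(1, 1) & pad(1, -1) & pad(2, 1) & pad(2, -1) &
    pad(3, 1) & pad(3, -1)
  surf <- mask & !nb_all
  idx <- which(surf)
  ai <- arrayInd(idx, d)
  cbind(x = (ai[, 3] - 0.5) * voxel_size[3],
        y = (ai[, 2] - 0.5) * voxel_size[2],
        z = (ai[, 1] - 0.5) * voxel_size[1])
}

#' Measure the tail-to-head axis and the widest radial diameter
#'
#' The head apex is the mask surface point farthest from the tail attachment
#' point; `L` is that distance and the axis the tail-to-head unit vector.
#' `D` is the maximum caliper extent of the mask surface measured in the
#' plane orthogonal to the axis (the widest "radial" diameter at 90 degrees
#' to the tail), between voxel centres; `L` adds half a voxel pitch for the
#' head voxel centre sitting just inside the surface.
#'
#' @param mask logical 3D array.
#' @param voxel_size `(dz, dy, dx)` micrometres.
#' @param tail_point physical `(x, y, z)` of the tail attachment; errors if
#'   farther than two voxels from the mask surface.
#' @return `list(head_point, length_L, widest_diameter_D)`.
#' @export
measure_axes <- function(mask, voxel_size, tail_point) {
  sp <- surface_points(mask, voxel_size)
  if (nrow(sp) == 0) stop("mask has no surface voxels")
  h <- mean(voxel_size)
  dt <- sqrt(colSums((t(sp) - tail_point)^2))
  if (min(dt) > 2 * max(voxel_size))
    stop(sprintf("tail_point is %.3g um from the mask surface (> 2 voxels)",
                 min(dt)))
  ih <- which.max(dt)
  head_point <- as.numeric(sp[ih, ])
  L <- dt[ih] + h / 2  # head surface voxel centre sits ~half a voxel inside
  u <- (head_point - tail_point) / sqrt(sum((head_point - tail_point)^2))
  # orthonormal basis of the plane orthogonal to u
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  q <- cbind(sp %*% e1, sp %*% e2)
  hull <- grDevices::chull(q)
  qh <- q[hull, , drop = FALSE]
  D <- max(as.numeric(dist(qh)))
  list(head_point = head_point, length_L = as.numeric(L),
       widest_diameter_D = as.numeric(D))
}

#' Detect FISH signals within the nucleus
#'
#' Masks the FISH channel to the nucleus, lightly
#' smooths it, and finds connected components. Components reaching
#' `detect_threshold` with at least `min_voxels` voxels become *rendered*
#' signals with intensity-weighted centroids. Local intensity maxima that
#' exceed the lower `presence_threshold` but sit outside every
#' rendering-threshold component are counted as detected-but-not-rendered:
#' they enter longitudinal counts but are excluded from radial
#' distance-transform analysis, mirroring the handling of telomeres too dim
#' to render. Touching components whose intensity maxima are separated by at
#' least `split_min_sep` are declumped by nearest-maximum assignment;
#' closer spots genuinely merge into one signal, mirroring the way
#' iso-surface objects fuse when clusters overlap.
#'
#' @param fish a [voxel_image] of one FISH channel, registered with the mask.
#' @param nucleus a [nucleus_model].
#' @param detect_threshold intensity threshold for rendering.
#' @param min_voxels minimum component size in voxels.
#' @param presence_threshold lower threshold for counting a signal at all.
#' @param smooth_sigma pre-detection smoothing sigma (um).
#' @param split_min_sep minimum separation (um) between intensity maxima for
#'   a touching component to be split into distinct signals; spots whose
#'   peaks are closer than this genuinely merge.
#' @param background_sigma scale (um) of the local background subtracted
#'   before the presence-maxima search (band-pass detection of dim spots).
#' @return A data.frame of signals (`channel`, `x`, `y`, `z`, `voxels`,
#'   `peak`, `rendered`) with attribute `n_nonrendered`.
#' @export
detect_signals <- function(fish, nucleus, detect_threshold = 60,
                           min_voxels = 2L, presence_threshold = 12,
                           smooth_sigma = 0.1, split_min_sep = 0.4,
                           background_sigma = 0.5) {
  stopifnot(inherits(fish, "voxel_image"), inherits(nucleus, "nucleus_model"))
  vs <- fish$voxel_size
  arr <- fish$intensities
  arr[!nucleus$mask] <- 0
  if (smooth_sigma > 0) arr <- .blur3d(arr, dim(arr), smooth_sigma / vs)
  bg <- stats::median(arr[nucleus$mask])
  if (detect_threshold <= bg)
    warning(sprintf("detect_threshold (%.3g) is at or below the background level (%.3g)",
                    detect_threshold, bg))

  comp_stats <- function(lab) {
    idx <- which(lab > 0L)
    if (!length(idx)) return(NULL)
    li <- lab[idx]
    w <- arr[idx]
    ai <- arrayInd(idx, dim(arr))
    sw <- rowsum(w, li)
    ids <- as.integer(rownames(sw))
    fli <- factor(li, levels = ids)
    data.frame(
      id = ids,
      x = rowsum(w * (ai[, 3] - 0.5) * vs[3], li)[, 1] / sw[, 1],
      y = rowsum(w * (ai[, 2] - 0.5) * vs[2], li)[, 1] / sw[, 1],
      z = rowsum(w * (ai[, 1] - 0.5) * vs[1], li)[, 1] / sw[, 1],
      voxels = as.integer(tabulate(li)[ids]),
      peak = vapply(split(w, fli), max, numeric(1)))
  }

  labd <- .label3d(arr >= detect_threshold, dim(arr), 26L)
  # declump: components holding several well-separated intensity maxima are
  # split by nearest-maximum assignment, so touching spots whose peaks are
  # resolved do not collapse into one signal
  labd <- split_components(arr, labd, vs, min_sep = split_min_sep)
  std <- comp_stats(labd)

  rendered <- NULL
  if (!is.null(std)) {
    std <- std[std$voxels >= min_voxels, , drop = FALSE]
    if (nrow(std) > 0) rendered <- std
  }
  # detected-but-not-rendered: local maxima above the presence threshold
  # that fall outside every component at the rendering threshold. The
  # search runs on a band-passed image (local background of scale
  # `background_sigma` subtracted) so dim spots on the flanks of bright
  # ones keep their own maximum instead of drowning in the slope.
  nonrend <- NULL
  res <- arr - .blur3d(arr, dim(arr), background_sigma / vs)
  cand <- which(res >= presence_threshold & labd == 0L)
  if (length(cand) > 0) {
    d3 <- dim(arr)
    ai <- arrayInd(cand, d3)
    inner <- ai[, 1] > 1 & ai[, 1] < d3[1] & ai[, 2] > 1 & ai[, 2] < d3[2] &
      ai[, 3] > 1 & ai[, 3] < d3[3]
    cand <- cand[inner]; ai <- ai[inner, , drop = FALSE]
    is_max <- vapply(seq_along(cand), function(i) {
      nb <- res[(ai[i, 1] - 1):(ai[i, 1] + 1),
                (ai[i, 2] - 1):(ai[i, 2] + 1),
                (ai[i, 3] - 1):(ai[i, 3] + 1)]
      res[cand[i]] >= max(nb)
    }, logical(1))
    if (any(is_max)) {
      mi <- ai[is_max, , drop = FALSE]
      pts <- cbind(x = (mi[, 3] - 0.5) * vs[3], y = (mi[, 2] - 0.5) * vs[2],
                   z = (mi[, 1] - 0.5) * vs[1])
      # collapse maxima of the same blob (plateaus, shoulders)
      cl <- count_clusters(pts, merge_radius = 2 * max(vs))
      nonrend <- data.frame(id = NA_integer_,
                            x = cl$clusters$x, y = cl$clusters$y,
                            z = cl$clusters$z,
                            voxels = cl$clusters$size,
                            peak = vapply(split(arr[cand][is_max],
                                                cl$assignment), max,
                                          numeric(1)))
    }
  }
  mk_df <- function(st, rend) {
    if (is.null(st) || nrow(st) == 0) return(NULL)
    data.frame(channel = fish$channel, x = st$x, y = st$y, z = st$z,
               voxels = st$voxels, peak = st$peak, rendered = rend)
  }
  out <- rbind(mk_df(rendered, TRUE), mk_df(nonrend, FALSE))
  if (is.null(out))
    out <- data.frame(channel = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), voxels = integer(0), peak = numeric(0),
                      rendered = logical(0))
  rownames(out) <- NULL
  attr(out, "n_nonrendered") <- sum(!out$rendered)
  out
}
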