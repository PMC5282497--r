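#' Nucleus model
#'
#' Binary nuclear mask plus landmarks: the tail attachment point, the head
#' apex, the tail-to-head length `L`, the widest radial diameter `D`
#' (measured at 90 degrees to the tail-to-head axis) and the volume.
#' Synthetic nuclei additionally carry their analytic ellipsoid parameters.
#'
#' @param mask logical 3D array `(Z, Y, X)`.
#' @param voxel_size `(dz, dy, dx)` micrometres.
#' @param tail_point,head_point physical `(x, y, z)` positions in micrometres.
#' @param length_L tail-to-head length (um).
#' @param widest_diameter_D widest caliper extent orthogonal to the axis (um).
#' @param volume nuclear volume (um^3).
#' @param semi_axes,center,rotation analytic ellipsoid parameters for
#'   synthetic nuclei (optional; `rotation` is the angle about the z axis).
#' @return An object of class `nucleus_model`.
#' @export
nucleus_model <- function(mask, voxel_size, tail_point = NULL,
                          head_point = NULL, length_L = NULL,
                          widest_diameter_D = NULL, volume = NULL,
                          semi_axes = NULL, center = NULL, rotation = 0) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (is.null(volume)) volume <- sum(mask) * prod(voxel_size)
  nm <- structure(
    list(mask = mask, voxel_size = as.numeric(voxel_size),
         tail_point = tail_point, head_point = head_point,
         length_L = length_L, widest_diameter_D = widest_diameter_D,
         volume = volume, semi_axes = semi_axes, center = center,
         rotation = rotation, .cache = new.env(parent = emptyenv())),
    class = "nucleus_model")
  if (!is.null(nm$length_L) && nm$length_L <= 0) stop("length_L must be > 0")
  if (!is.null(nm$widest_diameter_D) && nm$widest_diameter_D <= 0)
    stop("widest_diameter_D must be > 0")
  if (nm$volume <= 0) stop("volume must be > 0")
  nm
}

#' @export
print.nucleus_model <- function(x, ...) {
  cat(sprintf("<nucleus_model> volume %.1f um^3, L = %s, D = %s\n",
              x$volume,
              if (is.null(x$length_L)) "?" else sprintf("%.2f um", x$length_L),
              if (is.null(x$widest_diameter_D)) "?" else
                sprintf("%.2f um", x$widest_diameter_D)))
  invisible(x)
}

# rotation about the z axis
rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

# normalized ellipsoidal coordinate rho over a (Z,Y,X) grid; rho = 1 on the
# surface. Separable in z against the (rotated) xy plane.
ellipsoid_rho <- function(dim3, voxel_size, center, semi_axes, rotation = 0) {
  ax <- semi_axes
  cz <- axis_centers(dim3, voxel_size)
  xs <- cz$x - center[1]; ys <- cz$y - center[2]; zs <- cz$z - center[3]
  ct <- cos(rotation); st <- sin(rotation)
  # body-frame coordinates: xb = ct*x + st*y, yb = -st*x + ct*y
  xb2 <- outer(ys * st, xs * ct, "+")^2 / ax[1]^2   # (ny, nx)
  yb2 <- outer(ys * ct, -xs * st, "+")^2 / ax[2]^2
  mxy <- xb2 + yb2
  zz2 <- zs^2 / ax[3]^2
  arr <- array(rep(mxy, each = dim3[1]), dim3)
  sqrt(arr + zz2)
}

#' Generate a synthetic DAPI nucleus
#'
#' Rasterizes an (optionally rotated) axis-aligned ellipsoid with a smooth
#' logistic edge falloff whose half-maximum lies exactly on the analytic
#' surface, adds Gaussian read noise, and returns the image together with a
#' [nucleus_model] carrying exact analytic landmarks: `L = 2a`,
#' `D = 2 * max(b, c)`, volume `4/3 * pi * a * b * c`. The tail attachment
#' landmark sits at the pole of the long axis.
#'
#' @param spec a [synthetic_spec].
#' @param treated logical; use the DTT-swollen (`TRUE`) or untreated
#'   semi-axes.
#' @param seed optional integer seed for the read noise.
#' @param rotation rotation angle (radians) about the z axis.
#' @param dim optional grid dimensions `(nz, ny, nx)`; errors naming the
#'   offending axis if the ellipsoid (plus PSF margin) does not fit.
#' @return `list(image = voxel_image, nucleus = nucleus_model)`.
#' @export
make_nucleus <- function(spec, treated = TRUE, seed = NULL, rotation = 0,
                         dim = NULL) {
  validate_synthetic_spec(spec)
  ax <- if (treated) spec$semi_axes_treated else spec$semi_axes_untreated
  vs <- spec$voxel_size
  margin <- max(4 * spec$psf_sigma, 0.5)
  ct <- abs(cos(rotation)); st <- abs(sin(rotation))
  ext <- c(x = sqrt((ax[1] * ct)^2 + (ax[2] * st)^2),
           y = sqrt((ax[1] * st)^2 + (ax[2] * ct)^2),
           z = ax[3])
  need <- 2 * (ext + margin)              # physical extent needed (x, y, z)
  dims_needed <- c(nz = ceiling(need["z"] / vs[1]),
                   ny = ceiling(need["y"] / vs[2]),
                   nx = ceiling(need["x"] / vs[3]))
  if (is.null(dim)) {
    dim3 <- as.integer(dims_needed)
    dim3 <- dim3 + 1L - dim3 %% 2L  # odd dims: grid centre on a voxel centre
  } else {
    dim3 <- as.integer(dim)
    too_small <- dim3 < dims_needed
    if (any(too_small)) {
      axis_names <- c("z", "y", "x")[too_small]
      stop(sprintf("ellipsoid (plus PSF margin) exceeds the grid along axis %s",
                   paste(axis_names, collapse = ", ")))
    }
  }
  center <- c(dim3[3] * vs[3], dim3[2] * vs[2], dim3[1] * vs[1]) / 2  # (x,y,z)
  rho <- ellipsoid_rho(dim3, vs, center, ax, rotation)
  gm <- prod(ax)^(1 / 3)
  img <- spec$dapi_amplitude / (1 + exp((rho - 1) * gm / spec$edge_width))
  if (spec$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- img + rnorm(length(img), sd = spec$noise_sd)
    img[img < 0] <- 0
    dim(img) <- dim3
  }
  mask <- rho <= 1
  rot <- rot_z(rotation)
  tail_point <- as.numeric(center + rot %*% c(-ax[1], 0, 0))
  head_point <- as.numeric(center + rot %*% c(ax[1], 0, 0))
  nucleus <- nucleus_model(
    mask = mask, voxel_size = vs,
    tail_point = tail_point, head_point = head_point,
    length_L = 2 * ax[1], widest_diameter_D = 2 * max(ax[2], ax[3]),
    volume = ellipsoid_volume(ax),
    semi_axes = ax, center = center, rotation = rotation)
  list(image = voxel_image(img, vs, "DAPI"), nucleus = nucleus)
}

# uniform points strictly inside the (rotated) ellipsoid; returns (x,y,z) matrix
uniform_in_ellipsoid <- function(n, nucleus) {
  if (is.null(nucleus$semi_axes))
    stop("nucleus has no analytic ellipsoid parameters")
  g <- matrix(rnorm(3 * n), n, 3)
  g <- g / sqrt(rowSums(g^2))
  r <- runif(n)^(1 / 3)
  pts <- g * r
  pts <- sweep(pts, 2, nucleus$semi_axes, "*")
  pts <- pts %*% t(rot_z(nucleus$rotation))
  sweep(pts, 2, nucleus$center, "+")
}
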