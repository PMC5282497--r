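#' Multi-dimensional voxel image
#'
#' A thin container around a 3D intensity array stored in `(Z, Y, X)` order
#' with anisotropic physical voxel sizes in micrometres. Physical coordinates
#' are voxel-centre positions: the centre of the 0-based voxel `(iz, iy, ix)`
#' sits at `((ix + 0.5) * dx, (iy + 0.5) * dy, (iz + 0.5) * dz)` micrometres,
#' reported as `(x, y, z)`.
#'
#' @param intensities numeric 3D array, dimensions `(nz, ny, nx)`.
#' @param voxel_size numeric length-3, `(dz, dy, dx)` in micrometres.
#' @param channel channel label, e.g. `"DAPI"` or `"pantelomere"`.
#' @return An object of class `voxel_image`.
#' @export
voxel_image <- function(intensities, voxel_size, channel = "unknown") {
  if (length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array (Z, Y, X)")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be three positive finite values (dz, dy, dx)")
  if (any(!is.finite(intensities)))
    stop("intensities must be finite")
  structure(
    list(intensities = intensities,
         voxel_size = as.numeric(voxel_size),
         channel = as.character(channel)),
    class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<voxel_image> channel=%s dim=(%d x %d x %d) [Z,Y,X] voxel=(%.3g, %.3g, %.3g) um\n",
              x$channel, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

# physical (x, y, z) of all voxel centres along each axis
axis_centers <- function(dim3, voxel_size) {
  list(z = (seq_len(dim3[1]) - 0.5) * voxel_size[1],
       y = (seq_len(dim3[2]) - 0.5) * voxel_size[2],
       x = (seq_len(dim3[3]) - 0.5) * voxel_size[3])
}

# voxel (1-based integer index) containing each physical point;
# points: matrix with columns x, y, z
point_to_voxel <- function(points, voxel_size, dim3) {
  ix <- pmin(pmax(floor(points[, 1] / voxel_size[3]) + 1L, 1L), dim3[3])
  iy <- pmin(pmax(floor(points[, 2] / voxel_size[2]) + 1L, 1L), dim3[2])
  iz <- pmin(pmax(floor(points[, 3] / voxel_size[1]) + 1L, 1L), dim3[1])
  cbind(iz = iz, iy = iy, ix = ix)
}

# trilinear interpolation of a (Z,Y,X) array at physical points (x,y,z)
trilinear <- function(arr, voxel_size, points) {
  d <- dim(arr)
  # fractional 1-based voxel-centre coordinates
  fz <- points[, 3] / voxel_size[1] + 0.5
  fy <- points[, 2] / voxel_size[2] + 0.5
  fx <- points[, 1] / voxel_size[3] + 0.5
  fz <- pmin(pmax(fz, 1), d[1]); fy <- pmin(pmax(fy, 1), d[2])
  fx <- pmin(pmax(fx, 1), d[3])
  z0 <- pmin(floor(fz), d[1] - 1L); y0 <- pmin(floor(fy), d[2] - 1L)
  x0 <- pmin(floor(fx), d[3] - 1L)
  wz <- fz - z0; wy <- fy - y0; wx <- fx - x0
  at <- function(zi, yi, xi) arr[cbind(zi, yi, xi)]
  v000 <- at(z0,     y0,     x0)
  v100 <- at(z0 + 1, y0,     x0)
  v010 <- at(z0,     y0 + 1, x0)
  v110 <- at(z0 + 1, y0 + 1, x0)
  v001 <- at(z0,     y0,     x0 + 1)
  v101 <- at(z0 + 1, y0,     x0 + 1)
  v011 <- at(z0,     y0 + 1, x0 + 1)
  v111 <- at(z0 + 1, y0 + 1, x0 + 1)
  (1 - wz) * (1 - wy) * (1 - wx) * v000 +
       wz  * (1 - wy) * (1 - wx) * v100 +
  (1 - wz) *      wy  * (1 - wx) * v010 +
       wz  *      wy  * (1 - wx) * v110 +
  (1 - wz) * (1 - wy) *      wx  * v001 +
       wz  * (1 - wy) *      wx  * v101 +
  (1 - wz) *      wy  *      wx  * v011 +
       wz  *      wy  *      wx  * v111
}

# Otsu threshold on a numeric vector (256-bin histogram)
otsu_threshold <- function(x, nbins = 256L) {
  r <- range(x)
  if (diff(r) <= 0) stop("cannot threshold a constant image")
  br <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h); m <- cumsum(h * mids)
  n <- w[nbins]; mt <- m[nbins]
  w1 <- w[-nbins]; m1 <- m[-nbins]
  w2 <- n - w1
  ok <- w1 > 0 & w2 > 0
  bcv <- rep(-Inf, nbins - 1L)
  bcv[ok] <- (mt * w1[ok] - n * m1[ok])^2 / (w1[ok] * w2[ok])
  mids[which.max(bcv)]
}

# fill interior holes of a 3D binary mask (background components not
# touching the array border become foreground)
fill_holes3d <- function(mask) {
  d <- dim(mask)
  lab <- .label3d(!mask, d, 6L)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  border <- border[border != 0L]
  mask | (lab != 0L & !(lab %in% border))
}

#' Write a voxel image as a multi-page TIFF z-stack
#'
#' One page per optical section, plus a plain-text sidecar recording the
#' physical voxel sizes. Intensities are rescaled to `[0, 1]` for storage; the
#' scale factor is recorded in the sidecar.
#'
#' @param img a [voxel_image].
#' @param path output `.tif` path.
#' @export
write_voxel_tiff <- function(img, path) {
  arr <- img$intensities
  sc <- max(arr, 1e-12)
  pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ] / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- c(sprintf("voxel_size_um: %g %g %g", img$voxel_size[1],
                    img$voxel_size[2], img$voxel_size[3]),
            sprintf("channel: %s", img$channel),
            sprintf("intensity_scale: %g", sc))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read a voxel image written by [write_voxel_tiff()]
#' @param path `.tif` path (its `.meta` sidecar must sit next to it).
#' @return A [voxel_image].
#' @export
read_voxel_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- readLines(paste0(path, ".meta"))
  vs <- as.numeric(strsplit(sub("voxel_size_um: ", "", meta[1]), " ")[[1]])
  ch <- sub("channel: ", "", meta[2])
  sc <- as.numeric(sub("intensity_scale: ", "", meta[3]))
  arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]] * sc
  voxel_image(arr, vs, ch)
}
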