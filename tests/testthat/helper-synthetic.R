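# shared fixtures, built in code; small geometries keep tests fast

# small ellipsoidal nucleus spec (untreated-scale) for chain tests
small_spec <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 1L, cells_per_subject = 1L,
         semi_axes_treated = c(3.0, 2.2, 2.2)),
    list(...))
  do.call(synthetic_spec, args)
}

# spherical nucleus, noise-free
sphere_spec <- function(radius = 3, voxel = 0.1, ...) {
  synthetic_spec(semi_axes_treated = rep(radius, 3),
                 voxel_size = rep(voxel, 3), noise_sd = 0, ...)
}

.fixture_env <- new.env(parent = emptyenv())

# memoized clean sphere nucleus (radius 3, 0.1 um voxels)
sphere_nucleus <- function() {
  if (is.null(.fixture_env$sphere))
    .fixture_env$sphere <- make_nucleus(sphere_spec())$nucleus
  .fixture_env$sphere
}

# memoized default-geometry simulated telomere cell and its segmentation
telomere_cell <- function() {
  if (is.null(.fixture_env$cell)) {
    spec <- synthetic_spec()
    cell <- simulate_cell(spec, cell_seed = 101L, channels = "pantelomere")
    seg <- segment_nucleus(cell$images$DAPI, tail_point = cell$nucleus$tail_point)
    .fixture_env$cell <- list(spec = spec, cell = cell, seg = seg)
  }
  .fixture_env$cell
}

# brute-force single-linkage clustering oracle (union-find over all pairs)
brute_single_linkage <- function(pts, radius) {
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (sqrt(sum((pts[i, ] - pts[j, ])^2)) <= radius) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
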