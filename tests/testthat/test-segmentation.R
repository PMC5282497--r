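test_that("segmentation recovers the treated nuclear volume within 2%", {
  fx <- telomere_cell()
  expect_lt(abs(fx$seg$volume - 153.9) / 153.9, 0.02)
})

test_that("treated versus untreated segmentation gives the 2.4-fold swelling", {
  spec <- synthetic_spec(noise_sd = 0)
  tr <- make_nucleus(spec, treated = TRUE)
  un <- make_nucleus(spec, treated = FALSE)
  v1 <- segment_nucleus(tr$image)$volume
  v2 <- segment_nucleus(un$image)$volume
  expect_lt(abs(v1 / v2 - 2.4), 0.1)
})

test_that("degenerate DAPI images produce informative errors", {
  vs <- c(0.2, 0.1, 0.1)
  zero <- voxel_image(array(0, c(20, 20, 20)), vs, "DAPI")
  expect_error(segment_nucleus(zero, threshold_method = "fixed",
                               threshold_value = 10), "empty mask")
  expect_error(segment_nucleus(zero), "constant")
  # two comparable blobs
  arr <- array(0, c(20, 40, 40))
  arr[8:12, 5:12, 5:12] <- 100
  arr[8:12, 28:35, 28:35] <- 100
  two <- voxel_image(arr, vs, "DAPI")
  expect_error(segment_nucleus(two, gaussian_sigma = 0,
                               threshold_method = "fixed",
                               threshold_value = 50),
               "multiple comparable components")
})

test_that("mask volume is monotone non-increasing in the threshold", {
  fx <- telomere_cell()
  vols <- vapply(c(40, 80, 120, 160), function(thr)
    segment_nucleus(fx$cell$images$DAPI, threshold_method = "fixed",
                    threshold_value = thr)$volume, numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("axis measurement recovers L and D of known shapes", {
  spec <- synthetic_spec(noise_sd = 0)
  nuc <- make_nucleus(spec)$nucleus          # (4.08, 3, 3) ellipsoid
  ax <- measure_axes(nuc$mask, nuc$voxel_size, nuc$tail_point)
  expect_lt(abs(ax$length_L - 8.16), 0.2)
  expect_lt(abs(ax$widest_diameter_D - 6.0), 0.2)
  expect_lt(sqrt(sum((ax$head_point - nuc$head_point)^2)), 0.75)

  sph <- sphere_nucleus()                     # radius-3 sphere
  ax2 <- measure_axes(sph$mask, sph$voxel_size, sph$tail_point)
  expect_lt(abs(ax2$length_L - 6.0), 0.2)
  expect_lt(abs(ax2$widest_diameter_D - 6.0), 0.2)
})

test_that("axis measurement is rotation invariant within a voxel", {
  spec <- synthetic_spec(noise_sd = 0)
  rot <- make_nucleus(spec, rotation = pi / 7)$nucleus
  ax <- measure_axes(rot$mask, rot$voxel_size, rot$tail_point)
  expect_lt(abs(ax$length_L - 8.16), 0.25)
  expect_lt(abs(ax$widest_diameter_D - 6.0), 0.25)
})

test_that("a far-away tail point is rejected", {
  sph <- sphere_nucleus()
  expect_error(measure_axes(sph$mask, sph$voxel_size, c(0.2, 0.2, 0.2)),
               "tail_point")
})

test_that("a single clean spot is rendered with sub-voxel centroid accuracy", {
  spec <- sphere_spec(tail_background_amplitude = 0)
  nuc <- sphere_nucleus()
  truth <- c(3.87, 3.33, 4.11)
  sp <- data.frame(channel = "pantelomere", x = truth[1], y = truth[2],
                   z = truth[3], cluster_id = 1L, renderable = TRUE)
  img <- render_spots(NULL, sp, spec, nuc)
  sg <- detect_signals(img, nuc)
  expect_equal(nrow(sg), 1L)
  expect_true(sg$rendered)
  err <- sqrt(sum((c(sg$x, sg$y, sg$z) - truth)^2))
  expect_lt(err, sqrt(sum(nuc$voxel_size^2)))  # within one voxel diagonal
})

test_that("unresolvably close spots merge; resolved spots do not", {
  spec <- sphere_spec(tail_background_amplitude = 0)
  nuc <- sphere_nucleus()
  close2 <- data.frame(channel = "pantelomere",
                       x = c(3.0, 3.1), y = 3.4, z = 3.2,
                       cluster_id = 1:2, renderable = TRUE)
  sg1 <- detect_signals(render_spots(NULL, close2, spec, nuc), nuc)
  expect_equal(sum(sg1$rendered), 1L)
  far2 <- data.frame(channel = "pantelomere",
                     x = c(2.2, 4.2), y = 3.0, z = 3.0,
                     cluster_id = 1:2, renderable = TRUE)
  sg2 <- detect_signals(render_spots(NULL, far2, spec, nuc), nuc)
  expect_equal(sum(sg2$rendered), 2L)
})

test_that("detection is exact on noise-free planted cells", {
  spec <- sphere_spec(n_telomere_units = 12, tail_background_amplitude = 0,
                      telomere_cluster_sizes = c("1" = 1, "2" = 0, "4" = 0),
                      nonrender_fraction_target = 0)
  nuc <- sphere_nucleus()
  spots <- sample_spot_positions(nuc, spec, "pantelomere", seed = 21)
  # keep spots well separated to avoid legitimate merges
  keep <- !duplicated(round(as.matrix(spots[, c("x", "y", "z")]) / 1.2))
  spots <- spots[keep, , drop = FALSE]
  img <- render_spots(NULL, spots, spec, nuc)
  sg <- detect_signals(img, nuc)
  expect_lte(nrow(sg), nrow(spots))           # no false positives
  expect_equal(attr(sg, "n_nonrendered"), 0L)
})

test_that("dim signals are counted as detected-but-not-rendered", {
  spec <- sphere_spec(tail_background_amplitude = 0)
  nuc <- sphere_nucleus()
  sp <- data.frame(channel = "pantelomere",
                   x = c(2.0, 4.5), y = 3.0, z = 3.0,
                   cluster_id = 1:2, renderable = c(TRUE, FALSE))
  sg <- detect_signals(render_spots(NULL, sp, spec, nuc), nuc)
  expect_equal(nrow(sg), 2L)
  expect_equal(sum(sg$rendered), 1L)
  expect_equal(attr(sg, "n_nonrendered"), 1L)
})
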