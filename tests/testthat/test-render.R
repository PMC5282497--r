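test_that("rendering zero spots leaves only noise and background", {
  spec <- sphere_spec(tail_background_amplitude = 0)
  nuc <- sphere_nucleus()
  empty <- data.frame(channel = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), cluster_id = integer(0),
                      renderable = logical(0))
  img <- render_spots(NULL, empty, spec, nuc)
  expect_equal(max(img$intensities), 0)  # noise-free spec variant
  spec2 <- sphere_spec()  # with tail background
  img2 <- render_spots(NULL, empty, spec2, nuc)
  expect_lte(max(img2$intensities), spec2$tail_background_amplitude + 1e-9)
})

test_that("a noise-free spot peaks at its own voxel", {
  spec <- sphere_spec(tail_background_amplitude = 0)
  nuc <- sphere_nucleus()
  sp <- data.frame(channel = "pantelomere", x = 3.55, y = 3.85, z = 4.05,
                   cluster_id = 1L, renderable = TRUE)
  img <- render_spots(NULL, sp, spec, nuc)
  peak <- which(img$intensities == max(img$intensities), arr.ind = TRUE)
  vs <- img$voxel_size
  expect_equal(as.numeric((peak[1, c(3, 2, 1)] - 0.5) * vs[c(3, 2, 1)]),
               c(3.55, 3.85, 4.05))
  expect_equal(max(img$intensities), spec$signal_amplitude, tolerance = 1e-6)
})

test_that("an undersampled PSF warns rather than errors", {
  spec <- sphere_spec(psf_sigma = 0.04, tail_background_amplitude = 0)
  nuc <- sphere_nucleus()
  sp <- data.frame(channel = "pantelomere", x = 3.0, y = 3.0, z = 3.0,
                   cluster_id = 1L, renderable = TRUE)
  expect_warning(render_spots(NULL, sp, spec, nuc), "undersampled")
})

test_that("spots outside the grid are rejected", {
  spec <- sphere_spec(tail_background_amplitude = 0)
  nuc <- sphere_nucleus()
  sp <- data.frame(channel = "pantelomere", x = 99, y = 3, z = 3,
                   cluster_id = 1L, renderable = TRUE)
  expect_error(render_spots(NULL, sp, spec, nuc), "inside the image grid")
})

test_that("tail-proximal background decays away from the tail", {
  spec <- sphere_spec()
  nuc <- sphere_nucleus()
  empty <- data.frame(channel = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), cluster_id = integer(0),
                      renderable = logical(0))
  img <- render_spots(NULL, empty, spec, nuc)$intensities
  vs <- spec$voxel_size
  mid_iz <- (dim(img)[1] + 1) / 2
  mid_iy <- (dim(img)[2] + 1) / 2
  profile <- img[mid_iz, mid_iy, ]  # along x: tail pole to head pole
  expect_gt(profile[5], profile[length(profile) - 4])
})
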