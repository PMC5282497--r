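test_that("rasterized ellipsoid volume matches the analytic volume", {
  spec <- small_spec(noise_sd = 0)
  nuc <- make_nucleus(spec)
  vx <- sum(nuc$nucleus$mask) * prod(spec$voxel_size)
  expect_lt(abs(vx - nuc$nucleus$volume) / nuc$nucleus$volume, 0.02)
})

test_that("analytic landmarks are exact: L = 2a, D = 2 max(b, c)", {
  spec <- small_spec(noise_sd = 0)
  nuc <- make_nucleus(spec)$nucleus
  expect_equal(nuc$length_L, 6.0)
  expect_equal(nuc$widest_diameter_D, 4.4)
  expect_equal(nuc$volume, ellipsoid_volume(c(3.0, 2.2, 2.2)))
  # tail at one pole of the long axis, head at the other
  expect_equal(sqrt(sum((nuc$head_point - nuc$tail_point)^2)), 6.0)
  expect_equal(nuc$tail_point[2:3], nuc$center[2:3])
})

test_that("an ellipsoid that does not fit the grid errors naming the axis", {
  spec <- small_spec(noise_sd = 0)
  expect_error(make_nucleus(spec, dim = c(5, 81, 81)), "axis z")
  expect_error(make_nucleus(spec, dim = c(41, 5, 81)), "axis y")
})

test_that("nucleus generation is seed-deterministic", {
  spec <- small_spec()
  a <- make_nucleus(spec, seed = 7)
  b <- make_nucleus(spec, seed = 7)
  expect_identical(a$image$intensities, b$image$intensities)
  expect_identical(a$nucleus$mask, b$nucleus$mask)
})

test_that("rotated nuclei keep their analytic landmarks on the rotated axis", {
  spec <- small_spec(noise_sd = 0)
  nuc <- make_nucleus(spec, rotation = pi / 6)$nucleus
  expect_equal(sqrt(sum((nuc$head_point - nuc$tail_point)^2)), 6.0)
  u <- (nuc$head_point - nuc$tail_point) / 6.0
  expect_equal(u, c(cos(pi / 6), sin(pi / 6), 0))
})
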