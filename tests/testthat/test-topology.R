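test_that("distance to edge matches known sphere geometry", {
  nuc <- sphere_nucleus()
  h <- max(nuc$voxel_size)
  d_center <- distance_to_edge(nuc, points = matrix(nuc$center, ncol = 3))
  expect_lt(abs(d_center - 3.0), h / 2)
  # surface-adjacent point
  near <- nuc$center + c(2.95, 0, 0)
  d_near <- distance_to_edge(nuc, points = matrix(near, ncol = 3))
  expect_lt(d_near, sqrt(sum(nuc$voxel_size^2)) + 0.05)
  expect_error(distance_to_edge(nuc, points = matrix(nuc$center + c(5, 0, 0),
                                                     ncol = 3)),
               "outside the mask")
})

test_that("the distance transform honours anisotropic voxels", {
  spec_iso <- sphere_spec(voxel = 0.1)
  spec_ani <- synthetic_spec(semi_axes_treated = rep(3, 3),
                             voxel_size = c(0.2, 0.1, 0.1), noise_sd = 0)
  iso <- make_nucleus(spec_iso)$nucleus
  ani <- make_nucleus(spec_ani)$nucleus
  d_iso <- distance_to_edge(iso, points = matrix(iso$center, ncol = 3))
  d_ani <- distance_to_edge(ani, points = matrix(ani$center, ncol = 3))
  expect_lt(abs(d_iso - d_ani), 0.2)
})

test_that("radial binning follows the thirds-of-the-radius rule", {
  expect_equal(as.character(assign_radial(0.5, 6)$region), "periphery")
  expect_equal(as.character(assign_radial(1.5, 6)$region), "intermediate")
  expect_equal(as.character(assign_radial(2.5, 6)$region), "interior")
  # half-open edges, interior closed above
  expect_equal(as.character(assign_radial(c(1, 2, 3), 6)$region),
               c("intermediate", "interior", "interior"))
  expect_warning(out <- assign_radial(3.5, 6), "clamped")
  expect_equal(out$normalized_r, 1)
  expect_equal(as.character(out$region), "interior")
})

test_that("longitudinal binning follows the thirds-of-the-length rule", {
  tail <- c(0, 0, 0); head <- c(9, 0, 0)
  s <- function(x) assign_longitudinal(c(x, 0, 0), tail, head)
  expect_equal(as.character(s(1.0)$region), "tail")
  expect_equal(as.character(s(4.5)$region), "mid")
  expect_equal(as.character(s(8.9)$region), "head")
  expect_equal(as.character(s(3.0)$region), "mid")   # boundary: half-open
  expect_warning(out <- assign_longitudinal(c(9.5, 0, 0), tail, head),
                 "clamped")
  expect_equal(out$normalized_t, 1)
  # z is ignored when landmarks are planar (2D mode)
  flat <- assign_longitudinal(c(1, 0, 5), tail, head)
  expect_equal(as.character(flat$region), "tail")
  expect_error(assign_longitudinal(c(1, 0, 0), tail, tail), "L = 0")
})

test_that("every signal falls in exactly one radial and one longitudinal region", {
  nuc <- sphere_nucleus()
  set.seed(42)
  pts <- spermtopo:::uniform_in_ellipsoid(500, nuc)
  d <- distance_to_edge(nuc, points = pts)
  rad <- assign_radial(d, nuc$widest_diameter_D)$region
  lng <- assign_longitudinal(pts, nuc$tail_point, nuc$head_point)$region
  expect_false(anyNA(rad)); expect_false(anyNA(lng))
  expect_equal(sum(table(rad)), 500)
  expect_equal(sum(table(lng)), 500)
})

test_that("region assignment is invariant under common rescaling", {
  nuc <- sphere_nucleus()
  set.seed(7)
  pts <- spermtopo:::uniform_in_ellipsoid(200, nuc)
  d <- distance_to_edge(nuc, points = pts)
  r1 <- assign_radial(d, nuc$widest_diameter_D)$region
  r2 <- assign_radial(2.5 * d, 2.5 * nuc$widest_diameter_D)$region
  expect_identical(r1, r2)
  # the same mask interpreted at doubled voxel size gives the same regions
  d2 <- distance_to_edge(nuc$mask, nuc$voxel_size * 2, points = pts * 2)
  r3 <- assign_radial(d2, 2 * nuc$widest_diameter_D)$region
  expect_identical(r1, r3)
})

test_that("per-cell region counts partition rendered and detected signals", {
  nuc <- sphere_nucleus()
  ctr <- nuc$center
  sig <- data.frame(channel = "pantelomere",
                    x = ctr[1] + c(2.6, 1.4, 0.2, -2.8),
                    y = ctr[2], z = ctr[3],
                    rendered = c(TRUE, TRUE, TRUE, FALSE))
  cc <- cell_region_counts(sig, nuc)
  expect_equal(as.numeric(cc[, c("periphery", "intermediate", "interior")]),
               c(1, 1, 1))                     # rendered only
  expect_equal(cc$n_rendered, 3)
  expect_equal(cc$n_total, 4)                  # longitudinal counts all
  expect_equal(cc$frac_tail + cc$frac_mid + cc$frac_head, 1)
  cc0 <- cell_region_counts(sig[0, , drop = FALSE], nuc, channels = "NOR")
  expect_equal(cc0$n_total, 0)
  expect_true(cc0$empty)
  expect_true(is.na(cc0$frac_mid))
})
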