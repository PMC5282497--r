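test_that("default semi-axes reproduce the study's mean nuclear volumes", {
  spec <- synthetic_spec()
  v_treated <- ellipsoid_volume(spec$semi_axes_treated)
  v_untreated <- ellipsoid_volume(spec$semi_axes_untreated)
  expect_lt(abs(v_treated - 153.9) / 153.9, 0.001)
  expect_lt(abs(v_untreated - 62.83) / 62.83, 0.01)
  # DTT swelling factor
  expect_equal(round(v_treated / v_untreated, 1), 2.4)
})

test_that("spec validation rejects degenerate parameters", {
  expect_error(synthetic_spec(semi_axes_treated = c(0, 3, 3)), "semi-axes")
  expect_error(synthetic_spec(radial_fractions = c(0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(synthetic_spec(longitudinal_fractions = c(0.9, 0.2, -0.1)),
               "sum to 1|non-negative")
  expect_error(synthetic_spec(telomere_cluster_sizes = c("3" = 1)),
               "cluster sizes")
  expect_error(synthetic_spec(n_chromocenters = 0), "counts")
  expect_error(synthetic_spec(voxel_size = c(0.2, 0, 0.1)), "voxel")
  expect_error(synthetic_spec(nonrender_fraction_target = 1.5), "probability")
})

test_that("fraction triples must sum to one within 1e-9", {
  expect_error(synthetic_spec(radial_fractions = c(0.42, 0.45, 0.13 + 1e-6)),
               "sum to 1")
  expect_silent(synthetic_spec(radial_fractions = c(0.42, 0.45, 0.13 + 1e-12)))
})
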