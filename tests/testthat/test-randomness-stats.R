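test_that("chi-squared goodness of fit reproduces closed-form values", {
  g0 <- chisq_gof(c(100, 100, 100))
  expect_equal(g0$chi2, 0)
  expect_equal(g0$p_value, 1)
  expect_equal(g0$degrees_of_freedom, 2)

  # the study's 2D telomere longitudinal counts at n = 964
  g1 <- chisq_gof(c(509, 235, 220))
  expect_equal(g1$chi2, 164.75, tolerance = 1e-3)
  expect_lt(g1$p_value, 0.05)

  expect_warning(g2 <- chisq_gof(c(10, 0, 0)), "below 5")
  expect_equal(g2$chi2, 20)
  expect_equal(g2$p_value, pchisq(20, 2, lower.tail = FALSE))
  expect_equal(g2$p_value, 4.54e-5, tolerance = 1e-2)
})

test_that("goodness of fit rejects invalid inputs", {
  expect_error(chisq_gof(c(0, 0, 0)), "zero")
  expect_error(chisq_gof(c(5, 5), c(0.8, 0.1)), "sum to 1")
  expect_error(chisq_gof(c(5, 5), c(1, 0)), "positive")
  expect_error(chisq_gof(c(-1, 5, 5)), "non-negative")
})

test_that("paired method comparison matches the closed-form t statistic", {
  r <- paired_method_comparison(c(2, 4, 6), c(1, 2, 3))  # differences 1,2,3
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 0.0742, tolerance = 1e-2)

  same <- paired_method_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_equal(same$mean_difference, 0)

  degen <- paired_method_comparison(c(2, 3, 4), c(1, 2, 3))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 0)

  expect_error(paired_method_comparison(1, 2), "2 pairs")
  expect_error(paired_method_comparison(1:3, 1:4), "equal length")
})

test_that("between-subject homogeneity matches closed forms", {
  same_rows <- matrix(rep(c(30, 50, 20), 4), 4, byrow = TRUE)
  h0 <- subject_homogeneity(same_rows)
  expect_equal(h0$chi2, 0)
  expect_equal(h0$p_value, 1)
  expect_equal(h0$degrees_of_freedom, 6)

  h1 <- subject_homogeneity(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
  expect_equal(h1$chi2, 20)               # no continuity correction
  expect_equal(h1$p_value, pchisq(20, 1, lower.tail = FALSE))

  expect_error(subject_homogeneity(matrix(c(1, 2, 3), 1)), "2 subjects")
  expect_warning(h2 <- subject_homogeneity(rbind(c(10, 10), c(0, 0),
                                                 c(8, 12))),
                 "dropped")
  expect_equal(nrow(h2$observed), 2)
})

test_that("the Monte-Carlo radial null is a proper distribution with SEs", {
  nuc <- sphere_nucleus()
  mc <- monte_carlo_region_null(nuc, n_points = 2e4, seed = 17)
  expect_equal(sum(mc$fractions), 1)
  expect_true(all(mc$se >= 0))
  mc2 <- monte_carlo_region_null(nuc, n_points = 4e4, seed = 18)
  expect_equal(unname(mc$se[1] / mc2$se[1]), sqrt(2), tolerance = 0.1)
  # volume-weighted null differs sharply from equal thirds on a sphere
  expect_gt(mc$fractions["periphery"], 0.6)
  expect_lt(mc$fractions["interior"], 0.1)
})

test_that("uniform placement is not rejected against its own null", {
  set.seed(31)
  mc <- monte_carlo_region_null(sphere_nucleus(), n_points = 5e4, seed = 19)
  counts <- as.numeric(rmultinom(1, 500, mc$fractions))
  g <- chisq_gof(counts, mc$fractions, null_kind = "monte_carlo_volume")
  expect_gt(g$p_value, 0.001)
  expect_equal(g$null_kind, "monte_carlo_volume")
})
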