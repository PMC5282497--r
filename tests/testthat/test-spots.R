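test_that("pure-periphery targets put every spot within R/3 of the edge", {
  spec <- sphere_spec(radial_fractions = c(1, 0, 0),
                      n_telomere_units = 40,
                      telomere_cluster_sizes = c("1" = 1, "2" = 0, "4" = 0))
  nuc <- sphere_nucleus()
  spots <- sample_spot_positions(nuc, spec, "pantelomere", seed = 3)
  d <- distance_to_edge(nuc, points = as.matrix(spots[, c("x", "y", "z")]))
  expect_true(all(d < nuc$widest_diameter_D / 6))
})

test_that("placed marginal fractions converge to the targets", {
  spec <- synthetic_spec(n_telomere_units = 10000,
                         telomere_cluster_sizes = c("1" = 1, "2" = 0, "4" = 0),
                         radial_fractions = c(0.42, 0.45, 0.13))
  nuc <- make_nucleus(spec, seed = 1)$nucleus
  spots <- sample_spot_positions(nuc, spec, "pantelomere", seed = 5)
  rad <- prop.table(table(spots$true_radial_region))
  lng <- prop.table(table(spots$true_longitudinal_region))
  expect_lt(max(abs(rad[c("periphery", "intermediate", "interior")] -
                      c(0.42, 0.45, 0.13))), 0.02)
  expect_lt(max(abs(lng[c("tail", "mid", "head")] -
                      spec$longitudinal_fractions)), 0.02)
})

test_that("cluster members stay mutually close (jitter containment)", {
  spec <- sphere_spec(n_telomere_units = 40, cluster_jitter = 0.1,
                      telomere_cluster_sizes = c("1" = 0, "2" = 0, "4" = 1))
  spots <- sample_spot_positions(sphere_nucleus(), spec, "pantelomere",
                                 seed = 9)
  for (cid in unique(spots$cluster_id)) {
    m <- as.matrix(spots[spots$cluster_id == cid, c("x", "y", "z")])
    expect_equal(nrow(m), 4)
    expect_lt(max(dist(m)), 0.3)
  }
})

test_that("stored true regions equal the topology module's assignment", {
  fx <- telomere_cell()
  spots <- fx$cell$truth
  nuc <- fx$cell$nucleus
  d <- distance_to_edge(nuc, points = as.matrix(spots[, c("x", "y", "z")]))
  rad <- assign_radial(d, nuc$widest_diameter_D)$region
  lng <- assign_longitudinal(as.matrix(spots[, c("x", "y", "z")]),
                             nuc$tail_point, nuc$head_point)$region
  expect_identical(as.character(rad), spots$true_radial_region)
  expect_identical(as.character(lng), spots$true_longitudinal_region)
})

test_that("positions lie strictly inside the nucleus ellipsoid", {
  fx <- telomere_cell()
  spots <- fx$cell$truth
  nuc <- fx$cell$nucleus
  body <- sweep(as.matrix(spots[, c("x", "y", "z")]), 2, nuc$center) %*%
    spermtopo:::rot_z(nuc$rotation)
  expect_true(all(rowSums(sweep(body, 2, nuc$semi_axes, "/")^2) < 1))
})

test_that("non-renderable flags follow the target rate binomially", {
  spec <- sphere_spec(n_telomere_units = 1000,
                      telomere_cluster_sizes = c("1" = 1, "2" = 0, "4" = 0),
                      nonrender_fraction_target = 0.264)
  spots <- sample_spot_positions(sphere_nucleus(), spec, "pantelomere",
                                 seed = 11)
  expect_equal(nrow(spots), 1000)
  expect_lt(abs(sum(!spots$renderable) - 264), 30)
})

test_that("geometrically impossible joint targets error with achieved fractions", {
  spec <- sphere_spec(n_telomere_units = 30,
                      telomere_cluster_sizes = c("1" = 1, "2" = 0, "4" = 0),
                      radial_fractions = c(0, 0, 1),
                      longitudinal_fractions = c(1, 0, 0))
  expect_error(sample_spot_positions(sphere_nucleus(), spec, "pantelomere",
                                     seed = 2),
               "acceptance|achieved|place")
})

test_that("probe channels attach to supplied chromocenter anchors", {
  spec <- sphere_spec()
  nuc <- sphere_nucleus()
  cen <- sample_spot_positions(nuc, spec, "pancentromere", seed = 13)
  anchors <- attr(cen, "seeds")
  expect_equal(nrow(anchors), spec$n_chromocenters)
  nor <- sample_spot_positions(nuc, spec, "NOR", seed = 14, anchors = anchors)
  expect_equal(nrow(nor), spec$n_nor_units)
  d_anchor <- sqrt(rowSums((as.matrix(nor[, c("x", "y", "z")]) -
                              anchors[nor$anchor_id, , drop = FALSE])^2))
  expect_true(all(d_anchor <= spec$anchor_jitter + 1e-9))
  expect_error(sample_spot_positions(nuc, spec, "NOR", seed = 1),
               "anchors")
})
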