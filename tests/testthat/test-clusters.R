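test_that("single-linkage clustering counts known configurations", {
  # 4 signals mutually within 0.1 um
  tight <- matrix(c(0, 0, 0,  0.05, 0, 0,  0, 0.05, 0,  0.05, 0.05, 0.02),
                  ncol = 3, byrow = TRUE)
  cl <- count_clusters(tight, merge_radius = 0.3)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$size, 4)

  # 46 well-separated pairs
  centers <- expand.grid(x = seq(0, 6 * 6, by = 6), y = seq(0, 6 * 6, by = 6),
                         z = c(0, 6))[1:46, ]
  pts <- rbind(as.matrix(centers), as.matrix(centers) + 0.05)
  cl46 <- count_clusters(pts, merge_radius = 0.3)
  expect_equal(nrow(cl46$clusters), 46)
  expect_true(all(cl46$clusters$size == 2))

  # chain transitivity: A-B-C with d(A,B) = d(B,C) = 0.25, d(A,C) = 0.5
  chain <- matrix(c(0, 0, 0,  0.25, 0, 0,  0.5, 0, 0), ncol = 3, byrow = TRUE)
  expect_equal(nrow(count_clusters(chain, merge_radius = 0.3)$clusters), 1)

  # merge_radius 0: one cluster per signal
  expect_equal(nrow(count_clusters(chain, merge_radius = 0)$clusters), 3)
  # degenerate inputs
  expect_equal(nrow(count_clusters(chain[1, , drop = FALSE])$clusters), 1)
  expect_equal(nrow(count_clusters(chain[0, , drop = FALSE])$clusters), 0)
})

test_that("clustering agrees with a brute-force union-find oracle", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(2:15, 1)
    pts <- matrix(runif(3 * n, 0, 2), ncol = 3)
    r <- runif(1, 0.1, 0.8)
    ours <- count_clusters(pts, merge_radius = r)$assignment
    oracle <- brute_single_linkage(pts, r)
    # same partition (labels may differ)
    expect_equal(length(unique(ours)), length(unique(oracle)))
    expect_true(all(tapply(oracle, ours, function(g) length(unique(g))) == 1))
  }
})

test_that("cluster count is monotone non-increasing in merge radius", {
  set.seed(5)
  pts <- matrix(runif(60, 0, 3), ncol = 3)
  radii <- c(0, 0.1, 0.3, 0.6, 1.2, 3)
  counts <- vapply(radii, function(r)
    nrow(count_clusters(pts, merge_radius = r)$clusters), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("chromocenter association counts distinct chromocenters hit", {
  chromo <- data.frame(cluster_id = 1:3,
                       x = c(0, 3, 6), y = 0, z = 0, size = 3)
  near_one <- data.frame(x = c(0.1, -0.2, 0.3), y = c(0.2, 0, -0.1), z = 0)
  rec <- associate_with_chromocenters(near_one, chromo, proximity = 0.5)
  expect_equal(rec$n_distinct_chromocenters_associated, 1)
  expect_true(rec$all_in_one)

  spread <- data.frame(x = c(0.1, 3.2, 5.9), y = 0, z = 0)
  rec2 <- associate_with_chromocenters(spread, chromo, proximity = 0.5)
  expect_equal(rec2$n_distinct_chromocenters_associated, 3)
  expect_false(rec2$all_in_one)

  lost <- data.frame(x = 1.5, y = 2, z = 2)
  rec3 <- associate_with_chromocenters(lost, chromo, proximity = 0.5)
  expect_equal(rec3$n_distinct_chromocenters_associated, 0)
  expect_equal(rec3$n_unassociated, 1)

  rec4 <- associate_with_chromocenters(spread, chromo[0, ], proximity = 0.5)
  expect_true(rec4$no_chromocenters)
  expect_true(is.na(rec4$n_distinct_chromocenters_associated))

  expect_true(shares_chromocenter(rec, rec2))
  expect_false(shares_chromocenter(rec3, rec))
})

test_that("the colocalization null PMF matches exact enumeration", {
  p <- null_colocalization_pmf(3, 7, method = "enumerate")
  expect_equal(unname(p["1"]), 1 / 49)
  expect_equal(unname(p["3"]), 210 / 343)
  expect_equal(sum(p), 1)
  expect_equal(unname(null_colocalization_pmf(1, 5)["1"]), 1)
  expect_equal(unname(null_colocalization_pmf(3, 1)["1"]), 1)
})

test_that("enumeration and Stirling closed form agree to 1e-12", {
  for (n in 1:6) for (k in c(1, 2, 3, 7, 10)) {
    pe <- null_colocalization_pmf(n, k, method = "enumerate")
    pc <- null_colocalization_pmf(n, k, method = "closed_form")
    expect_lt(max(abs(pe - pc)), 1e-12)
    expect_equal(sum(pc), 1, tolerance = 1e-12)
  }
})

test_that("uniform placement over chromocenters reproduces the null PMF", {
  set.seed(123)
  n_cells <- 300
  distinct <- replicate(n_cells, length(unique(sample.int(7, 3, TRUE))))
  obs <- tabulate(distinct, 3) / n_cells
  p <- null_colocalization_pmf(3, 7)
  se <- sqrt(p * (1 - p) / n_cells)
  expect_true(all(abs(obs - p) < 4 * se + 1e-9))
})
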