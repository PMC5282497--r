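# inferential statistics: goodness of fit, geometric null, method comparison

#' Chi-squared goodness of fit for region counts
#'
#' Pearson chi-squared test of observed region counts against expected
#' fractions, `df = k - 1` -- the study's test of whether an organization
#' differs from random. The default null is equal thirds; a volume-weighted
#' Monte-Carlo null from [monte_carlo_region_null()] can be supplied
#' instead. Warns when any expected count falls below 5.
#'
#' @param counts non-negative integer counts per region, total `> 0`.
#' @param expected_fractions positive fractions summing to 1 (default equal).
#' @param null_kind label recorded in the result (`"equal_thirds"` or
#'   `"monte_carlo_volume"`).
#' @return A `gof_result` list: `observed`, `expected_fractions`, `chi2`,
#'   `degrees_of_freedom`, `p_value`, `null_kind`.
#' @export
chisq_gof <- function(counts,
                      expected_fractions = rep(1 / length(counts),
                                               length(counts)),
                      null_kind = "equal_thirds") {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) <= 0) stop("total count is zero")
  if (abs(sum(expected_fractions) - 1) > 1e-9 || any(expected_fractions <= 0))
    stop("expected fractions must be positive and sum to 1")
  ht <- suppressWarnings(chisq.test(counts, p = expected_fractions))
  if (any(ht$expected < 5))
    warning("some expected counts are below 5; the chi-squared approximation may be poor")
  structure(list(observed = counts,
                 expected_fractions = expected_fractions,
                 chi2 = unname(ht$statistic),
                 degrees_of_freedom = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 null_kind = null_kind),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("chi-squared GOF (%s): chi2 = %.3f, df = %d, p = %.3g\n",
              x$null_kind, x$chi2, x$degrees_of_freedom, x$p_value))
  invisible(x)
}

#' Monte-Carlo volume-weighted radial null
#'
#' The thirds-of-the-radius regions are not of equal volume, so "random"
#' need not mean equal thirds. This estimates the fraction of the nuclear
#' volume occupied by each radial region by dropping uniform random points
#' into the mask and assigning them with the same distance-transform rule
#' used for signals. For a sphere the closed form is
#' (19/27, 7/27, 1/27) = (periphery, intermediate, interior).
#'
#' @param nucleus a [nucleus_model] with `widest_diameter_D`.
#' @param n_points number of points (`>= 1`).
#' @param seed optional integer seed.
#' @return `list(fractions, se, n_points)`; fractions sum to 1, `se` are
#'   binomial Monte-Carlo standard errors.
#' @export
monte_carlo_region_null <- function(nucleus, n_points = 1e5, seed = NULL) {
  stopifnot(inherits(nucleus, "nucleus_model"), n_points >= 1)
  if (is.null(nucleus$widest_diameter_D))
    stop("nucleus must carry the widest radial diameter D")
  if (!is.null(seed)) set.seed(seed)
  vs <- nucleus$voxel_size
  ids <- which(nucleus$mask)
  pick <- sample(ids, n_points, replace = TRUE)
  ai <- arrayInd(pick, dim(nucleus$mask))
  pts <- cbind(x = (ai[, 3] - 1 + runif(n_points)) * vs[3],
               y = (ai[, 2] - 1 + runif(n_points)) * vs[2],
               z = (ai[, 1] - 1 + runif(n_points)) * vs[1])
  d <- sample_distance(distance_map(nucleus), pts)
  reg <- factor(.radial_bin(d, nucleus$widest_diameter_D / 2),
                levels = RADIAL_REGIONS)
  f <- as.numeric(prop.table(table(reg)))
  names(f) <- RADIAL_REGIONS
  list(fractions = f, se = sqrt(f * (1 - f) / n_points),
       n_points = n_points)
}

#' Paired 3D-versus-2D method comparison
#'
#' Two-tailed paired t-test on per-subject values (region fractions or
#' per-cell mean signal counts) measured by the 3D and 2D arms of the
#' analysis. All-zero differences give `p = 1` by convention; zero variance
#' with a nonzero mean difference is reported as a degenerate case rather
#' than a t statistic.
#'
#' @param values_3d,values_2d equal-length paired numeric vectors,
#'   `n >= 2`.
#' @return A `method_comparison` list: `mean_difference`, `t`, `df`,
#'   `p_value`, `degenerate`, `n_pairs`.
#' @export
paired_method_comparison <- function(values_3d, values_2d) {
  if (length(values_3d) != length(values_2d))
    stop("paired vectors must have equal length")
  n <- length(values_3d)
  if (n < 2) stop("at least 2 pairs are required")
  d <- values_3d - values_2d
  if (all(d == 0)) {
    res <- list(mean_difference = 0, t = 0, df = n - 1, p_value = 1,
                degenerate = FALSE, n_pairs = n)
  } else if (sd(d) == 0) {
    res <- list(mean_difference = mean(d), t = sign(mean(d)) * Inf,
                df = n - 1, p_value = 0, degenerate = TRUE, n_pairs = n)
  } else {
    ht <- t.test(values_3d, values_2d, paired = TRUE)
    res <- list(mean_difference = unname(ht$estimate),
                t = unname(ht$statistic), df = unname(ht$parameter),
                p_value = ht$p.value, degenerate = FALSE, n_pairs = n)
  }
  structure(res, class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("paired t-test: mean diff = %.4g, t = %.3f, df = %d, p = %.3g%s\n",
              x$mean_difference, x$t, x$df, x$p_value,
              if (x$degenerate) " (degenerate: zero-variance differences)" else ""))
  invisible(x)
}

#' Between-subject homogeneity of region counts
#'
#' Pearson chi-squared test of homogeneity (no continuity correction) on a
#' subjects-by-regions count table, `df = (S - 1)(k - 1)` -- the study's
#' check that organization is reproducible across subjects.
#'
#' @param subject_by_region_counts numeric matrix, one row per subject, one
#'   column per region. Zero rows are dropped with a warning.
#' @return A `gof_result`-like list with `chi2`, `degrees_of_freedom`,
#'   `p_value`, and the (possibly row-reduced) `observed` table.
#' @export
subject_homogeneity <- function(subject_by_region_counts) {
  tab <- as.matrix(subject_by_region_counts)
  zero <- rowSums(tab) == 0
  if (any(zero)) {
    warning(sprintf("%d subject row(s) with zero total dropped", sum(zero)))
    tab <- tab[!zero, , drop = FALSE]
  }
  if (nrow(tab) < 2)
    stop("at least 2 subjects are required (df would be 0)")
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(observed = tab,
                 chi2 = unname(ht$statistic),
                 degrees_of_freedom = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 null_kind = "homogeneity"),
            class = "gof_result")
}
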