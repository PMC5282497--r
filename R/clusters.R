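# cluster counting, chromocenter colocalization, and the combinatorial null

#' Count signal clusters by single-linkage agglomeration
#'
#' Signals whose centroids chain together within `merge_radius` (single
#' linkage, so merging is transitive) form one cluster, mirroring the
#' transitive way iso-surface objects merge when an intensity threshold is
#' raised. `merge_radius = 0` returns one cluster per signal.
#'
#' @param signals data.frame with centroid columns `x`, `y`, `z` (one cell,
#'   one channel), or a bare coordinate matrix.
#' @param merge_radius micrometres.
#' @return `list(clusters, assignment)`: `clusters` has one row per cluster
#'   (`cluster_id`, `size`, merged centroid `x`, `y`, `z`), `assignment`
#'   maps each input signal to its cluster.
#' @export
count_clusters <- function(signals, merge_radius = 0.3) {
  stopifnot(merge_radius >= 0)
  pts <- if (is.matrix(signals)) signals else
    as.matrix(signals[, c("x", "y", "z")])
  n <- nrow(pts)
  if (n == 0)
    return(list(clusters = data.frame(cluster_id = integer(0),
                                      size = integer(0), x = numeric(0),
                                      y = numeric(0), z = numeric(0)),
                assignment = integer(0)))
  if (n == 1 || merge_radius == 0) {
    assignment <- seq_len(n)
  } else {
    hc <- hclust(dist(pts), method = "single")
    assignment <- cutree(hc, h = merge_radius)
  }
  sizes <- tabulate(assignment)
  cl <- data.frame(
    cluster_id = seq_along(sizes),
    size = sizes,
    x = rowsum(pts[, 1], assignment)[, 1] / sizes,
    y = rowsum(pts[, 2], assignment)[, 1] / sizes,
    z = rowsum(pts[, 3], assignment)[, 1] / sizes)
  list(clusters = cl, assignment = as.integer(assignment))
}

#' Associate probe signals with chromocenters
#'
#' Assigns each probe signal (NOR or centromere-1/5/19) to its nearest
#' chromocenter when that chromocenter lies within `proximity`; farther
#' signals are recorded as unassociated and excluded from the distinct
#' count. This quantifies how many distinct chromocenters a probe set
#' physically colocalizes with, the study's test of whether specific
#' chromosomes form the same chromocenters.
#'
#' @param probe_signals data.frame with `x`, `y`, `z` (discrete signals of
#'   one probe set in one cell).
#' @param chromocenter_clusters `clusters` data.frame from
#'   [count_clusters()] run on the pancentromere channel of the same cell.
#' @param proximity association distance in micrometres.
#' @return A list: `n_discrete_signals`,
#'   `n_distinct_chromocenters_associated`, `all_in_one`, `n_unassociated`,
#'   `chromocenters_hit` (ids), `assignment` (chromocenter id or `NA` per
#'   signal), and `no_chromocenters` flag.
#' @export
associate_with_chromocenters <- function(probe_signals, chromocenter_clusters,
                                         proximity = 0.5) {
  n <- nrow(probe_signals)
  if (nrow(chromocenter_clusters) == 0) {
    return(list(n_discrete_signals = n,
                n_distinct_chromocenters_associated = NA_integer_,
                all_in_one = NA, n_unassociated = n,
                chromocenters_hit = integer(0),
                assignment = rep(NA_integer_, n),
                no_chromocenters = TRUE))
  }
  p <- as.matrix(probe_signals[, c("x", "y", "z")])
  q <- as.matrix(chromocenter_clusters[, c("x", "y", "z")])
  assignment <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    dd <- sqrt(colSums((t(q) - p[i, ])^2))
    j <- which.min(dd)
    if (dd[j] <= proximity)
      assignment[i] <- chromocenter_clusters$cluster_id[j]
  }
  hit <- unique(assignment[!is.na(assignment)])
  list(n_discrete_signals = n,
       n_distinct_chromocenters_associated = length(hit),
       all_in_one = n > 0 && length(hit) == 1 && !anyNA(assignment),
       n_unassociated = sum(is.na(assignment)),
       chromocenters_hit = sort(hit),
       assignment = assignment,
       no_chromocenters = FALSE)
}

#' Do two probe sets share a chromocenter?
#' @param rec1,rec2 records from [associate_with_chromocenters()] computed
#'   against the same chromocenter set.
#' @return Logical.
#' @export
shares_chromocenter <- function(rec1, rec2) {
  length(intersect(rec1$chromocenters_hit, rec2$chromocenters_hit)) > 0
}

# Stirling numbers of the second kind, S(n, 0..n), by recurrence
stirling2_row <- function(n) {
  s <- c(1, rep(0, n))  # S(0, 0..n)
  if (n == 0) return(s)
  for (m in seq_len(n)) {
    new <- numeric(n + 1)
    for (j in seq_len(m)) {
      new[j + 1] <- s[j] + j * s[j + 1]
    }
    s <- new
  }
  s
}

#' Null distribution of distinct chromocenters hit
#'
#' Exact distribution of the number of distinct chromocenters associated
#' with `n_signals` probe signals when each signal independently and
#' uniformly picks one of `n_chromocenters` chromocenters -- the "by chance
#' alone" reference for the colocalization counts. Computed by full
#' enumeration for small inputs and by the Stirling-number closed form
#' `P(j) = C(k, j) S(n, j) j! / k^n` otherwise; the two routes agree.
#'
#' @param n_signals number of probe signals (`>= 1`).
#' @param n_chromocenters number of chromocenters (`>= 1`).
#' @param method `"auto"`, `"enumerate"` or `"closed_form"`.
#' @return Named numeric vector: `P(j distinct)` for
#'   `j = 1..min(n_signals, n_chromocenters)`; sums to 1.
#' @export
null_colocalization_pmf <- function(n_signals, n_chromocenters,
                                    method = c("auto", "enumerate",
                                               "closed_form")) {
  stopifnot(n_signals >= 1, n_chromocenters >= 1)
  method <- match.arg(method)
  n <- as.integer(n_signals); k <- as.integer(n_chromocenters)
  jmax <- min(n, k)
  if (method == "auto")
    method <- if (k^n <= 2e6) "enumerate" else "closed_form"
  if (method == "enumerate") {
    if (k^n > 2e7) stop("enumeration too large; use closed_form")
    grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
    distinct <- apply(as.matrix(grid), 1, function(a) length(unique(a)))
    p <- tabulate(distinct, jmax) / k^n
  } else {
    s2 <- stirling2_row(n)  # S(n, 0..n)
    j <- seq_len(jmax)
    p <- choose(k, j) * s2[j + 1] * factorial(j) / k^n
  }
  names(p) <- as.character(seq_len(jmax))
  p
}
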