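# configuration, tabular I/O and the end-to-end pipeline

SPOT_REQUIRED_COLS <- c("cell_id", "channel", "x", "y", "z")

#' Read a spot/centroid table
#'
#' Reads and validates a per-signal CSV (columns `cell_id`, `channel`, `x`,
#' `y`, `z`; optional `subject`, `voxels`, `peak`, `rendered`, and per-cell
#' landmark columns `tail_x`, `tail_y`, `tail_z`, `head_x`, `head_y`,
#' `head_z` for the 2D mode where only centroids and manually measured
#' landmarks exist). Unknown channels are rejected; a malformed coordinate
#' is reported with its row number.
#'
#' @param path CSV path.
#' @return A named list of per-cell data.frames; the full validated table is
#'   attached as `attr(, "table")`.
#' @export
read_spot_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SPOT_REQUIRED_COLS, names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  if (nrow(df) > 0) {
    bad_channel <- !(df$channel %in% FISH_CHANNELS)
    if (any(bad_channel))
      stop(sprintf("unknown channel(s): %s",
                   paste(unique(df$channel[bad_channel]), collapse = ", ")))
    for (cc in intersect(c("x", "y", "z", "tail_x", "tail_y", "tail_z",
                           "head_x", "head_y", "head_z"), names(df))) {
      v <- suppressWarnings(as.numeric(df[[cc]]))
      bad <- which(is.na(v) & !is.na(df[[cc]]))
      if (length(bad) > 0)
        stop(sprintf("malformed value in column '%s' at row %d", cc, bad[1]))
      df[[cc]] <- v
    }
    if (is.null(df$rendered)) df$rendered <- TRUE
  } else {
    if (is.null(df$rendered)) df$rendered <- logical(0)
  }
  out <- split(df, df$cell_id)
  attr(out, "table") <- df
  out
}

#' Write a signal/spot table
#' @param signals data.frame of signals.
#' @param path CSV path.
#' @export
write_spot_table <- function(signals, path) {
  write.csv(signals, path, row.names = FALSE)
  invisible(path)
}

#' Build a run configuration
#'
#' Gathers the pipeline's free parameters: the synthetic spec, segmentation
#' and detection thresholds, clustering radii, the randomness null, seed and
#' output directory. `read_run_config()` loads the same structure from a
#' YAML file.
#'
#' @param mode `"simulate"`, `"analyze"` or `"report"`.
#' @param spec a [synthetic_spec] (or list of overrides for its arguments).
#' @param channels FISH channels to process.
#' @param gaussian_sigma DAPI smoothing sigma (um).
#' @param detect_threshold,presence_threshold,min_voxels,smooth_sigma
#'   detection parameters (see [detect_signals()]).
#' @param merge_radius single-linkage cluster radius (um).
#' @param proximity chromocenter association distance (um).
#' @param null_kind `"equal_thirds"`, `"monte_carlo_volume"` or `"both"`.
#' @param seed integer; overrides `spec$seed` when given.
#' @param output_dir output directory (`NULL` for in-memory results only).
#' @param spot_table optional CSV path: analyze pre-measured centroids (2D
#'   mode) instead of simulating images.
#' @param overwrite allow overwriting existing outputs.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("analyze", "simulate", "report"),
                       spec = synthetic_spec(),
                       channels = FISH_CHANNELS,
                       gaussian_sigma = 0.15,
                       detect_threshold = 60,
                       presence_threshold = 12,
                       min_voxels = 2L,
                       smooth_sigma = 0.1,
                       merge_radius = 0.3,
                       proximity = 0.5,
                       null_kind = "both",
                       seed = NULL,
                       output_dir = NULL,
                       spot_table = NULL,
                       overwrite = FALSE) {
  mode <- match.arg(mode)
  if (!inherits(spec, "synthetic_spec"))
    spec <- do.call(synthetic_spec, spec)
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  if (any(c(gaussian_sigma, detect_threshold, presence_threshold,
            min_voxels, smooth_sigma, merge_radius, proximity) < 0))
    stop("thresholds must be non-negative")
  if (!is.null(spot_table) && !file.exists(spot_table))
    stop(sprintf("spot_table does not exist: %s", spot_table))
  structure(list(mode = mode, spec = spec, channels = channels,
                 gaussian_sigma = gaussian_sigma,
                 detect_threshold = detect_threshold,
                 presence_threshold = presence_threshold,
                 min_voxels = as.integer(min_voxels),
                 smooth_sigma = smooth_sigma,
                 merge_radius = merge_radius, proximity = proximity,
                 null_kind = null_kind, output_dir = output_dir,
                 spot_table = spot_table, overwrite = overwrite),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML configuration file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec_args <- y$spec %||% list()
  y$spec <- do.call(synthetic_spec, spec_args)
  do.call(run_config, y)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  flat <- config
  flat$spec <- unclass(flat$spec)
  yaml::write_yaml(flat, tmp)
  unname(tools::md5sum(tmp))
}

# analyze one simulated cell through segmentation -> detection -> topology
# -> clusters -> colocalization; returns per-cell record tables
analyze_cell <- function(cell, config, cell_id, subject) {
  seg <- segment_nucleus(cell$images$DAPI,
                         gaussian_sigma = config$gaussian_sigma,
                         tail_point = cell$nucleus$tail_point)
  channels <- intersect(config$channels, names(cell$images))
  signals <- list()
  for (ch in channels) {
    sg <- detect_signals(cell$images[[ch]], seg,
                         detect_threshold = config$detect_threshold,
                         min_voxels = config$min_voxels,
                         presence_threshold = config$presence_threshold,
                         smooth_sigma = config$smooth_sigma)
    signals[[ch]] <- sg
  }
  signals <- do.call(rbind, signals)
  counts <- cell_region_counts(signals, seg)

  clusters <- lapply(channels, function(ch) {
    sg <- signals[signals$channel == ch, , drop = FALSE]
    cl <- count_clusters(sg, merge_radius = config$merge_radius)
    data.frame(channel = ch, n_signals = nrow(sg),
               n_clusters = nrow(cl$clusters))
  })
  clusters <- do.call(rbind, clusters)

  coloc <- NULL
  if ("pancentromere" %in% channels &&
      any(c("NOR", "cen_1_5_19") %in% channels)) {
    cen <- signals[signals$channel == "pancentromere" & signals$rendered, ,
                   drop = FALSE]
    chromo <- count_clusters(cen, merge_radius = config$merge_radius)$clusters
    recs <- list()
    for (ps in intersect(c("NOR", "cen_1_5_19"), channels)) {
      probe <- signals[signals$channel == ps, , drop = FALSE]
      recs[[ps]] <- associate_with_chromocenters(probe, chromo,
                                                 proximity = config$proximity)
    }
    shares <- if (length(recs) == 2) shares_chromocenter(recs[[1]], recs[[2]])
              else NA
    coloc <- do.call(rbind, lapply(names(recs), function(ps) {
      r <- recs[[ps]]
      data.frame(probe_set = ps,
                 n_discrete_signals = r$n_discrete_signals,
                 n_distinct_chromocenters = r$n_distinct_chromocenters_associated,
                 all_in_one = r$all_in_one,
                 n_unassociated = r$n_unassociated,
                 no_chromocenters = r$no_chromocenters,
                 shares_with_other_probe = shares)
    }))
  }

  # 2D arm: project detected centroids and landmarks into the image plane,
  # merge signals that overlap in projection, and re-assign longitudinally
  counts2d <- NULL
  tel2d <- signals[signals$channel == "pantelomere", , drop = FALSE]
  if (nrow(tel2d) > 0) {
    p2 <- as.matrix(tel2d[, c("x", "y", "z")])
    p2[, 3] <- 0
    merged <- count_clusters(p2, merge_radius = config$merge_radius)$clusters
    t2 <- seg$tail_point; h2 <- seg$head_point
    t2[3] <- 0; h2[3] <- 0
    la <- assign_longitudinal(as.matrix(merged[, c("x", "y", "z")]), t2, h2)
    tb <- table(la$region)
    counts2d <- data.frame(channel = "pantelomere_2d",
                           n_signals_2d = nrow(merged),
                           tail = as.numeric(tb["tail"]),
                           mid = as.numeric(tb["mid"]),
                           head = as.numeric(tb["head"]))
  }

  prep <- function(df) if (is.null(df)) NULL else
    cbind(cell_id = cell_id, subject = subject, df, row.names = NULL)
  list(signals = prep(signals), counts = prep(counts),
       clusters = prep(clusters), coloc = prep(coloc),
       counts2d = prep(counts2d), nucleus = seg)
}

#' Run the pipeline end to end
#'
#' Executes simulate -> segment -> topology -> clusters -> statistics as
#' requested by the configuration. In `"simulate"` mode only ground truth
#' (and optionally images) is produced. In `"analyze"` mode each cell is
#' simulated, segmented and measured in a stream (images are discarded after
#' use), and the statistical report is assembled: pooled and per-subject
#' chi-squared goodness of fit against the equal-thirds null and (for the
#' radial axis) the Monte-Carlo volume-weighted null, between-subject
#' homogeneity, the paired 3D-versus-2D comparison, and the non-rendered
#' signal fraction. Cells that fail are skipped with a logged reason; the
#' run aborts if more than half fail. All outputs carry the configuration
#' hash and seed.
#'
#' @param config a [run_config] (or a YAML path readable by
#'   [read_run_config()]).
#' @return Invisibly, a list with `cell_counts`, `signals`, `clusters`,
#'   `colocalization`, `counts2d`, `stats` (tidy test table), `summary`,
#'   `log`, `config_hash`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  spec <- config$spec
  hash <- config_hash(config)

  if (config$mode == "simulate") {
    res <- simulate_cohort(spec, channels = config$channels, render = FALSE,
                           output_dir = config$output_dir,
                           overwrite = config$overwrite)
    res$config_hash <- hash
    return(invisible(res))
  }

  if (!is.null(config$spot_table)) {
    return(invisible(analyze_spot_table(config, hash)))
  }

  seeds <- cohort_seeds(spec)
  n_cells <- length(seeds)
  acc <- list(signals = list(), counts = list(), clusters = list(),
              coloc = list(), counts2d = list())
  log <- character(0)
  failed <- 0L
  template_nucleus <- NULL
  idx <- 0L
  for (s in seq_len(spec$n_subjects)) {
    for (cc in seq_len(spec$cells_per_subject)) {
      idx <- idx + 1L
      cell_id <- sprintf("S%02d_C%03d", s, cc)
      res <- tryCatch({
        cell <- simulate_cell(spec, seeds[idx], channels = config$channels,
                              render = TRUE)
        analyze_cell(cell, config, cell_id, s)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed <- failed + 1L
        log <- c(log, sprintf("cell %s skipped: %s", cell_id,
                              conditionMessage(res)))
        next
      }
      if (is.null(template_nucleus)) template_nucleus <- res$nucleus
      for (nm in names(acc)) acc[[nm]][[cell_id]] <- res[[nm]]
    }
  }
  if (idx == 0L || failed == idx) stop("no cells found")
  if (failed > idx / 2)
    stop(sprintf("more than half of the cells failed (%d of %d)", failed, idx))

  tables <- lapply(acc, function(l) {
    l <- Filter(Negate(is.null), l)
    if (length(l) == 0) NULL else do.call(rbind, c(l, make.row.names = FALSE))
  })

  stats_rows <- list()
  add_test <- function(target, subject, axis, null_kind, res) {
    stats_rows[[length(stats_rows) + 1L]] <<- data.frame(
      target = target, subject = subject, axis = axis,
      null_kind = null_kind, chi2 = res$chi2,
      df = res$degrees_of_freedom, p = res$p_value)
  }

  mc_null <- NULL
  if (config$null_kind %in% c("both", "monte_carlo_volume") &&
      !is.null(template_nucleus)) {
    mc_null <- monte_carlo_region_null(template_nucleus, n_points = 2e4,
                                       seed = spec$seed)
  }

  counts <- tables$counts
  for (ch in unique(counts$channel)) {
    sub <- counts[counts$channel == ch, , drop = FALSE]
    rad <- colSums(sub[, RADIAL_REGIONS, drop = FALSE])
    lng <- colSums(sub[, LONGITUDINAL_REGIONS, drop = FALSE])
    if (sum(rad) > 0) {
      if (config$null_kind %in% c("both", "equal_thirds"))
        add_test(ch, "pooled", "radial", "equal_thirds", chisq_gof(rad))
      if (!is.null(mc_null))
        add_test(ch, "pooled", "radial", "monte_carlo_volume",
                 chisq_gof(rad, mc_null$fractions,
                           null_kind = "monte_carlo_volume"))
    }
    if (sum(lng) > 0)
      add_test(ch, "pooled", "longitudinal", "equal_thirds", chisq_gof(lng))
    # per-subject tests and homogeneity
    rad_tab <- rowsum(as.matrix(sub[, RADIAL_REGIONS]), sub$subject)
    lng_tab <- rowsum(as.matrix(sub[, LONGITUDINAL_REGIONS]), sub$subject)
    for (sj in rownames(rad_tab)) {
      if (sum(rad_tab[sj, ]) > 0)
        add_test(ch, sj, "radial", "equal_thirds", chisq_gof(rad_tab[sj, ]))
      if (sum(lng_tab[sj, ]) > 0)
        add_test(ch, sj, "longitudinal", "equal_thirds",
                 chisq_gof(lng_tab[sj, ]))
    }
    if (nrow(rad_tab) > 1 && all(rowSums(rad_tab) > 0))
      add_test(ch, "between-subjects", "radial", "homogeneity",
               subject_homogeneity(rad_tab))
    if (nrow(lng_tab) > 1 && all(rowSums(lng_tab) > 0))
      add_test(ch, "between-subjects", "longitudinal", "homogeneity",
               subject_homogeneity(lng_tab))
  }
  stats_tab <- do.call(rbind, stats_rows)

  # paired 3D vs 2D comparison on telomere longitudinal fractions and counts
  method_cmp <- NULL
  if (!is.null(tables$counts2d) && "pantelomere" %in% counts$channel &&
      length(unique(counts$subject)) >= 2) {
    tel <- counts[counts$channel == "pantelomere", , drop = FALSE]
    c2 <- tables$counts2d
    by3 <- rowsum(as.matrix(tel[, LONGITUDINAL_REGIONS]), tel$subject)
    by2 <- rowsum(as.matrix(c2[, LONGITUDINAL_REGIONS]), c2$subject)
    f3 <- by3 / rowSums(by3); f2 <- by2 / rowSums(by2)
    method_cmp <- lapply(LONGITUDINAL_REGIONS, function(rg)
      paired_method_comparison(f3[, rg], f2[, rg]))
    names(method_cmp) <- LONGITUDINAL_REGIONS
    n3 <- tapply(tel$n_total, tel$subject, mean)
    n2 <- tapply(c2$n_signals_2d, c2$subject, mean)
    common <- intersect(names(n3), names(n2))
    method_cmp$signal_count <- paired_method_comparison(n3[common], n2[common])
  }

  summary <- list(
    n_cells = idx - failed, n_failed = failed,
    seed = spec$seed, config_hash = hash,
    nonrender_fraction = if (!is.null(tables$signals)) {
      tel <- tables$signals[tables$signals$channel == "pantelomere", ]
      if (nrow(tel) > 0) mean(!tel$rendered) else NA_real_
    } else NA_real_,
    mean_clusters = if (!is.null(tables$clusters))
      tapply(tables$clusters$n_clusters, tables$clusters$channel, mean)
    else NULL,
    mc_null = mc_null)

  out <- list(cell_counts = tables$counts, signals = tables$signals,
              clusters = tables$clusters, colocalization = tables$coloc,
              counts2d = tables$counts2d, stats = stats_tab,
              method_comparison = method_cmp, summary = summary,
              log = log, config_hash = hash)
  if (!is.null(config$output_dir))
    write_pipeline_outputs(out, config)
  invisible(out)
}

analyze_spot_table <- function(config, hash) {
  cells <- read_spot_table(config$spot_table)
  if (length(cells) == 0) stop("no cells found")
  tab <- attr(cells, "table")
  if (!all(c("tail_x", "tail_y", "head_x", "head_y") %in% names(tab)))
    stop("2D mode requires per-cell landmark columns tail_x/tail_y/head_x/head_y")
  counts <- lapply(cells, function(df) {
    tp <- c(df$tail_x[1], df$tail_y[1],
            if ("tail_z" %in% names(df)) df$tail_z[1] else 0)
    hp <- c(df$head_x[1], df$head_y[1],
            if ("head_z" %in% names(df)) df$head_z[1] else 0)
    z <- if (all(is.finite(df$z))) df$z else 0
    la <- assign_longitudinal(cbind(df$x, df$y, z * 0), tp * c(1, 1, 0),
                              hp * c(1, 1, 0))
    tb <- table(la$region)
    data.frame(cell_id = df$cell_id[1],
               subject = if ("subject" %in% names(df)) df$subject[1] else 1,
               channel = df$channel[1], n_total = nrow(df),
               tail = as.numeric(tb["tail"]), mid = as.numeric(tb["mid"]),
               head = as.numeric(tb["head"]))
  })
  counts <- do.call(rbind, c(counts, make.row.names = FALSE))
  lng <- colSums(counts[, LONGITUDINAL_REGIONS])
  stats_tab <- data.frame(target = counts$channel[1], subject = "pooled",
                          axis = "longitudinal", null_kind = "equal_thirds",
                          chi2 = NA, df = NA, p = NA)
  gof <- chisq_gof(lng)
  stats_tab$chi2 <- gof$chi2; stats_tab$df <- gof$degrees_of_freedom
  stats_tab$p <- gof$p_value
  out <- list(cell_counts = counts, stats = stats_tab,
              summary = list(n_cells = length(cells), config_hash = hash),
              config_hash = hash)
  if (!is.null(config$output_dir)) write_pipeline_outputs(out, config)
  invisible(out)
}

write_pipeline_outputs <- function(out, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df))
      write.csv(df, file.path(config$output_dir, name), row.names = FALSE)
  }
  wr(out$cell_counts, "cell_counts.csv")
  wr(out$signals, "signals.csv")
  wr(out$clusters, "cluster_counts.csv")
  wr(out$colocalization, "colocalization.csv")
  wr(out$stats, "stats_tests.csv")
  wr(out$counts2d, "counts_2d.csv")
  if (!is.null(out$method_comparison)) {
    mc <- do.call(rbind, lapply(names(out$method_comparison), function(nm) {
      m <- out$method_comparison[[nm]]
      data.frame(quantity = nm, mean_difference = m$mean_difference,
                 t = m$t, df = m$df, p = m$p_value,
                 degenerate = m$degenerate, n_pairs = m$n_pairs)
    }))
    wr(mc, "method_comparison.csv")
  }
  rep_lines <- c(
    sprintf("run hash: %s  seed: %d", out$config_hash, config$spec$seed),
    sprintf("cells analyzed: %d (failed: %d)", out$summary$n_cells,
            out$summary$n_failed %||% 0L),
    if (!is.na(out$summary$nonrender_fraction %||% NA))
      sprintf("non-rendered telomere fraction: %.1f%%",
              100 * out$summary$nonrender_fraction),
    if (!is.null(out$summary$mean_clusters))
      sprintf("mean clusters per cell: %s",
              paste(sprintf("%s=%.2f", names(out$summary$mean_clusters),
                            out$summary$mean_clusters), collapse = ", ")),
    if (length(out$log)) c("cell log:", out$log) else "cell log: clean")
  writeLines(rep_lines, file.path(config$output_dir, "report.txt"))
  invisible(NULL)
}
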