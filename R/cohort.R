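# cohort simulation: deterministic per-cell seeds, ground truth and manifest

#' Simulate a single synthetic sperm cell
#'
#' Generates the DAPI nucleus, samples ground-truth spots for the requested
#' channels (chromocenter anchors are generated whenever a probe channel
#' needs them), and optionally renders the FISH channels. All randomness
#' derives from `cell_seed`, so the same seed reproduces the cell exactly.
#'
#' @param spec a [synthetic_spec].
#' @param cell_seed integer seed for this cell.
#' @param treated logical; DTT-swollen geometry by default.
#' @param channels subset of `c("pantelomere", "pancentromere", "NOR",
#'   "cen_1_5_19")`.
#' @param render if `FALSE`, only ground truth is generated (no images).
#' @return `list(images, truth, nucleus)`; `images` holds the DAPI channel
#'   plus one [voxel_image] per rendered FISH channel.
#' @export
simulate_cell <- function(spec, cell_seed, treated = TRUE,
                          channels = FISH_CHANNELS, render = TRUE) {
  channels <- match.arg(channels, FISH_CHANNELS, several.ok = TRUE)
  set.seed(cell_seed)
  nuc <- make_nucleus(spec, treated = treated)
  need_anchors <- any(c("NOR", "cen_1_5_19") %in% channels)
  truth <- list()
  anchors <- NULL

  if ("pantelomere" %in% channels)
    truth$pantelomere <- sample_spot_positions(nuc$nucleus, spec, "pantelomere")
  if ("pancentromere" %in% channels || need_anchors) {
    cen <- sample_spot_positions(nuc$nucleus, spec, "pancentromere")
    anchors <- attr(cen, "seeds")
    if ("pancentromere" %in% channels) truth$pancentromere <- cen
  }
  if ("NOR" %in% channels)
    truth$NOR <- sample_spot_positions(nuc$nucleus, spec, "NOR",
                                       anchors = anchors)
  if ("cen_1_5_19" %in% channels)
    truth$cen_1_5_19 <- sample_spot_positions(nuc$nucleus, spec, "cen_1_5_19",
                                              anchors = anchors)
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  images <- list(DAPI = nuc$image)
  if (render) {
    for (ch in channels) {
      sp <- truth[truth$channel == ch, , drop = FALSE]
      images[[ch]] <- render_spots(NULL, sp, spec, nuc$nucleus)
    }
  }
  list(images = images, truth = truth, nucleus = nuc$nucleus)
}

# deterministic per-cell seed table for a cohort
cohort_seeds <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_subjects * spec$cells_per_subject
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a full cohort
#'
#' Produces `n_subjects x cells_per_subject` cells, each driven by its own
#' seed derived deterministically from the master seed, so re-running with
#' the same spec reproduces byte-identical ground-truth tables. Ground truth
#' and a manifest (cell id, subject, seed, file paths) can be written as CSV;
#' images as multi-page TIFF stacks.
#'
#' @param spec a [synthetic_spec].
#' @param treated logical.
#' @param channels FISH channels to generate.
#' @param render render images (needed only when `write_images = TRUE` or
#'   `keep_images = TRUE`).
#' @param output_dir optional directory for `ground_truth.csv`,
#'   `manifest.csv` and images; refused if the files already exist unless
#'   `overwrite = TRUE`.
#' @param write_images write per-cell per-channel TIFF stacks.
#' @param keep_images return images in memory (only sensible for small runs).
#' @param overwrite allow overwriting an existing output directory.
#' @return `list(truth, manifest, spec)` (+ `cells` when `keep_images`).
#' @export
simulate_cohort <- function(spec, treated = TRUE,
                            channels = "pantelomere",
                            render = FALSE,
                            output_dir = NULL, write_images = FALSE,
                            keep_images = FALSE, overwrite = FALSE) {
  validate_synthetic_spec(spec)
  if (write_images || keep_images) render <- TRUE
  if (!is.null(output_dir)) {
    if (file.exists(file.path(output_dir, "manifest.csv")) && !overwrite)
      stop("output path collision: manifest.csv exists (use overwrite = TRUE)")
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  }
  seeds <- cohort_seeds(spec)
  idx <- 0L
  truth_all <- vector("list", length(seeds))
  manifest <- vector("list", length(seeds))
  cells <- if (keep_images) vector("list", length(seeds)) else NULL

  for (s in seq_len(spec$n_subjects)) {
    for (cc in seq_len(spec$cells_per_subject)) {
      idx <- idx + 1L
      cell_id <- sprintf("S%02d_C%03d", s, cc)
      cell <- simulate_cell(spec, seeds[idx], treated = treated,
                            channels = channels, render = render)
      tr <- cbind(cell_id = cell_id, subject = s, cell$truth)
      truth_all[[idx]] <- tr
      paths <- NA_character_
      if (!is.null(output_dir) && write_images) {
        paths <- vapply(names(cell$images), function(ch) {
          p <- file.path(output_dir, sprintf("%s_%s.tif", cell_id, ch))
          write_voxel_tiff(cell$images[[ch]], p)
          p
        }, character(1))
        paths <- paste(paths, collapse = ";")
      }
      manifest[[idx]] <- data.frame(cell_id = cell_id, subject = s,
                                    cell = cc, seed = seeds[idx],
                                    treated = treated, paths = paths)
      if (keep_images) cells[[idx]] <- cell
    }
  }
  truth <- do.call(rbind, truth_all)
  rownames(truth) <- NULL
  manifest <- do.call(rbind, manifest)
  if (!is.null(output_dir)) {
    write.csv(truth, file.path(output_dir, "ground_truth.csv"),
              row.names = FALSE)
    write.csv(manifest, file.path(output_dir, "manifest.csv"),
              row.names = FALSE)
  }
  out <- list(truth = truth, manifest = manifest, spec = spec)
  if (keep_images) out$cells <- cells
  out
}
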