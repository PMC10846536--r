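#' Run configuration
#'
#' Collects everything one pipeline run needs: file paths, analysis windows,
#' the inclusion threshold, the protocol z grid and sweep direction, and a
#' seed. All referenced files must exist at load time.
#'
#' @param movie,sync,rois Paths to the movie TIFF, sync CSV and ROI file.
#' @param out_dir Output directory (created if missing).
#' @param baseline_s,response_s Analysis windows, seconds.
#' @param inclusion_threshold dF/F inclusion threshold. Default 0.35.
#' @param z_offsets Protocol z offsets, um, sorted ascending.
#' @param direction Sweep direction of this acquisition.
#' @param frame_rate Frames per second.
#' @param opsf_condition Condition label carried into outputs.
#' @param control_rois Integer indices of ROIs that are controls (not
#'   photostimulated); excluded from the group curve.
#' @param seed Integer seed recorded in the log.
#' @return A validated `run_config` list.
#' @export
run_config <- function(movie, sync, rois, out_dir,
                       baseline_s = 1.5, response_s = 1.5,
                       inclusion_threshold = 0.35,
                       z_offsets = seq(-60, 60, by = 15),
                       direction = c("standard", "reverse"),
                       frame_rate = 30, opsf_condition = NA_character_,
                       control_rois = integer(), seed = 1L) {
  direction <- match.arg(direction)
  for (p in c(movie, sync, rois)) {
    if (!file.exists(p))
      rlang::abort(sprintf("Configured input does not exist: %s", p))
  }
  stopifnot(baseline_s > 0, response_s > 0, inclusion_threshold > 0,
            !is.unsorted(z_offsets), frame_rate > 0)
  structure(
    list(movie = movie, sync = sync, rois = rois, out_dir = out_dir,
         baseline_s = baseline_s, response_s = response_s,
         inclusion_threshold = inclusion_threshold,
         z_offsets = as.numeric(z_offsets), direction = direction,
         frame_rate = frame_rate, opsf_condition = opsf_condition,
         control_rois = as.integer(control_rois), seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file with the fields of `run_config()`; relative paths
#'   are resolved against the YAML file's directory.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  run_config(
    movie = resolve(cfg$movie), sync = resolve(cfg$sync),
    rois = resolve(cfg$rois),
    out_dir = if (is.null(cfg$out_dir)) file.path(base, "out")
              else resolve(cfg$out_dir),
    baseline_s = cfg$baseline_s %||% 1.5,
    response_s = cfg$response_s %||% 1.5,
    inclusion_threshold = cfg$inclusion_threshold %||% 0.35,
    z_offsets = unlist(cfg$z_offsets) %||% seq(-60, 60, by = 15),
    direction = cfg$direction %||% "standard",
    frame_rate = cfg$frame_rate %||% 30,
    opsf_condition = cfg$opsf_condition %||% NA_character_,
    control_rois = unlist(cfg$control_rois) %||% integer(),
    seed = cfg$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full movie-to-PPSF pipeline
#'
#' Loads the movie, sync trace and ROIs; locates trials from the frame clock
#' and stimulation gate; builds a per-neuron response curve for every
#' (non-control) ROI; applies the inclusion filter, max-alignment and (for
#' reverse acquisitions) flipping; combines included neurons into the
#' normalised group curve and measures its FWHM at half prominence. Writes
#' per-neuron and group curve CSVs, a stats JSON and a run log; rerunning
#' with identical inputs reproduces identical outputs.
#'
#' @param config A [run_config()] or the path to its YAML file.
#' @return Invisibly, a list with `curves`, `group`, `stats`, `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    sprintf("ppsftools %s", as.character(utils::packageVersion("ppsftools"))),
    sprintf("seed: %d", config$seed),
    sprintf("config hash: %s",
            rlang::hash(config[setdiff(names(config), "out_dir")])),
    sprintf("direction: %s  opsf_condition: %s", config$direction,
            as.character(config$opsf_condition))
  )
  movie <- load_movie(config$movie)
  sync <- read_sync(config$sync)
  rois <- load_rois(config$rois, frame_shape = dim(movie)[2:3])
  onsets <- detect_trial_onsets(sync)
  z_seq <- config$z_offsets
  if (config$direction == "reverse") z_seq <- rev(z_seq)
  n_per_z <- nrow(onsets) / length(z_seq)
  if (n_per_z != round(n_per_z))
    rlang::abort(sprintf(
      "Pipeline stage trial-matching failed: %d trials are not a multiple of %d z offsets.",
      nrow(onsets), length(z_seq)))
  trials <- dplyr::mutate(onsets, z_um = rep(z_seq, each = n_per_z))
  windows <- trial_windows(config$baseline_s, config$response_s)

  target_ids <- setdiff(seq_along(rois), config$control_rois)
  curves <- purrr::map(seq_along(rois), function(i) {
    build_response_curve(movie, rois[[i]], trials, windows,
                         frame_rate = config$frame_rate,
                         neuron_id = names(rois)[i],
                         direction = config$direction,
                         opsf_condition = config$opsf_condition)
  })
  names(curves) <- names(rois)

  included <- purrr::map_lgl(curves, inclusion_filter,
                             threshold = config$inclusion_threshold)
  for (i in seq_along(curves)) {
    log_lines <- c(log_lines, sprintf(
      "%s: max mean dF/F %.3f -> %s%s", names(curves)[i],
      max(curves[[i]]$mean_response),
      if (included[i]) "included" else
        sprintf("excluded (below %.2f dF/F at every z)",
                config$inclusion_threshold),
      if (i %in% config$control_rois) " [control]" else ""
    ))
  }

  use <- intersect(which(included), target_ids)
  processed <- purrr::map(curves[use], function(cv) {
    cv <- align_to_max(cv)
    if (identical(cv$direction, "reverse")) cv <- flip_reverse(cv)
    cv
  })

  curve_tbl <- purrr::imap_dfr(curves, function(cv, nm) {
    td <- tidy(cv)
    td$included <- included[[nm]]
    td$is_control <- match(nm, names(curves)) %in% config$control_rois
    td
  })

  group <- NULL
  stats_out <- list(
    n_rois = length(rois),
    n_targets = length(target_ids),
    n_included = length(use),
    inclusion_threshold_dff = config$inclusion_threshold,
    direction = config$direction,
    opsf_condition = config$opsf_condition,
    p_adjusted = "none"
  )
  if (length(processed) >= 1) {
    group <- combine_group(processed, normalize = TRUE, join = "union")
    stats_out$group_fwhm_um <- fwhm_half_prominence(group$z_um,
                                                    group$mean_response)
    stats_out$n_neurons <- max(group$n_neurons)
  }

  paths <- list(
    curves = file.path(config$out_dir, "neuron_curves.csv"),
    group = file.path(config$out_dir, "group_curve.csv"),
    stats = file.path(config$out_dir, "stats.json"),
    log = file.path(config$out_dir, "run.log")
  )
  utils::write.csv(curve_tbl, paths$curves, row.names = FALSE)
  if (!is.null(group))
    utils::write.csv(as.data.frame(group), paths$group, row.names = FALSE)
  jsonlite::write_json(stats_out, paths$stats, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, paths$log)
  invisible(list(curves = curves, group = group, stats = stats_out,
                 paths = paths))
}

#' Generate deterministic on-disk test datasets
#'
#' Writes a small, fully synthetic dataset for one of four scenarios:
#' `beads_small` / `beads_large` (bead z-stacks whose fitted axial FWHM is
#' 8.3 / 18.6 um), `cohort_null` (two movie acquisitions, one per OPSF
#' condition, equal-size cells), and `cohort_shifted_peak` (one neuron whose
#' soma sits 15 um below the imaging plane, so its curve peaks at +15 um).
#' Movies are reduced in frame count and field of view relative to a real
#' acquisition; geometry (z grid, trial structure, windows) is preserved.
#'
#' @param scenario One of the four scenario names.
#' @param seed Integer seed; identical seeds give identical files.
#' @param dir Output directory (created).
#' @return Invisibly, a named list of written file paths.
#' @export
make_fixtures <- function(scenario = c("beads_small", "beads_large",
                                       "cohort_null", "cohort_shifted_peak"),
                          seed = 1L, dir = tempfile("fixtures")) {
  scenario <- match.arg(scenario)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  small <- opsf_model(axial_fwhm = 8.3, lateral_fwhm = 1.2)
  large <- opsf_model(axial_fwhm = 18.6, lateral_fwhm = 1.8)
  if (scenario %in% c("beads_small", "beads_large")) {
    opsf <- if (scenario == "beads_small") small else large
    bs <- generate_bead_stack(opsf, n_beads = 3,
                              stack_shape = c(141, 96, 96),
                              photon_noise_scale = 0.5, read_noise_sd = 2,
                              seed = seed)
    paths$stack <- file.path(dir, "beads.tif")
    write_stack(bs$stack, paths$stack, axes = "Z",
                meta = list(z_step_um = bs$axial_step,
                            xy_px_um = bs$lateral_step))
    paths$truth <- file.path(dir, "bead_truth.csv")
    utils::write.csv(bs$centroids, paths$truth, row.names = FALSE)
  } else {
    write_cohort_member <- function(tag, opsf, cond, cell_z) {
      cells <- list(cell_spec(center = c(20, 20, cell_z)))
      protocol <- stim_protocol(inter_trial = 4)
      acq <- acquisition_spec(frame_shape = c(32, 32))
      sim <- simulate_experiment(cells, protocol, acq, opsf, seed = seed)
      p <- list()
      p$movie <- file.path(dir, paste0(tag, "_movie.tif"))
      write_stack(sim$movie, p$movie, axes = "T",
                  meta = list(frame_rate_hz = acq$frame_rate,
                              pixel_size_um = acq$pixel_size))
      p$sync <- file.path(dir, paste0(tag, "_sync.csv"))
      write_sync(sim$sync, p$sync)
      p$truth <- file.path(dir, paste0(tag, "_truth.csv"))
      utils::write.csv(sim$truth, p$truth, row.names = FALSE)
      lab <- matrix(0L, acq$frame_shape[1], acq$frame_shape[2])
      lab[sim$rois[[1]]] <- 1L
      p$rois <- file.path(dir, paste0(tag, "_rois.tif"))
      tiff::writeTIFF(lab / 65535, p$rois, bits.per.sample = 16,
                      compression = "none")
      p$config <- file.path(dir, paste0(tag, "_config.yaml"))
      yaml::write_yaml(list(
        movie = basename(p$movie), sync = basename(p$sync),
        rois = basename(p$rois),
        out_dir = paste0(tag, "_out"),
        frame_rate = acq$frame_rate, direction = "standard",
        opsf_condition = cond, seed = seed
      ), p$config)
      p
    }
    if (scenario == "cohort_null") {
      paths$large <- write_cohort_member("large", large, "large", 0)
      paths$small <- write_cohort_member("small", small, "small", 0)
    } else {
      paths$shifted <- write_cohort_member("shifted", large, "large", 15)
    }
  }
  invisible(paths)
}
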