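#' Photostimulation protocol
#'
#' The z-offset stepping protocol: 9 axial offsets from -60 to +60 um in
#' 15 um steps, three 250 ms spiral-scan trials per offset repeated every
#' 10 s, all trials at one offset before moving to the next. The sweep runs
#' in the `"standard"` (ascending, -60 to +60 um) or `"reverse"` (descending)
#' direction; directions are alternated across neurons in the emulated design
#' to control for opsin desensitisation. Note the sign convention for z is a
#' declaration (+z = focus deeper than the imaging plane), not a physical
#' calibration.
#'
#' @param z_offsets Photostimulation z offsets in um, sorted ascending.
#' @param trials_per_z Trials per offset. Default 3.
#' @param direction `"standard"` or `"reverse"`.
#' @param inter_trial Seconds between trial onsets. Default 10.
#' @param stim_duration Spiral stimulation duration, seconds. Default 0.25.
#' @param spiral_diameter Spiral diameter, um. Default 10.
#' @param spiral_revolutions Concentric revolutions per spiral. Default 5.
#' @param pre_onset Seconds from the start of a trial slot to stimulation
#'   onset; must leave >= 1.5 s of baseline. Default 2.
#' @return A `stim_protocol` object.
#' @export
stim_protocol <- function(z_offsets = seq(-60, 60, by = 15),
                          trials_per_z = 3,
                          direction = c("standard", "reverse"),
                          inter_trial = 10, stim_duration = 0.25,
                          spiral_diameter = 10, spiral_revolutions = 5,
                          pre_onset = 2) {
  direction <- match.arg(direction)
  stopifnot(length(z_offsets) >= 1, !is.unsorted(z_offsets),
            trials_per_z >= 1, inter_trial > 0, stim_duration > 0,
            spiral_diameter > 0, spiral_revolutions >= 1,
            pre_onset >= 1.5)
  structure(
    list(z_offsets = as.numeric(z_offsets), trials_per_z = as.integer(trials_per_z),
         direction = direction, inter_trial = inter_trial,
         stim_duration = stim_duration, spiral_diameter = spiral_diameter,
         spiral_revolutions = spiral_revolutions, pre_onset = pre_onset),
    class = "stim_protocol"
  )
}

#' Imaging acquisition parameters
#'
#' Resonant-scanning calcium imaging defaults: 30 Hz frame rate, 512 x 512
#' pixels at ~1.25 um/px. Noise is a Gaussian approximation to shot noise
#' (variance proportional to signal) plus additive read noise.
#'
#' @param frame_rate Frames per second. Default 30.
#' @param frame_shape Integer (rows, cols) in pixels. Default c(512, 512).
#' @param pixel_size um per pixel. Default 1.25.
#' @param photon_noise_scale Scale of the signal-dependent noise:
#'   sd = scale * sqrt(signal). 0 disables. Default 0.
#' @param read_noise_sd Additive Gaussian read-noise sd (a.u.). Default 0.
#' @param baseline_fluorescence Resting fluorescence inside a labelled cell
#'   (a.u.). Default 100.
#' @return An `acquisition_spec` object.
#' @export
acquisition_spec <- function(frame_rate = 30, frame_shape = c(512, 512),
                             pixel_size = 1.25, photon_noise_scale = 0,
                             read_noise_sd = 0, baseline_fluorescence = 100) {
  stopifnot(frame_rate > 0, length(frame_shape) == 2, all(frame_shape >= 1),
            pixel_size > 0, photon_noise_scale >= 0, read_noise_sd >= 0,
            baseline_fluorescence > 0)
  structure(
    list(frame_rate = frame_rate, frame_shape = as.integer(frame_shape),
         pixel_size = pixel_size, photon_noise_scale = photon_noise_scale,
         read_noise_sd = read_noise_sd,
         baseline_fluorescence = baseline_fluorescence),
    class = "acquisition_spec"
  )
}

# Trial schedule: one row per trial in acquisition order. Frame indices are
# 0-based (frame k spans [k/rate, (k+1)/rate)).
trial_schedule <- function(protocol, frame_rate) {
  z <- protocol$z_offsets
  if (protocol$direction == "reverse") z <- rev(z)
  zs <- rep(z, each = protocol$trials_per_z)
  i <- seq_along(zs)
  onset <- (i - 1) * protocol$inter_trial + protocol$pre_onset
  offset <- onset + protocol$stim_duration
  tibble::tibble(
    trial = i,
    z_um = zs,
    rep = rep(seq_len(protocol$trials_per_z), length.out = length(zs)),
    onset_s = onset,
    offset_s = offset,
    stim_start_frame = floor(onset * frame_rate),
    stim_end_frame = floor(offset * frame_rate)
  )
}

#' Simulate a photostimulation calcium-imaging experiment
#'
#' Renders a full movie (T x Y x X), the synchronisation record, and a
#' ground-truth table. Each trial adds a GCaMP transient to the pixels of
#' every targeted cell, with amplitude given by the Hill response to the
#' axial dose at that trial's z offset. Stimulation-period frames carry an
#' additive photostimulation artifact in the target pixels (there is no
#' artifact-reduction strategy; analysis windows simply exclude those
#' frames). Identical seeds give identical outputs.
#'
#' @param cells List of [cell_spec()] (x, y in um within the field of view;
#'   z relative to the imaging plane).
#' @param protocol A [stim_protocol()].
#' @param acq An [acquisition_spec()].
#' @param opsf An [opsf_model()].
#' @param seed Integer RNG seed.
#' @param post_window Seconds of recording required after the last
#'   stimulation ends. Default 1.6.
#' @param artifact_amplitude Additive artifact in target pixels during
#'   stimulation frames, in units of the cell baseline. Default 2.
#' @return A list with `movie` (T x Y x X array), `sync` (a [sync_record()]),
#'   `truth` (tibble: neuron_id, trial, z_um, rep, stim frames, dose,
#'   amplitude), `rois` (list of logical Y x X masks), `protocol`, `acq`.
#' @export
simulate_experiment <- function(cells, protocol = stim_protocol(),
                                acq = acquisition_spec(), opsf = opsf_model(18.6),
                                seed = 1L, post_window = 1.6,
                                artifact_amplitude = 2) {
  stopifnot(length(cells) >= 1)
  purrr::walk(cells, function(c) stopifnot(inherits(c, "cell_spec")))
  min_period <- protocol$pre_onset + protocol$stim_duration + post_window
  if (protocol$inter_trial < min_period)
    rlang::abort(sprintf(
      "inter_trial (%g s) too short for baseline + stimulation + response windows (%g s).",
      protocol$inter_trial, min_period))

  sched <- trial_schedule(protocol, acq$frame_rate)
  duration <- nrow(sched) * protocol$inter_trial
  n_frames <- ceiling(duration * acq$frame_rate)
  t_frames <- (seq_len(n_frames) - 1) / acq$frame_rate

  ny <- acq$frame_shape[1]; nx <- acq$frame_shape[2]
  rois <- purrr::map(cells, function(cl) cell_mask(cl, acq))

  # per-cell, per-trial dose and amplitude
  truth <- purrr::imap_dfr(cells, function(cl, id) {
    dose <- excitation_dose(opsf, cl, sched$z_um)
    amp <- amplitude_from_dose(dose, cl$response)
    dplyr::mutate(sched, neuron_id = id, dose = dose, amplitude = amp,
                  .before = 1)
  })

  # per-cell dF/F time course: sum of transients over trials
  cell_dff <- purrr::map(seq_along(cells), function(id) {
    tr <- truth[truth$neuron_id == id, ]
    dff <- numeric(n_frames)
    for (k in seq_len(nrow(tr))) {
      dff <- dff + tr$amplitude[k] *
        gcamp_kernel(t_frames - tr$onset_s[k], cells[[id]]$response)
    }
    dff
  })

  base <- acq$baseline_fluorescence
  movie <- array(base * 0.1, dim = c(n_frames, ny, nx)) # dim background
  artifact_frames <- unique(unlist(purrr::map2(
    sched$stim_start_frame, sched$stim_end_frame, function(a, b) a:b))) + 1L

  for (id in seq_along(cells)) {
    idx <- which(rois[[id]], arr.ind = TRUE)
    f_t <- base * (1 + cell_dff[[id]])
    for (r in seq_len(nrow(idx))) {
      movie[, idx[r, 1], idx[r, 2]] <- f_t
    }
  }
  # additive stimulation artifact in target pixels
  for (id in seq_along(cells)) {
    idx <- which(rois[[id]], arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      movie[artifact_frames, idx[r, 1], idx[r, 2]] <-
        movie[artifact_frames, idx[r, 1], idx[r, 2]] + artifact_amplitude * base
    }
  }

  if (acq$photon_noise_scale > 0 || acq$read_noise_sd > 0) {
    movie <- withr::with_seed(seed, {
      noise <- acq$photon_noise_scale * sqrt(pmax(movie, 0)) *
        stats::rnorm(length(movie)) +
        acq$read_noise_sd * stats::rnorm(length(movie))
      movie + array(noise, dim = dim(movie))
    })
  }

  sync <- make_sync_record(n_frames, acq$frame_rate, sched)

  list(movie = movie, sync = sync,
       truth = truth[, c("neuron_id", "trial", "z_um", "rep",
                         "stim_start_frame", "stim_end_frame",
                         "onset_s", "offset_s", "dose", "amplitude")],
       rois = rois, protocol = protocol, acq = acq, opsf = opsf)
}

# Logical Y x X mask of the pixels inside a cell's soma disk.
cell_mask <- function(cell, acq) {
  ny <- acq$frame_shape[1]; nx <- acq$frame_shape[2]
  px <- acq$pixel_size
  # pixel centers in um
  yc <- (seq_len(ny) - 0.5) * px
  xc <- (seq_len(nx) - 0.5) * px
  dy <- outer(yc - cell$center[2], rep(1, nx))
  dx <- outer(rep(1, ny), xc - cell$center[1])
  mask <- (dx^2 + dy^2) <= (cell$diameter / 2)^2
  if (!any(mask))
    rlang::abort("Cell footprint contains no pixel centers; check center/pixel_size.")
  mask
}

#' Fast-path simulation of per-neuron response curves
#'
#' Skips movie rendering: each neuron's trial response at each z offset is
#' the Hill response to the axial dose plus i.i.d. Gaussian trial noise.
#' Used for statistical property checks at scale. Trial ordering (standard
#' vs reverse sweep) does not enter this path.
#'
#' @inheritParams simulate_experiment
#' @param noise_sd Trial noise sd in dF/F units.
#' @return List of [response_curve()] objects, one per cell.
#' @export
simulate_response_curves <- function(cells, protocol = stim_protocol(),
                                     opsf = opsf_model(18.6),
                                     noise_sd = 0, seed = 1L) {
  stopifnot(length(cells) >= 1, noise_sd >= 0)
  z <- protocol$z_offsets
  nt <- protocol$trials_per_z
  withr::with_seed(seed, {
    purrr::imap(cells, function(cl, id) {
      dose <- excitation_dose(opsf, cl, z)
      amp <- amplitude_from_dose(dose, cl$response)
      resp <- matrix(rep(amp, nt), nrow = length(z), ncol = nt)
      if (noise_sd > 0)
        resp <- resp + matrix(stats::rnorm(length(resp), sd = noise_sd),
                              nrow = length(z))
      response_curve(z_um = z, responses = resp, neuron_id = id,
                     direction = protocol$direction)
    })
  })
}

#' Synchronisation record
#'
#' Digitised frame clock and stimulation gate, mirroring a voltage recording:
#' one rising edge of `frame_clock` per acquired frame, `stim_gate` high for
#' exactly each stimulation period.
#'
#' @param time_s Sample times, seconds.
#' @param frame_clock,stim_gate Binary (0/1) sample series.
#' @param sample_rate Samples per second.
#' @return A `sync_record` object.
#' @export
sync_record <- function(time_s, frame_clock, stim_gate, sample_rate) {
  stopifnot(length(time_s) == length(frame_clock),
            length(time_s) == length(stim_gate),
            all(frame_clock %in% c(0, 1)), all(stim_gate %in% c(0, 1)))
  structure(
    list(time_s = time_s, frame_clock = as.integer(frame_clock),
         stim_gate = as.integer(stim_gate), sample_rate = sample_rate),
    class = "sync_record"
  )
}

make_sync_record <- function(n_frames, frame_rate, sched, sample_rate = 1000) {
  duration <- n_frames / frame_rate
  n <- ceiling(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  # frame clock: short high pulse at the start of each frame
  clock <- integer(n)
  starts <- floor((seq_len(n_frames) - 1) / frame_rate * sample_rate) + 1L
  pulse <- max(1L, floor(sample_rate / frame_rate / 2))
  for (s in starts) clock[s:min(s + pulse - 1L, n)] <- 1L
  gate <- integer(n)
  for (k in seq_len(nrow(sched))) {
    a <- floor(sched$onset_s[k] * sample_rate) + 1L
    b <- floor(sched$offset_s[k] * sample_rate)
    gate[a:min(b, n)] <- 1L
  }
  sync_record(t, clock, gate, sample_rate)
}
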