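#' Trial analysis windows
#'
#' Defines the per-trial windows relative to the stimulation gate: a baseline
#' period before stimulation onset (for F0), a response period after
#' stimulation end, and the stimulation-period frames themselves, which carry
#' the photostimulation artifact and are excluded from both.
#'
#' @param baseline_s Baseline duration before onset, seconds. Default 1.5.
#' @param response_s Response duration after stimulation end, seconds.
#'   Default 1.5.
#' @return A `trial_windows` object.
#' @export
trial_windows <- function(baseline_s = 1.5, response_s = 1.5) {
  stopifnot(baseline_s > 0, response_s > 0)
  structure(list(baseline_s = baseline_s, response_s = response_s),
            class = "trial_windows")
}

#' Per-neuron axial response curve
#'
#' The PPSF measurement for one neuron: per-trial post-stimulation mean dF/F
#' at each photostimulation z offset.
#'
#' @param z_um Axial offsets, um, strictly increasing.
#' @param responses Numeric matrix, one row per z offset, one column per
#'   trial repeat (dF/F).
#' @param neuron_id Identifier.
#' @param direction `"standard"` or `"reverse"` sweep.
#' @param opsf_condition Optional condition label (e.g. "large", "small").
#' @param applied_shift_um Axial relabelling already applied, um. Default 0.
#' @return A `response_curve` object; `$mean_response` is the per-z mean
#'   across trials.
#' @export
response_curve <- function(z_um, responses, neuron_id = NA,
                           direction = c("standard", "reverse"),
                           opsf_condition = NA_character_,
                           applied_shift_um = 0) {
  direction <- match.arg(direction)
  responses <- as.matrix(responses)
  stopifnot(!is.unsorted(z_um, strictly = TRUE),
            nrow(responses) == length(z_um))
  structure(
    list(z_um = as.numeric(z_um), responses = responses,
         mean_response = rowMeans(responses),
         neuron_id = neuron_id, direction = direction,
         opsf_condition = opsf_condition,
         applied_shift_um = applied_shift_um),
    class = "response_curve"
  )
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf(
    "<response_curve> neuron %s, %d z offsets x %d trials, %s direction, shift %g um\n",
    as.character(x$neuron_id), length(x$z_um), ncol(x$responses),
    x$direction, x$applied_shift_um))
  print(tidy(x), ...)
  invisible(x)
}

#' @method tidy response_curve
#' @export
tidy.response_curve <- function(x, ...) {
  tibble::tibble(
    neuron_id = x$neuron_id,
    z_um = x$z_um,
    mean_dff = x$mean_response,
    n_trials = ncol(x$responses),
    direction = x$direction,
    applied_shift_um = x$applied_shift_um
  )
}

#' Locate stimulation trials in a synchronisation record
#'
#' Counts frame-clock rising edges to convert the stimulation gate edges into
#' acquisition frame indices. Frame indices are 0-based (frame k is the
#' (k+1)-th acquired frame); any frame overlapping the gate at all is an
#' artifact frame, so the trial spans `stim_start_frame:stim_end_frame`
#' inclusive.
#'
#' @param sync A [sync_record()].
#' @return Tibble `trial`, `stim_start_frame`, `stim_end_frame` (0-based).
#' @export
detect_trial_onsets <- function(sync) {
  stopifnot(inherits(sync, "sync_record"))
  clock_edges <- which(diff(c(0L, sync$frame_clock)) == 1L)
  if (length(clock_edges) == 0)
    rlang::abort("No frame-clock edges in the synchronisation record.")
  gate_up <- which(diff(c(0L, sync$stim_gate)) == 1L)
  gate_down <- which(diff(c(sync$stim_gate, 0L)) == -1L)
  if (length(gate_up) == 0)
    return(tibble::tibble(trial = integer(), stim_start_frame = integer(),
                          stim_end_frame = integer()))
  if (length(gate_up) != length(gate_down) || any(gate_down < gate_up))
    rlang::abort("Unpaired stimulation gate edges in the synchronisation record.")
  frame_of <- function(sample) {
    n <- findInterval(sample, clock_edges)
    if (any(n == 0))
      rlang::abort("Stimulation gate precedes the first acquired frame.")
    n - 1L  # 0-based frame index
  }
  tibble::tibble(
    trial = seq_along(gate_up),
    stim_start_frame = frame_of(gate_up),
    stim_end_frame = frame_of(gate_down)
  )
}

#' Normalised fluorescence change
#'
#' `dF/F = (F - F0) / F0` with `F0` the mean raw fluorescence over the
#' baseline frames.
#'
#' @param trace Raw fluorescence series.
#' @param baseline_frames Indices into `trace` defining the baseline.
#' @return dF/F series, same length as `trace`.
#' @export
compute_dff <- function(trace, baseline_frames) {
  stopifnot(length(baseline_frames) >= 1,
            all(baseline_frames >= 1), all(baseline_frames <= length(trace)))
  f0 <- mean(trace[baseline_frames])
  if (!is.finite(f0) || f0 <= 0)
    rlang::abort("Baseline F0 must be positive; the baseline window looks corrupt.")
  (trace - f0) / f0
}

#' Centred rolling average
#'
#' Centred moving mean with shrunken windows at the edges. Used for
#' time-series display only, never for trial statistics.
#'
#' @param series Numeric series.
#' @param window Odd window width in samples. Default 5.
#' @return Smoothed series, same length.
#' @export
rolling_average <- function(series, window = 5) {
  stopifnot(window >= 1)
  if (window %% 2 == 0) rlang::abort("`window` must be odd.")
  if (window == 1) return(series)
  zoo::rollapply(series, width = window, FUN = mean, partial = TRUE,
                 align = "center")
}

#' Scalar trial response
#'
#' Arithmetic mean dF/F over the response-window frames.
#'
#' @param dff dF/F series for one trial's frames.
#' @param response_frames Indices of the response window (artifact frames
#'   already excluded).
#' @return Mean dF/F (scalar).
#' @export
trial_response <- function(dff, response_frames) {
  if (length(response_frames) == 0)
    rlang::abort("Empty response window after artifact exclusion.")
  stopifnot(all(response_frames >= 1), all(response_frames <= length(dff)))
  mean(dff[response_frames])
}

# Frame-index windows for one trial; frames are 0-based in the trial table,
# returned 1-based for array indexing.
trial_frame_windows <- function(stim_start_frame, stim_end_frame,
                                frame_rate, windows, n_frames) {
  b0 <- stim_start_frame - round(windows$baseline_s * frame_rate)
  baseline <- seq(b0, stim_start_frame - 1L)
  response <- seq(stim_end_frame + 1L,
                  stim_end_frame + round(windows$response_s * frame_rate))
  baseline <- baseline[baseline >= 0]
  response <- response[response <= n_frames - 1L]
  if (length(baseline) == 0 || length(response) == 0)
    rlang::abort("Trial windows fall outside the recording.")
  list(baseline = baseline + 1L, response = response + 1L,
       artifact = seq(stim_start_frame, stim_end_frame) + 1L)
}

#' Build a per-neuron response curve from a movie
#'
#' For each trial: ROI-mean raw fluorescence per frame, dF/F against that
#' trial's baseline window, then the mean dF/F over the response window;
#' trial scalars are grouped by z offset and averaged across repeats. A
#' control ROI (same shape, drawn away from the target) is processed
#' identically by passing its mask as `roi`.
#'
#' @param movie T x Y x X numeric array.
#' @param roi Logical Y x X mask (non-empty).
#' @param trials Tibble with `z_um`, `stim_start_frame`, `stim_end_frame`
#'   (0-based frames), e.g. [detect_trial_onsets()] joined to the protocol's
#'   z sequence.
#' @param windows A [trial_windows()].
#' @param frame_rate Frames per second.
#' @param neuron_id,direction,opsf_condition Curve metadata.
#' @return A [response_curve()].
#' @export
build_response_curve <- function(movie, roi, trials, windows = trial_windows(),
                                 frame_rate = 30, neuron_id = NA,
                                 direction = "standard",
                                 opsf_condition = NA_character_) {
  stopifnot(is.array(movie), length(dim(movie)) == 3)
  if (!is.logical(roi) || !any(roi))
    rlang::abort("`roi` must be a non-empty logical mask.")
  if (!all(dim(roi) == dim(movie)[2:3]))
    rlang::abort("`roi` does not match the movie frame shape.")
  stopifnot(all(c("z_um", "stim_start_frame", "stim_end_frame") %in% names(trials)))
  n_frames <- dim(movie)[1]
  flat <- matrix(movie, nrow = n_frames)
  trace <- rowMeans(flat[, as.vector(roi), drop = FALSE])
  per_trial <- purrr::pmap_dbl(
    trials[, c("stim_start_frame", "stim_end_frame")],
    function(stim_start_frame, stim_end_frame) {
      w <- trial_frame_windows(stim_start_frame, stim_end_frame,
                               frame_rate, windows, n_frames)
      dff <- compute_dff(trace, w$baseline)
      trial_response(dff, w$response)
    })
  by_z <- split(per_trial, trials$z_um)
  z <- as.numeric(names(by_z))
  nt <- max(lengths(by_z))
  resp <- t(vapply(by_z, function(v) c(v, rep(NA_real_, nt - length(v))),
                   numeric(nt)))
  dimnames(resp) <- NULL
  ord <- order(z)
  rc <- response_curve(z_um = z[ord],
                       responses = resp[ord, , drop = FALSE],
                       neuron_id = neuron_id, direction = direction,
                       opsf_condition = opsf_condition)
  rc$mean_response <- rowMeans(rc$responses, na.rm = TRUE)
  rc
}

#' Responsiveness inclusion filter
#'
#' A neuron is included when its mean post-stimulation response reaches the
#' threshold at at least one axial position; otherwise the photostimulation
#' is deemed unsuccessful and the neuron is removed.
#'
#' @param curve A [response_curve()].
#' @param threshold Inclusion threshold in dF/F. Default 0.35.
#' @return Logical: include this neuron?
#' @export
inclusion_filter <- function(curve, threshold = 0.35) {
  stopifnot(inherits(curve, "response_curve"))
  max(curve$mean_response) >= threshold
}

#' Align a response curve to its maximum
#'
#' Relabels the z axis so the maximum-response offset sits at 0 um,
#' compensating for axial uncertainty about the true soma center. Ties are
#' broken toward the smaller-magnitude shift; an exact magnitude tie takes
#' the negative-z peak. A warning (not an error) is emitted when the shift
#' exceeds 15 um, one z step, since larger shifts indicate something other
#' than soma-position uncertainty.
#'
#' @param curve A [response_curve()].
#' @param warn_beyond_um Warning threshold on |shift|, um. Default 15.
#' @return The curve with relabelled `z_um` and `applied_shift_um` recorded.
#' @export
align_to_max <- function(curve, warn_beyond_um = 15) {
  stopifnot(inherits(curve, "response_curve"))
  m <- curve$mean_response
  peaks <- which(m == max(m))
  zp <- curve$z_um[peaks]
  pick <- order(abs(zp), zp)[1]  # smallest |z|, then negative first
  shift <- -zp[pick]
  if (abs(shift) > warn_beyond_um)
    rlang::warn(sprintf(
      "Curve for neuron %s shifted by %g um (> %g um, one z step).",
      as.character(curve$neuron_id), shift, warn_beyond_um))
  curve$z_um <- curve$z_um + shift
  curve$applied_shift_um <- curve$applied_shift_um + shift
  curve
}

#' Flip a reverse-direction curve onto the standard orientation
#'
#' Negates the z axis and reorders ascending so reverse-sweep curves can be
#' pooled with standard-sweep curves. Applying it to a standard-direction
#' curve is an error.
#'
#' @param curve A [response_curve()] with `direction == "reverse"`.
#' @return The flipped curve, relabelled `direction = "standard"` with
#'   attribute-like field `flipped = TRUE`.
#' @export
flip_reverse <- function(curve) {
  stopifnot(inherits(curve, "response_curve"))
  if (!identical(curve$direction, "reverse"))
    rlang::abort("`flip_reverse()` applies only to reverse-direction curves.")
  ord <- order(-curve$z_um)
  curve$z_um <- -curve$z_um[ord]
  curve$responses <- curve$responses[ord, , drop = FALSE]
  curve$mean_response <- curve$mean_response[ord]
  curve$applied_shift_um <- -curve$applied_shift_um
  curve$direction <- "standard"
  curve$flipped <- TRUE
  curve
}

#' Combine per-neuron curves into a group curve
#'
#' Optionally normalises each neuron's curve to its own maximum, then takes
#' the pointwise mean and normal-approximation 95% CI across neurons. With
#' `join = "strict"` (default) all curves must share the z grid exactly;
#' `join = "union"` averages over the union grid with per-z neuron counts,
#' which is what relabelled (max-aligned) curves require.
#'
#' @param curves List of [response_curve()] (all passed inclusion).
#' @param normalize Normalise each curve to its own max first. Default TRUE.
#' @param join `"strict"` or `"union"`.
#' @return A `group_curve` tibble: `z_um`, `mean_response`, `ci_lo`,
#'   `ci_hi`, `n_neurons`, with the per-neuron matrix in
#'   `attr(, "per_neuron")`.
#' @export
combine_group <- function(curves, normalize = TRUE,
                          join = c("strict", "union")) {
  join <- match.arg(join)
  stopifnot(length(curves) >= 1)
  purrr::walk(curves, function(c) stopifnot(inherits(c, "response_curve")))
  grids <- purrr::map(curves, "z_um")
  if (join == "strict") {
    same <- purrr::every(grids, function(g) isTRUE(all.equal(g, grids[[1]])))
    if (!same)
      rlang::abort(paste0(
        "Curves have mismatched z grids; align/flip first or use join = \"union\"."))
    z <- grids[[1]]
  } else {
    z <- sort(unique(unlist(grids)))
  }
  vals <- purrr::map(curves, function(cv) {
    v <- cv$mean_response
    if (normalize) v <- v / max(v)
    out <- rep(NA_real_, length(z))
    out[match(cv$z_um, z)] <- v
    out
  })
  mat <- do.call(rbind, vals)
  n <- colSums(!is.na(mat))
  mu <- colMeans(mat, na.rm = TRUE)
  se <- apply(mat, 2, function(col) {
    k <- sum(!is.na(col))
    if (k < 2) NA_real_ else stats::sd(col, na.rm = TRUE) / sqrt(k)
  })
  out <- tibble::tibble(
    z_um = z, mean_response = mu,
    ci_lo = mu - 1.96 * se, ci_hi = mu + 1.96 * se,
    n_neurons = n
  )
  attr(out, "per_neuron") <- mat
  attr(out, "normalized") <- normalize
  class(out) <- c("group_curve", class(out))
  out
}

#' @method glance group_curve
#' @export
glance.group_curve <- function(x, ...) {
  tibble::tibble(
    fwhm_um = fwhm_half_prominence(x$z_um, x$mean_response),
    n_neurons = max(x$n_neurons),
    peak_response = max(x$mean_response)
  )
}

#' Peak width at half prominence
#'
#' The group PPSF FWHM statistic: locate the global maximum; its prominence
#' is the peak height minus the higher of the two flanking minima (a curve
#' boundary counts as a base); the width is measured where a horizontal line
#' at `peak - prominence/2` intercepts the curve, with the crossings found
#' by linear interpolation between samples.
#'
#' @param z_positions Axial positions, um, increasing (>= 3 points).
#' @param values Curve values.
#' @return Width in um; `NA_real_` for flat or monotone curves (zero
#'   prominence or a boundary peak with no crossing on one side).
#' @export
fwhm_half_prominence <- function(z_positions, values) {
  stopifnot(length(z_positions) >= 3, length(values) == length(z_positions),
            !is.unsorted(z_positions, strictly = TRUE))
  i_max <- which.max(values)
  peak <- values[i_max]
  left_base <- if (i_max == 1) peak else min(values[1:i_max])
  right_base <- if (i_max == length(values)) peak
                else min(values[i_max:length(values)])
  prominence <- peak - max(left_base, right_base)
  if (prominence <= 0) return(NA_real_)
  half_width_at(z_positions, values, height = peak - prominence / 2)
}

#' Per-z two-sample comparison of two groups of neurons
#'
#' Welch two-sample t-test at each z position between the per-neuron
#' responses of two conditions, without multiple-testing correction (the
#' nine per-z tests are reported as-is; `p_adjusted = "none"` in the output
#' metadata flags this).
#'
#' @param group_a,group_b Numeric matrices, neurons x z positions (>= 2
#'   neurons each).
#' @param z_um Optional z labels (defaults to column index).
#' @param alpha Significance level recorded in the output. Default 0.05.
#' @return Tibble `z_um`, `t`, `df`, `p` (`NA` where both groups are
#'   degenerate/zero-variance), `significant`; attribute `p_adjusted = "none"`.
#' @export
compare_conditions <- function(group_a, group_b, z_um = NULL, alpha = 0.05) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  stopifnot(ncol(group_a) == ncol(group_b),
            nrow(group_a) >= 2, nrow(group_b) >= 2)
  if (is.null(z_um)) z_um <- seq_len(ncol(group_a))
  res <- purrr::map_dfr(seq_len(ncol(group_a)), function(j) {
    a <- group_a[, j]; b <- group_b[, j]
    tt <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                   error = function(e) NULL)
    if (is.null(tt))
      tibble::tibble(z_um = z_um[j], t = NA_real_, df = NA_real_, p = NA_real_)
    else
      tibble::tibble(z_um = z_um[j], t = unname(tt$statistic),
                     df = unname(tt$parameter), p = tt$p.value)
  })
  res$significant <- !is.na(res$p) & res$p < alpha
  attr(res, "p_adjusted") <- "none"
  res
}
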