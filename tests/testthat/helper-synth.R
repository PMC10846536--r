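# Shared fixture builders: everything is generated in code at test time.

opsf_small <- function() opsf_model(axial_fwhm = 8.3, lateral_fwhm = 1.2)
opsf_large <- function() opsf_model(axial_fwhm = 18.6, lateral_fwhm = 1.8)

# Small noiseless single-bead stack (8.3 um axial FWHM condition).
tiny_bead_stack <- function(opsf = opsf_small(), seed = 2, noisy = FALSE,
                            stack_shape = c(61, 64, 64)) {
  generate_bead_stack(
    opsf, n_beads = 1, stack_shape = stack_shape,
    photon_noise_scale = if (noisy) 0.5 else 0,
    read_noise_sd = if (noisy) 2 else 0,
    seed = seed
  )
}

# Reduced-scale movie experiment: real trial geometry (9 z offsets, 3
# trials) at a small field of view; inter-trial interval configurable so
# fast tests can trade transient carry-over for runtime.
tiny_experiment <- function(cells = list(cell_spec(center = c(20, 20, 0))),
                            opsf = opsf_large(), seed = 1,
                            inter_trial = 4, frame_shape = c(32, 32),
                            direction = "standard", ...) {
  simulate_experiment(
    cells,
    stim_protocol(inter_trial = inter_trial, direction = direction),
    acquisition_spec(frame_shape = frame_shape, ...),
    opsf, seed = seed
  )
}

# Expected noiseless trial response for every trial in a truth table:
# the full forward model, including transient tails carried over from
# earlier trials, evaluated at the frame times of the response window.
expected_trial_responses <- function(truth, frame_rate, n_frames,
                                     windows = trial_windows(),
                                     params = response_params()) {
  trace_dff <- function(t) {
    out <- numeric(length(t))
    for (i in seq_len(nrow(truth)))
      out <- out + truth$amplitude[i] * gcamp_kernel(t - truth$onset_s[i], params)
    out
  }
  vapply(seq_len(nrow(truth)), function(i) {
    w <- trial_windows_frames_for_test(truth$stim_start_frame[i],
                                       truth$stim_end_frame[i],
                                       frame_rate, windows, n_frames)
    t_resp <- (w$response - 1) / frame_rate
    t_base <- (w$baseline - 1) / frame_rate
    f0 <- mean(1 + trace_dff(t_base))
    mean((1 + trace_dff(t_resp)) / f0 - 1)
  }, numeric(1))
}

# 1-based frame windows, mirroring the package's window arithmetic but kept
# in the test code so the round trip is checked against an independent copy.
trial_windows_frames_for_test <- function(start0, end0, rate, windows,
                                          n_frames) {
  baseline <- seq(start0 - round(windows$baseline_s * rate), start0 - 1L)
  response <- seq(end0 + 1L, end0 + round(windows$response_s * rate))
  list(baseline = baseline[baseline >= 0] + 1L,
       response = response[response <= n_frames - 1L] + 1L)
}

# Bisection solver for the closed-form top-hat x Gaussian half width,
# written independently of erf_oracle_fwhm for the tests that need their
# own oracle.
oracle_half_curve <- function(fwhm, d, z) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  pnorm((z + d / 2) / s) - pnorm((z - d / 2) / s)
}
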