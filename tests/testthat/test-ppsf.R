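# Build a sync record directly: 30 Hz clock, arbitrary gate intervals.
make_test_sync <- function(gates, duration = 10, frame_rate = 30,
                           sample_rate = 1000) {
  n <- duration * sample_rate
  t <- (seq_len(n) - 1) / sample_rate
  clock <- integer(n)
  starts <- floor(seq(0, duration - 1 / frame_rate, by = 1 / frame_rate) *
                    sample_rate) + 1
  for (s in starts) clock[s:min(s + 10, n)] <- 1L
  gate <- integer(n)
  for (g in gates) gate[(g[1] * sample_rate + 1):(g[2] * sample_rate)] <- 1L
  sync_record(t, clock, gate, sample_rate)
}

test_that("trial onsets are located by counting frame-clock edges", {
  sync <- make_test_sync(list(c(1.50, 1.75)))
  on <- detect_trial_onsets(sync)
  expect_equal(on$stim_start_frame, 45)   # floor(1.50 * 30)
  expect_equal(on$stim_end_frame, 52)     # floor(1.75 * 30)
  empty <- detect_trial_onsets(make_test_sync(list()))
  expect_equal(nrow(empty), 0)
  # stimulation gate firing before the first acquired frame is rejected
  n <- 5000
  clock <- integer(n); clock[2000:2010] <- 1L   # imaging starts late
  gate <- integer(n); gate[500:600] <- 1L
  early <- sync_record((seq_len(n) - 1) / 1000, clock, gate, 1000)
  expect_error(detect_trial_onsets(early), "precedes the first")
  # multi-trial sync from the simulator matches the generator's log exactly
  sim <- tiny_experiment(seed = 8)
  on <- detect_trial_onsets(sim$sync)
  expect_equal(on$stim_start_frame, sim$truth$stim_start_frame)
  expect_equal(on$stim_end_frame, sim$truth$stim_end_frame)
})

test_that("dF/F is (F - F0)/F0 with mean-baseline F0, and is scale invariant", {
  expect_equal(compute_dff(c(10, 10, 10, 20), 1:3), c(0, 0, 0, 1))
  expect_equal(compute_dff(rep(7, 5), 1:2), rep(0, 5))
  expect_error(compute_dff(c(-1, -1, 3), 1:2), "positive")
  f <- c(80, 95, 100, 130, 120)
  expect_equal(compute_dff(3.7 * f, 1:2), compute_dff(f, 1:2))
})

test_that("rolling average is centred with shrunken edges", {
  expect_equal(rolling_average(rep(2, 10)), rep(2, 10))
  imp <- c(0, 0, 0, 0, 1, 0, 0, 0, 0)
  expect_equal(rolling_average(imp, 5)[3:7], rep(0.2, 5))
  expect_equal(rolling_average(imp, 1), imp)
  expect_error(rolling_average(imp, 4), "odd")
})

test_that("trial response is the mean over the response window", {
  expect_equal(trial_response(c(0.4, 0.6, 0.5), 1:3), 0.5)
  expect_equal(trial_response(rep(0, 5), 1:5), 0)
  expect_error(trial_response(1:5, integer()), "Empty response window")
})

test_that("build_response_curve averages ROI pixels and repeats per z", {
  # hand-built movie: 2 z offsets x 2 trials, constant plateau responses
  rate <- 10
  n_frames <- 160
  base <- 100
  amps <- c(0.8, 0.8, 0.3, 0.3)   # two trials at z=0 then two at z=15
  onsets <- c(2, 6, 10, 14) * rate          # 0-based onset frames
  movie <- array(base, dim = c(n_frames, 6, 6))
  roi <- matrix(FALSE, 6, 6); roi[2:4, 2:4] <- TRUE
  for (i in seq_along(onsets)) {
    resp_frames <- (onsets[i] + 3):(onsets[i] + 3 + 14) + 1
    movie[resp_frames, 2:4, 2:4] <- base * (1 + amps[i])
  }
  trials <- tibble::tibble(z_um = c(0, 0, 15, 15),
                           stim_start_frame = onsets,
                           stim_end_frame = onsets + 2)
  rc <- build_response_curve(movie, roi, trials, frame_rate = rate,
                             neuron_id = "n1")
  expect_equal(rc$z_um, c(0, 15))
  expect_equal(unname(rc$responses[1, ]), c(0.8, 0.8))
  expect_equal(unname(rc$responses[2, ]), c(0.3, 0.3))
  # control ROI far from the signal reads ~0 at every z
  ctrl <- matrix(FALSE, 6, 6); ctrl[6, 6] <- TRUE
  rc_ctrl <- build_response_curve(movie, ctrl, trials, frame_rate = rate)
  expect_equal(rc_ctrl$mean_response, c(0, 0))
  expect_error(build_response_curve(movie, matrix(FALSE, 6, 6), trials,
                                    frame_rate = rate), "non-empty")
})

test_that("responses fall off monotonically from a centred cell", {
  curves <- simulate_response_curves(list(cell_spec(center = c(20, 20, 0))),
                                     stim_protocol(), opsf_large())
  m <- curves[[1]]$mean_response
  i0 <- which(curves[[1]]$z_um == 0)
  expect_true(all(diff(m[1:i0]) > 0))
  expect_true(all(diff(m[i0:length(m)]) < 0))
})

test_that("inclusion filter applies the 0.35 dF/F threshold to the per-z mean", {
  z <- seq(-60, 60, by = 15)
  mk <- function(peak) response_curve(z, matrix(c(rep(0, 4), peak, rep(0, 4)),
                                                ncol = 1))
  expect_true(inclusion_filter(mk(0.35)))    # boundary: >= is included
  expect_false(inclusion_filter(mk(0.349)))
  expect_false(inclusion_filter(mk(0)))
  expect_true(inclusion_filter(mk(0.2), threshold = 0.1))
})

test_that("align_to_max relabels the peak to z = 0 with declared tie-breaking", {
  z <- seq(-60, 60, by = 15)
  v <- exp(-(z - 15)^2 / 500)
  rc <- response_curve(z, matrix(v, ncol = 1))
  al <- align_to_max(rc)
  expect_equal(al$applied_shift_um, -15)
  expect_equal(al$z_um, z - 15)
  expect_equal(which.max(al$mean_response), which(al$z_um == 0))
  # already centred: identity
  rc0 <- response_curve(z, matrix(exp(-z^2 / 500), ncol = 1))
  expect_equal(align_to_max(rc0)$applied_shift_um, 0)
  # tie between -15 and +15: negative-z peak wins, shift is +15
  vt <- c(0, 0, 0, 1, 0.5, 1, 0, 0, 0)
  tie <- align_to_max(response_curve(z, matrix(vt, ncol = 1)))
  expect_equal(tie$applied_shift_um, 15)
  # tie between 0 and +15: smaller magnitude wins
  vs <- c(0, 0, 0, 0.5, 1, 1, 0, 0, 0)
  expect_equal(align_to_max(response_curve(z, matrix(vs, ncol = 1)))$applied_shift_um, 0)
  # peak beyond one z step warns but still aligns
  vw <- exp(-(z - 45)^2 / 500)
  expect_warning(align_to_max(response_curve(z, matrix(vw, ncol = 1))),
                 "shifted by")
})

test_that("flip_reverse mirrors the z axis and is an involution on values", {
  z <- seq(-60, 60, by = 15)
  v <- seq(0.1, 0.9, length.out = 9)
  rc <- response_curve(z, matrix(v, ncol = 1), direction = "reverse")
  fl <- flip_reverse(rc)
  expect_equal(fl$mean_response, rev(v))
  expect_equal(fl$z_um, z)
  expect_equal(fl$direction, "standard")
  expect_error(flip_reverse(fl), "reverse-direction")
  # symmetric curve is unchanged by flipping
  sym <- response_curve(z, matrix(exp(-z^2 / 900), ncol = 1),
                        direction = "reverse")
  expect_equal(flip_reverse(sym)$mean_response, sym$mean_response)
})

test_that("combine_group normalises, averages, and rejects mismatched grids", {
  z <- seq(-60, 60, by = 15)
  v <- exp(-z^2 / 900)
  c1 <- response_curve(z, matrix(2 * v, ncol = 1), neuron_id = 1)
  c2 <- response_curve(z, matrix(5 * v, ncol = 1), neuron_id = 2)
  g <- combine_group(list(c1, c2))
  expect_equal(max(g$mean_response), 1)          # normalised peak
  expect_equal(g$mean_response, v / max(v))
  expect_equal(g$ci_lo, g$ci_hi)                 # identical curves: width 0
  g1 <- combine_group(list(c1))
  expect_true(all(is.na(g1$ci_lo)))
  shifted <- response_curve(z + 15, matrix(v, ncol = 1), neuron_id = 3)
  expect_error(combine_group(list(c1, shifted)), "mismatched z grids")
  gu <- combine_group(list(c1, shifted), join = "union")
  expect_equal(length(gu$z_um), 10)
  expect_equal(gu$n_neurons[gu$z_um == -60], 1)
  expect_equal(max(gu$n_neurons), 2)
})

test_that("group mean of noisy curves converges to the true shape", {
  z <- seq(-60, 60, by = 15)
  shape <- exp(-z^2 / (2 * 18^2))
  set.seed(9)
  curves <- lapply(1:100, function(i)
    response_curve(z, matrix(pmax(shape + rnorm(9, sd = 0.05), 1e-6), ncol = 1),
                   neuron_id = i))
  g <- combine_group(curves, normalize = FALSE)
  se <- 0.05 / sqrt(100)
  expect_true(all(abs(g$mean_response - shape) < 4 * se))
})

test_that("half-prominence FWHM interpolates crossings and fails on flat curves", {
  expect_equal(fwhm_half_prominence(c(-30, -15, 0, 15, 30),
                                    c(0, 0.5, 1, 0.5, 0)), 30)
  # Gaussian of FWHM 44 um on the 15 um grid: coarse-grid interpolation error
  z <- seq(-60, 60, by = 15)
  g44 <- exp(-z^2 / (2 * sigma_from_fwhm(44)^2))
  expect_equal(fwhm_half_prominence(z, g44), 44, tolerance = 1 / 44)
  # densely sampled Gaussian recovers its FWHM to 0.1%
  zd <- seq(-150, 150, by = 0.01)
  gd <- exp(-zd^2 / (2 * sigma_from_fwhm(44)^2))
  expect_equal(fwhm_half_prominence(zd, gd), 44, tolerance = 0.001)
  expect_true(is.na(fwhm_half_prominence(z, rep(1, 9))))
  expect_true(is.na(fwhm_half_prominence(z, seq(0, 1, length.out = 9))))
  # raised baseline: prominence, not absolute half max
  vr <- c(0.5, 0.5, 0.5, 0.75, 1, 0.75, 0.5, 0.5, 0.5)
  expect_equal(fwhm_half_prominence(z, vr), 30)  # half prominence at 0.75
})

test_that("per-z Welch comparison handles identical and degenerate groups", {
  a <- matrix(rep(c(0.2, 0.4, 0.6), 3), nrow = 3)
  res <- compare_conditions(a, a, z_um = c(-15, 0, 15))
  expect_equal(res$t, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
  expect_false(any(res$significant))
  degen <- compare_conditions(matrix(0, 3, 2), matrix(1, 3, 2))
  expect_true(all(is.na(degen$p)))
  expect_identical(attr(res, "p_adjusted"), "none")
})
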