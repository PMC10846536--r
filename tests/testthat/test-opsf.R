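test_that("detect_beads finds bead centroids to sub-voxel precision", {
  bs <- tiny_bead_stack(seed = 2)
  det <- detect_beads(bs$stack, min_separation = 5)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$z_um - bs$centroids$z_um), 0.5 * bs$axial_step)
  expect_lt(abs(det$y_um - bs$centroids$y_um), 0.5 * bs$lateral_step)
  expect_lt(abs(det$x_um - bs$centroids$x_um), 0.5 * bs$lateral_step)
})

test_that("detect_beads separates well-spaced beads and rejects empty stacks", {
  bs <- generate_bead_stack(opsf_small(), n_beads = 2,
                            stack_shape = c(91, 96, 96), seed = 4)
  sep <- dist(as.matrix(bs$centroids[, c("z_um", "y_um", "x_um")]))
  expect_gte(min(sep), 3 * 8.3)  # generator precondition
  det <- detect_beads(bs$stack, min_separation = 10)
  expect_equal(nrow(det), 2)
  expect_equal(nrow(detect_beads(array(0, c(5, 8, 8)))), 0)
  expect_equal(nrow(detect_beads(array(7, c(5, 8, 8)))), 0)
  expect_error(detect_beads(array(0, c(2, 8, 8))), "3 slices")
})

test_that("register_stack recovers injected drift and is idempotent", {
  bs <- tiny_bead_stack(seed = 2)
  kb <- which.max(apply(bs$stack, 1, max))
  signal <- apply(bs$stack, 1, max) - min(bs$stack) >
    0.1 * (max(bs$stack) - min(bs$stack))
  # aligned stack: all shifts ~ 0 where there is signal
  reg0 <- register_stack(bs$stack)
  expect_lt(max(abs(cbind(reg0$shifts$dy_px, reg0$shifts$dx_px))[signal, ]),
            0.05)
  # inject 0.2 px/slice lateral drift
  drifted <- bs$stack
  for (k in seq_len(dim(drifted)[1]))
    drifted[k, , ] <- ppsftools:::translate_bilinear(bs$stack[k, , ],
                                                     0.2 * (k - kb), 0)
  reg <- register_stack(drifted)
  expected <- -0.2 * (reg$shifts$slice - kb)
  expect_lt(max(abs(reg$shifts$dy_px - expected)[signal]), 0.1)
  reg2 <- register_stack(reg$stack)
  expect_lt(max(abs(cbind(reg2$shifts$dy_px, reg2$shifts$dx_px))[signal, ]),
            0.05)
})

test_that("extract_profile returns centred, unit-spaced profiles and checks bounds", {
  bs <- tiny_bead_stack(opsf_large(), seed = 6, stack_shape = c(141, 72, 72))
  det <- detect_beads(bs$stack, min_separation = 5)
  prof <- extract_profile(bs$stack, det[1, ], axis = "axial", half_window = 20)
  expect_lt(abs(prof$position_um[which.max(prof$intensity)]), 1)
  # FWHM 18.6 um at 1 um sampling: >= 18 samples above half max in [-10, 10]
  mid <- abs(prof$position_um) <= 10
  expect_gte(sum(prof$intensity[mid] > max(prof$intensity) / 2), 18)
  # 1-voxel aperture on noiseless data gives exact Gaussian samples
  p1 <- extract_profile(bs$stack, det[1, ], axis = "axial", half_window = 10,
                        aperture = 1)
  s <- sigma_from_fwhm(18.6)
  shape <- exp(-(p1$position_um + det$z_um[1] - bs$centroids$z_um)^2 /
                 (2 * s^2))
  # the single-voxel aperture sits a sub-voxel lateral offset from the bead
  # center, so the samples are the exact Gaussian times one constant
  scale <- (p1$intensity - 50) / shape
  expect_lt(stats::sd(scale) / mean(scale), 1e-6)
  expect_equal(mean(scale), 1000, tolerance = 0.02)
  expect_error(extract_profile(bs$stack, det[1, ], axis = "axial",
                               half_window = 500), "exceeds stack bounds")
})

test_that("fit_gaussian recovers exact samples and reports FWHM = 2.35482 sigma", {
  x <- seq(-15, 15, by = 1)
  y <- exp(-x^2 / (2 * 3.525^2))
  f <- fit_gaussian(tibble::tibble(position_um = x, intensity = y))
  expect_equal(f$mu, 0, tolerance = 1e-6)
  expect_equal(f$sigma, 3.525, tolerance = 1e-6 * 3.525)
  expect_equal(f$amplitude, 1, tolerance = 1e-6)
  expect_equal(f$offset, 0, tolerance = 1e-6)
  expect_true(f$usable)
  f1 <- fit_gaussian(tibble::tibble(position_um = x,
                                    intensity = exp(-x^2 / 2)))
  expect_equal(f1$fwhm, 2.35482, tolerance = 1e-5)
  expect_equal(tidy(f)$term, c("mu", "sigma", "amplitude", "offset"))
  expect_true(glance(f)$converged)
})

test_that("fit_gaussian is translation- and scale-equivariant", {
  x <- seq(-12, 12, by = 0.5)
  y <- 3 + 2 * exp(-(x - 1.2)^2 / (2 * 2.5^2))
  f <- fit_gaussian(tibble::tibble(position_um = x, intensity = y))
  fs <- fit_gaussian(tibble::tibble(position_um = x + 4, intensity = y))
  expect_equal(fs$mu, f$mu + 4, tolerance = 1e-6)
  expect_equal(fs$sigma, f$sigma, tolerance = 1e-6)
  fk <- fit_gaussian(tibble::tibble(position_um = x, intensity = 2.5 * y))
  expect_equal(fk$amplitude, 2.5 * f$amplitude, tolerance = 1e-6)
  expect_equal(fk$offset, 2.5 * f$offset, tolerance = 1e-6)
  expect_equal(fk$sigma, f$sigma, tolerance = 1e-6)
})

test_that("fit_gaussian returns a failure value distinct from a poor fit", {
  x <- seq(-10, 10, by = 1)
  flat <- fit_gaussian(tibble::tibble(position_um = x,
                                      intensity = rep(2, length(x))))
  expect_false(flat$converged)
  expect_true(is.na(flat$fwhm))
  # poor but converged fit is flagged unusable, not failed
  set.seed(42)
  noisy <- fit_gaussian(tibble::tibble(
    position_um = x,
    intensity = 0.05 * exp(-x^2 / 8) + rnorm(length(x), sd = 0.2)))
  if (noisy$converged) expect_false(noisy$usable)
})

test_that("noisy synthetic beads are recovered within 5% in both OPSF conditions", {
  errs <- vapply(1:6, function(s) {
    b <- tiny_bead_stack(opsf_small(), seed = s, noisy = TRUE)
    f <- fit_bead_stack(b$stack, axes = "axial")
    abs(f$fwhm[1] - 8.3) / 8.3
  }, numeric(1))
  expect_lt(median(errs), 0.05)
  errs_l <- vapply(1:6, function(s) {
    b <- tiny_bead_stack(opsf_large(), seed = s, noisy = TRUE,
                         stack_shape = c(141, 72, 72))
    f <- fit_bead_stack(b$stack, axes = "axial", half_window_axial = 25)
    abs(f$fwhm[1] - 18.6) / 18.6
  }, numeric(1))
  expect_lt(median(errs_l), 0.05)
})

test_that("summarize_opsf aggregates usable fits with a normal 95% CI", {
  fits <- tibble::tibble(
    bead_id = 1:3, axis = "axial",
    fwhm = c(8, 8.3, 8.6), usable = TRUE
  )
  s <- summarize_opsf(fits)
  expect_equal(s$mean_fwhm_um, 8.3)
  expect_equal(s$n_beads, 3)
  se <- sd(c(8, 8.3, 8.6)) / sqrt(3)
  expect_equal(s$ci_hi_um - s$ci_lo_um, 2 * 1.96 * se)
  # identical fits: zero-width CI
  s0 <- summarize_opsf(tibble::tibble(bead_id = 1:3, axis = "axial",
                                      fwhm = 8.3, usable = TRUE))
  expect_equal(s0$ci_lo_um, s0$ci_hi_um)
  # single fit: CI unavailable
  s1 <- summarize_opsf(tibble::tibble(bead_id = 1, axis = "axial",
                                      fwhm = 8.3, usable = TRUE))
  expect_true(is.na(s1$ci_lo_um))
  # unusable fits excluded and counted
  s2 <- summarize_opsf(tibble::tibble(bead_id = 1:4, axis = "axial",
                                      fwhm = c(8, 8.3, 8.6, 30),
                                      usable = c(TRUE, TRUE, TRUE, FALSE)))
  expect_equal(s2$mean_fwhm_um, 8.3)
  expect_equal(s2$n_excluded, 1)
  expect_error(summarize_opsf(tibble::tibble(bead_id = 1, axis = "axial",
                                             fwhm = 9, usable = FALSE)),
               "No usable")
})
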