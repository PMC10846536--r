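#' Generate a synthetic fluorescent-bead z-stack
#'
#' Renders sub-diffraction (0.2 um) beads as separable 3D Gaussians with the
#' OPSF's axial and lateral sigmas — a bead image is, to good approximation,
#' the PSF itself. Emulates the bead-imaging geometry used for PSF
#' estimation: 0.1 um lateral sampling, 1 um axial slice spacing. Noise is
#' the Gaussian shot-noise approximation (sd proportional to sqrt(signal))
#' plus additive read noise.
#'
#' @param opsf An [opsf_model()].
#' @param n_beads Number of beads to place. Default 1.
#' @param stack_shape Integer (Z, Y, X) in voxels.
#' @param axial_step um per z slice. Default 1.
#' @param lateral_step um per pixel. Default 0.1.
#' @param amplitude Peak bead intensity (a.u.). Default 1000.
#' @param background Constant background (a.u.). Default 50.
#' @param photon_noise_scale Shot-noise scale: sd = scale * sqrt(signal).
#'   Default 0 (noiseless).
#' @param read_noise_sd Additive Gaussian read-noise sd. Default 0.
#' @param seed Integer RNG seed (placement and noise).
#' @return List with `stack` (Z x Y x X array), `centroids` (tibble
#'   `bead_id`, `z_um`, `y_um`, `x_um`, ground truth, relative to the stack
#'   origin at voxel (1,1,1) center = 0), `axial_step`, `lateral_step`.
#' @export
generate_bead_stack <- function(opsf, n_beads = 1,
                                stack_shape = c(61, 64, 64),
                                axial_step = 1, lateral_step = 0.1,
                                amplitude = 1000, background = 50,
                                photon_noise_scale = 0, read_noise_sd = 0,
                                seed = 1L) {
  stopifnot(inherits(opsf, "opsf_model"), n_beads >= 1,
            length(stack_shape) == 3, axial_step > 0, lateral_step > 0)
  nz <- stack_shape[1]; ny <- stack_shape[2]; nx <- stack_shape[3]
  sz <- opsf$axial_sigma
  sl <- opsf$lateral_sigma
  z_extent <- (nz - 1) * axial_step
  xy_extent <- (min(ny, nx) - 1) * lateral_step
  if (z_extent < 6 * sz || xy_extent < 6 * sl)
    rlang::abort(sprintf(
      "Stack too small: need >= 6 sigma support (%.1f um axial, %.1f um lateral), have %.1f x %.1f um.",
      6 * sz, 6 * sl, z_extent, xy_extent))

  min_sep <- 3 * opsf$axial_fwhm
  withr::with_seed(seed, {
    # rejection-sample bead centers >= 3 axial FWHM apart, inside +/-3 sigma margins
    margin_z <- 3 * sz
    margin_l <- 3 * sl
    zr <- c(margin_z, z_extent - margin_z)
    yr <- c(margin_l, (ny - 1) * lateral_step - margin_l)
    xr <- c(margin_l, (nx - 1) * lateral_step - margin_l)
    if (zr[1] > zr[2] || yr[1] > yr[2] || xr[1] > xr[2])
      rlang::abort("Stack too small to contain a bead's +/-3 sigma support.")
    centers <- matrix(NA_real_, 0, 3)
    tries <- 0
    while (nrow(centers) < n_beads) {
      cand <- c(stats::runif(1, zr[1], zr[2]), stats::runif(1, yr[1], yr[2]),
                stats::runif(1, xr[1], xr[2]))
      ok <- nrow(centers) == 0 ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= min_sep)
      if (ok) centers <- rbind(centers, cand)
      tries <- tries + 1
      if (tries > 5000 * n_beads)
        rlang::abort("Could not place beads >= 3 axial FWHM apart in this stack.")
    }

    zs <- (seq_len(nz) - 1) * axial_step
    ys <- (seq_len(ny) - 1) * lateral_step
    xs <- (seq_len(nx) - 1) * lateral_step
    stack <- array(background, dim = c(nz, ny, nx))
    for (b in seq_len(n_beads)) {
      gz <- exp(-(zs - centers[b, 1])^2 / (2 * sz^2))
      gy <- exp(-(ys - centers[b, 2])^2 / (2 * sl^2))
      gx <- exp(-(xs - centers[b, 3])^2 / (2 * sl^2))
      # separable outer product, z-major
      stack <- stack + amplitude * outer(gz, outer(gy, gx))
    }
    if (photon_noise_scale > 0 || read_noise_sd > 0) {
      noise <- photon_noise_scale * sqrt(pmax(stack, 0)) *
        stats::rnorm(length(stack)) +
        read_noise_sd * stats::rnorm(length(stack))
      stack <- stack + array(noise, dim = dim(stack))
    }
    list(
      stack = stack,
      centroids = tibble::tibble(
        bead_id = seq_len(n_beads),
        z_um = centers[, 1], y_um = centers[, 2], x_um = centers[, 3]
      ),
      axial_step = axial_step, lateral_step = lateral_step
    )
  })
}
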