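#' Evaluation grid for the convolution model
#'
#' A regular axial grid, symmetric by construction of its endpoints, on which
#' OPSF and cell profiles are sampled. The grid must cover the support of both
#' factors: at least +/- 3 sigma of the widest Gaussian plus the largest cell
#' radius, or the convolution is truncated.
#'
#' @param z_min,z_max Grid extent in um.
#' @param spacing Grid spacing in um (> 0). Default 0.1 um.
#' @return A `model_grid` object; `$z` holds the sample positions.
#' @export
model_grid <- function(z_min = -80, z_max = 80, spacing = 0.1) {
  stopifnot(spacing > 0, z_max > z_min)
  z <- seq(z_min, z_max, by = spacing)
  structure(list(z = z, spacing = spacing, z_min = z_min, z_max = z_max),
            class = "model_grid")
}

#' Peak-normalised Gaussian axial profile
#'
#' Deterministic samples of a Gaussian centred at 0 with
#' sigma = fwhm / 2.3548, scaled to peak 1. This is the model's
#' representation of the OPSF axial intensity.
#'
#' @param fwhm FWHM in um (> 0).
#' @param grid A [model_grid()].
#' @return Numeric vector of profile values on `grid$z`.
#' @export
gaussian_profile <- function(fwhm, grid) {
  stopifnot(inherits(grid, "model_grid"))
  if (!is.numeric(fwhm) || length(fwhm) != 1L || fwhm <= 0)
    rlang::abort("`fwhm` must be a single positive number (um).")
  s <- sigma_from_fwhm(fwhm)
  if (grid$z_max < 2 * s || grid$z_min > -2 * s)
    rlang::abort("Grid is narrower than +/-2 sigma of the requested Gaussian.")
  exp(-grid$z^2 / (2 * s^2))
}

#' Binary square-wave (top-hat) cell profile
#'
#' The cell soma modelled as a sphere contributes a constant opsin-weighted
#' membrane area per unit z across its diameter, so its axial profile is a
#' binary square wave: 1 for |z| < diameter/2, 0 outside. A sample landing
#' exactly on an edge takes the jump midpoint value 0.5 — the standard
#' discretisation of a discontinuity, which keeps the discrete convolution
#' unbiased when edges coincide with grid points.
#'
#' @param diameter Cell diameter in um (>= 0).
#' @param grid A [model_grid()].
#' @return Numeric vector on `grid$z` with values in {0, 0.5, 1}.
#' @export
square_wave <- function(diameter, grid) {
  stopifnot(inherits(grid, "model_grid"))
  if (!is.numeric(diameter) || length(diameter) != 1L || diameter < 0)
    rlang::abort("`diameter` must be a single non-negative number (um).")
  r <- diameter / 2
  eps <- grid$spacing * 1e-9
  out <- as.numeric(abs(grid$z) < r - eps)
  out[abs(abs(grid$z) - r) <= eps] <- 0.5
  out
}

#' Convolve OPSF and cell profiles into a model PPSF profile
#'
#' Linear (full) discrete convolution of the two profiles, recentred onto the
#' input grid, then peak-normalised; optionally a centred moving average is
#' applied after normalisation. Smoothing is off by default because its effect
#' depends on the grid spacing; it is provided for reproducing smoothed plot
#' curves.
#'
#' @param gauss,square Profiles on the same grid (see [gaussian_profile()],
#'   [square_wave()]).
#' @param grid The shared [model_grid()].
#' @param smooth_window Centred moving-average width in samples (odd), or
#'   `NULL`/0 to skip smoothing. Default `NULL`.
#' @return Numeric profile on `grid$z`, peak value 1.
#' @export
convolve_normalize <- function(gauss, square, grid, smooth_window = NULL) {
  stopifnot(inherits(grid, "model_grid"))
  n <- length(grid$z)
  if (length(gauss) != n || length(square) != n)
    rlang::abort("`gauss` and `square` must be sampled on the same grid.")
  full <- stats::convolve(gauss, rev(square), type = "open")  # length 2n - 1
  # both factors are centred at z = 0 (grid midpoint), so the central n
  # samples of the full convolution live on the original grid
  mid <- (length(full) + 1L) %/% 2L
  centre <- (n + 1L) %/% 2L
  prof <- full[(mid - centre + 1L):(mid - centre + n)]
  prof <- pmax(prof, 0)
  if (max(prof) <= 0) rlang::abort("Convolution produced an all-zero profile.")
  prof <- prof / max(prof)
  if (!is.null(smooth_window) && smooth_window >= 2) {
    if (smooth_window %% 2 == 0)
      rlang::abort("`smooth_window` must be odd.")
    prof <- zoo::rollapply(prof, width = smooth_window, FUN = mean,
                           partial = TRUE, align = "center")
  }
  prof
}

#' FWHM of a unimodal model profile
#'
#' Width at half the peak value, with the half-height crossings located by
#' linear interpolation between the two samples that bracket them.
#'
#' @param profile Numeric profile values.
#' @param grid A [model_grid()] (or any object with `$z` positions).
#' @return FWHM in um, or `NA_real_` for flat profiles or peaks at the grid
#'   boundary (no bracketed crossing on one side).
#' @export
ppsf_fwhm <- function(profile, grid) {
  half_width_at(grid$z, profile, height = max(profile) / 2)
}

# Width of `values` about its global maximum at the given evaluation height,
# crossings by linear interpolation; NA when a side never crosses.
half_width_at <- function(positions, values, height) {
  i_max <- which.max(values)
  if (!is.finite(height) || max(values) == min(values)) return(NA_real_)
  if (i_max == 1L || i_max == length(values)) return(NA_real_)
  cross <- function(idx_out, idx_in) {
    # idx_out is below height, idx_in above (or equal)
    x0 <- positions[idx_out]; x1 <- positions[idx_in]
    y0 <- values[idx_out]; y1 <- values[idx_in]
    x0 + (height - y0) / (y1 - y0) * (x1 - x0)
  }
  left <- NA_real_
  for (i in seq(i_max, 2L)) {
    if (values[i - 1L] < height && values[i] >= height) {
      left <- cross(i - 1L, i); break
    }
  }
  right <- NA_real_
  for (i in seq(i_max, length(values) - 1L)) {
    if (values[i + 1L] < height && values[i] >= height) {
      right <- cross(i + 1L, i); break
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  right - left
}

#' Model PPSF FWHM as a function of cell diameter
#'
#' Runs the convolution model over a grid of OPSF FWHMs and cell diameters and
#' tabulates the resulting model PPSF FWHM. The `equality` column carries the
#' line-of-equality reference (PPSF FWHM = cell diameter) for plotting.
#'
#' @param opsf_fwhms Numeric vector of OPSF axial FWHMs (um).
#' @param diameters Numeric vector of cell diameters (um).
#' @param grid A [model_grid()]. Default 0.1 um spacing over +/-80 um.
#' @param smooth_window Passed to [convolve_normalize()]; default `NULL`
#'   (FWHM reported unsmoothed).
#' @return A tibble of class `model_curve` with columns `opsf_fwhm_um`,
#'   `diameter_um`, `ppsf_fwhm_um`, `equality_um`.
#' @examples
#' ppsf_vs_diameter(c(18.6, 8.3), diameters = c(0, 10, 20, 30))
#' @export
ppsf_vs_diameter <- function(opsf_fwhms, diameters,
                             grid = model_grid(), smooth_window = NULL) {
  stopifnot(length(opsf_fwhms) >= 1, length(diameters) >= 1)
  res <- purrr::map_dfr(opsf_fwhms, function(fw) {
    g <- gaussian_profile(fw, grid)
    purrr::map_dfr(diameters, function(d) {
      prof <- convolve_normalize(g, square_wave(d, grid), grid,
                                 smooth_window = smooth_window)
      tibble::tibble(
        opsf_fwhm_um = fw,
        diameter_um = d,
        ppsf_fwhm_um = ppsf_fwhm(prof, grid)
      )
    })
  })
  res$equality_um <- res$diameter_um
  class(res) <- c("model_curve", class(res))
  res
}

#' Diameter at which two OPSF conditions converge on the same PPSF
#'
#' Scans cell diameters and reports the smallest one where the absolute
#' difference between the model PPSF FWHMs of the two OPSF conditions is at
#' most `tolerance` and remains so for every larger scanned diameter.
#'
#' @param fwhm_a,fwhm_b The two OPSF axial FWHMs (um), distinct.
#' @param tolerance Convergence tolerance in um (> 0).
#' @param diameters Diameter scan grid (um). Default 0 to 50 um, step 1.
#' @param grid A [model_grid()].
#' @return Convergence diameter in um; `NA_real_` (with a warning reporting
#'   the scan range) if the curves never converge within the scan.
#' @export
convergence_diameter <- function(fwhm_a, fwhm_b, tolerance = 2,
                                 diameters = seq(0, 50, by = 1),
                                 grid = model_grid()) {
  stopifnot(tolerance > 0)
  if (isTRUE(all.equal(fwhm_a, fwhm_b))) return(min(diameters))
  curves <- ppsf_vs_diameter(c(fwhm_a, fwhm_b), diameters, grid = grid)
  wide <- tidyr::pivot_wider(curves[, 1:3], names_from = "opsf_fwhm_um",
                             values_from = "ppsf_fwhm_um")
  gap <- abs(wide[[2]] - wide[[3]])
  ok <- rev(cumall(rev(gap <= tolerance)))
  if (!any(ok)) {
    rlang::warn(sprintf(
      "No convergence below %g um within diameters [%g, %g] um.",
      tolerance, min(diameters), max(diameters)))
    return(NA_real_)
  }
  wide$diameter_um[which(ok)[1L]]
}

cumall <- function(x) cumprod(as.numeric(x)) > 0

#' Closed-form oracle for the Gaussian x top-hat FWHM
#'
#' The convolution of a unit top-hat of width `d` with a Gaussian of standard
#' deviation sigma is `C(z) = Phi((z + d/2)/sigma) - Phi((z - d/2)/sigma)`.
#' This solves `C(z) = C(0)/2` for z by bisection (tolerance 1e-6 um) and
#' returns the doubled root — an implementation of the model PPSF FWHM that is
#' independent of the discrete convolution pipeline, used to cross-validate it.
#'
#' @param gauss_fwhm Gaussian FWHM in um (> 0).
#' @param diameter Top-hat width in um (>= 0).
#' @return FWHM in um.
#' @export
erf_oracle_fwhm <- function(gauss_fwhm, diameter) {
  stopifnot(gauss_fwhm > 0, diameter >= 0)
  if (diameter == 0) return(gauss_fwhm)
  s <- sigma_from_fwhm(gauss_fwhm)
  C <- function(z) stats::pnorm((z + diameter / 2) / s) -
    stats::pnorm((z - diameter / 2) / s)
  half <- C(0) / 2
  lo <- 0
  hi <- diameter / 2 + 6 * s
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (C(mid) > half) lo <- mid else hi <- mid
  }
  2 * (lo + hi) / 2
}
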