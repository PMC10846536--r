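#' Detect beads in a z-stack
#'
#' Candidate voxels are local maxima (26-neighbourhood) whose intensity
#' exceeds the given quantile of the stack; candidates are non-maximum
#' suppressed within `min_separation` (brightest first) and refined to
#' sub-voxel precision by intensity center of mass in a local window.
#'
#' @param stack Z x Y x X numeric array.
#' @param min_separation Minimum distance between detections, um.
#' @param intensity_quantile Threshold quantile in (0, 1). Default 0.999.
#' @param axial_step,lateral_step Voxel spacing, um.
#' @param com_radius Center-of-mass window half-size in voxels. Default 2.
#' @return Tibble `bead_id`, `z_um`, `y_um`, `x_um` (origin at the center of
#'   voxel (1,1,1)); zero rows when nothing exceeds the threshold or the
#'   stack is constant.
#' @export
detect_beads <- function(stack, min_separation = 5, intensity_quantile = 0.999,
                         axial_step = 1, lateral_step = 0.1, com_radius = 2) {
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  if (dim(stack)[1] < 3) rlang::abort("Stack must have >= 3 slices.")
  empty <- tibble::tibble(bead_id = integer(), z_um = numeric(),
                          y_um = numeric(), x_um = numeric())
  if (max(stack) == min(stack)) return(empty)
  thr <- stats::quantile(stack, intensity_quantile, names = FALSE)
  is_max <- local_maxima_3d(stack)
  cand <- which(is_max & stack > thr, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  vals <- stack[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  sp <- c(axial_step, lateral_step, lateral_step)
  kept <- matrix(NA_real_, 0, 3)
  for (i in seq_len(nrow(cand))) {
    p <- (cand[i, ] - 1) * sp
    if (nrow(kept) == 0 ||
        all(sqrt(rowSums(sweep(kept, 2, p)^2)) >= min_separation)) {
      kept <- rbind(kept, p)
    }
  }
  # sub-voxel refinement by center of mass in a local window
  dims <- dim(stack)
  ref <- t(apply(kept, 1, function(p) {
    v <- round(p / sp) + 1
    lo <- pmax(v - com_radius, 1)
    hi <- pmin(v + com_radius, dims)
    sub <- stack[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    sub <- sub - min(sub)
    if (sum(sub) == 0) return(p)
    w <- sum(sub)
    zi <- (lo[1]:hi[1]) - 1
    yi <- (lo[2]:hi[2]) - 1
    xi <- (lo[3]:hi[3]) - 1
    c(sum(apply(sub, 1, sum) * zi) / w * sp[1],
      sum(apply(sub, 2, sum) * yi) / w * sp[2],
      sum(apply(sub, 3, sum) * xi) / w * sp[3])
  }))
  tibble::tibble(bead_id = seq_len(nrow(ref)),
                 z_um = ref[, 1], y_um = ref[, 2], x_um = ref[, 3])
}

# 26-neighbourhood strict local maxima of a 3D array (borders excluded).
local_maxima_3d <- function(a) {
  d <- dim(a)
  res <- array(TRUE, dim = d)
  shifts <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  shifts <- shifts[!(shifts$dz == 0 & shifts$dy == 0 & shifts$dx == 0), ]
  iz <- 2:(d[1] - 1); iy <- 2:(d[2] - 1); ix <- 2:(d[3] - 1)
  core <- a[iz, iy, ix, drop = FALSE]
  keep <- array(TRUE, dim = dim(core))
  for (k in seq_len(nrow(shifts))) {
    nb <- a[iz + shifts$dz[k], iy + shifts$dy[k], ix + shifts$dx[k],
            drop = FALSE]
    keep <- keep & (core > nb)
  }
  out <- array(FALSE, dim = d)
  out[iz, iy, ix] <- keep
  out
}

#' Register a z-stack by per-slice lateral translation
#'
#' Aligns every slice to the brightest slice by maximising their
#' cross-correlation (FFT-based), with sub-pixel refinement by parabolic
#' interpolation of the correlation peak, and applies the shifts with
#' bilinear interpolation. Removes apparent tilt in a bead's axial profile
#' caused by lateral drift through the stack.
#'
#' @param stack Z x Y x X numeric array with >= 2 slices.
#' @return List with `stack` (registered array) and `shifts` (tibble
#'   `slice`, `dy_px`, `dx_px` — the shift that was applied).
#' @export
register_stack <- function(stack) {
  stopifnot(is.array(stack), length(dim(stack)) == 3, dim(stack)[1] >= 2)
  nz <- dim(stack)[1]
  bright <- which.max(apply(stack, 1, max))
  ref <- stack[bright, , ]
  shifts <- matrix(0, nz, 2)
  out <- stack
  for (k in seq_len(nz)) {
    if (k == bright) next
    sh <- xcorr_shift(ref, stack[k, , ])
    shifts[k, ] <- sh
    out[k, , ] <- translate_bilinear(stack[k, , ], sh[1], sh[2])
  }
  list(stack = out,
       shifts = tibble::tibble(slice = seq_len(nz),
                               dy_px = shifts[, 1], dx_px = shifts[, 2]))
}

# Shift (dy, dx) that moves `img` onto `ref`, by cross-correlation peak with
# parabolic sub-pixel interpolation.
xcorr_shift <- function(ref, img) {
  d <- dim(ref)
  a <- ref - mean(ref)
  b <- img - mean(img)
  if (sum(abs(a)) == 0 || sum(abs(b)) == 0) return(c(0, 0))
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  sub <- function(axis, i) {
    n <- d[axis]
    im <- function(j) ((j - 1) %% n) + 1
    if (axis == 1) y <- c(cc[im(i - 1), pk[2]], cc[i, pk[2]], cc[im(i + 1), pk[2]])
    else y <- c(cc[pk[1], im(i - 1)], cc[pk[1], i], cc[pk[1], im(i + 1)])
    den <- y[1] - 2 * y[2] + y[3]
    if (den == 0) 0 else 0.5 * (y[1] - y[3]) / den
  }
  wrap <- function(i, n) { v <- i - 1; if (v > n / 2) v - n else v }
  dy <- wrap(pk[1], d[1]) + sub(1, pk[1])
  dx <- wrap(pk[2], d[2]) + sub(2, pk[2])
  c(dy, dx)
}

# Bilinear translation of a matrix by (dy, dx) pixels; out-of-range samples
# take the image edge value.
translate_bilinear <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  ys <- pmin(pmax(seq_len(ny) - dy, 1), ny)
  xs <- pmin(pmax(seq_len(nx) - dx, 1), nx)
  y0 <- floor(ys); y1 <- pmin(y0 + 1, ny); fy <- ys - y0
  x0 <- floor(xs); x1 <- pmin(x0 + 1, nx); fx <- xs - x0
  wy0 <- (1 - fy); wy1 <- fy
  m00 <- m[y0, x0, drop = FALSE]; m01 <- m[y0, x1, drop = FALSE]
  m10 <- m[y1, x0, drop = FALSE]; m11 <- m[y1, x1, drop = FALSE]
  wy0 * (sweep(m00, 2, 1 - fx, `*`) + sweep(m01, 2, fx, `*`)) +
    wy1 * (sweep(m10, 2, 1 - fx, `*`) + sweep(m11, 2, fx, `*`))
}

#' Extract a 1D intensity profile through a bead
#'
#' Intensity along one axis through the bead centroid, averaged over a small
#' aperture in the perpendicular directions to reduce noise. Positions are
#' in um relative to the centroid.
#'
#' @param stack Z x Y x X numeric array.
#' @param centroid Named or positional (z_um, y_um, x_um) bead position (as
#'   from [detect_beads()]).
#' @param axis One of `"axial"`, `"lateral_x"`, `"lateral_y"`.
#' @param half_window Profile half-length in um.
#' @param axial_step,lateral_step Voxel spacing, um.
#' @param aperture Aperture full width in voxels (odd). Default 3.
#' @return A `bead_profile` object: tibble with `position_um`,
#'   `intensity`, plus attributes `axis` and `centroid`.
#' @export
extract_profile <- function(stack, centroid,
                            axis = c("axial", "lateral_x", "lateral_y"),
                            half_window = 20, axial_step = 1,
                            lateral_step = 0.1, aperture = 3) {
  axis <- match.arg(axis)
  stopifnot(is.array(stack), length(dim(stack)) == 3, aperture %% 2 == 1)
  cen <- as.numeric(centroid[c("z_um", "y_um", "x_um")])
  if (anyNA(cen)) cen <- as.numeric(centroid)[1:3]
  sp <- c(axial_step, lateral_step, lateral_step)
  vox <- round(cen / sp) + 1
  d <- dim(stack)
  ax_i <- switch(axis, axial = 1L, lateral_y = 2L, lateral_x = 3L)
  half_vox <- round(half_window / sp[ax_i])
  lo <- vox[ax_i] - half_vox
  hi <- vox[ax_i] + half_vox
  if (lo < 1 || hi > d[ax_i])
    rlang::abort(sprintf(
      "Profile window [%d, %d] exceeds stack bounds [1, %d] along the %s axis.",
      lo, hi, d[ax_i], axis))
  ap <- (aperture - 1L) %/% 2L
  other <- setdiff(1:3, ax_i)
  rng <- function(j) max(1, vox[j] - ap):min(d[j], vox[j] + ap)
  idx <- list(NULL, NULL, NULL)
  idx[[ax_i]] <- lo:hi
  idx[[other[1]]] <- rng(other[1])
  idx[[other[2]]] <- rng(other[2])
  sub <- stack[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  intensity <- apply(sub, which(1:3 == ax_i), mean)
  pos <- ((lo:hi) - 1) * sp[ax_i] - cen[ax_i]
  structure(
    tibble::tibble(position_um = pos, intensity = as.numeric(intensity)),
    axis = axis, centroid = cen,
    class = c("bead_profile", class(tibble::tibble()))
  )
}

#' Fit a 1D Gaussian to a bead profile
#'
#' Bounded least squares of `offset + amplitude * exp(-(x - mu)^2 / (2 sigma^2))`
#' via [minpack.lm::nlsLM()], initialised from moments (mu at the profile
#' maximum, sigma from the second moment of the background-subtracted
#' intensities). The fit is flagged unusable when R^2 falls below
#' `r2_threshold`, replacing manual inspection of fit quality. Non-convergence
#' or a constant profile returns a failure value (all-`NA` fit with
#' `converged = FALSE`), distinct from a converged-but-poor fit.
#'
#' @param profile A [bead_profile][extract_profile()] or any data frame with
#'   `position_um` and `intensity` columns (>= 5 rows, strictly increasing
#'   positions).
#' @param r2_threshold Minimum R^2 for a usable fit. Default 0.9.
#' @return A `gaussian_fit` object: list with `mu`, `sigma`, `amplitude`,
#'   `offset`, `fwhm`, `r2`, `usable`, `converged`.
#' @export
fit_gaussian <- function(profile, r2_threshold = 0.9) {
  x <- profile$position_um
  y <- profile$intensity
  stopifnot(length(x) >= 5, !is.unsorted(x, strictly = TRUE))
  fail <- structure(
    list(mu = NA_real_, sigma = NA_real_, amplitude = NA_real_,
         offset = NA_real_, fwhm = NA_real_, r2 = NA_real_,
         usable = FALSE, converged = FALSE),
    class = "gaussian_fit"
  )
  if (max(y) == min(y)) return(fail)
  off0 <- min(y)
  amp0 <- max(y) - off0
  mu0 <- x[which.max(y)]
  w <- pmax(y - off0, 0)
  sig0 <- sqrt(sum(w * (x - mu0)^2) / sum(w))
  rng <- diff(range(x))
  spacing <- stats::median(diff(x))
  sig_lo <- 0.2 * spacing
  sig_hi <- 2 * rng
  sig0 <- min(max(sig0, sig_lo * 1.01), sig_hi * 0.99)
  gauss <- function(p) p[1] + p[2] * exp(-(x - p[3])^2 / (2 * p[4]^2))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(offset = off0, amplitude = amp0, mu = mu0, sigma = sig0),
      fn = function(p) y - gauss(p),
      lower = c(-Inf, 0, min(x), sig_lo),
      upper = c(Inf, Inf, max(x), sig_hi),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  # info codes 1-4 are convergence; 0 and 5+ are failures
  if (is.null(fit) || !(fit$info %in% 1:4)) return(fail)
  co <- fit$par
  resid <- y - gauss(co)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  structure(
    list(mu = unname(co["mu"]), sigma = unname(co["sigma"]),
         amplitude = unname(co["amplitude"]), offset = unname(co["offset"]),
         fwhm = fwhm_from_sigma(unname(co["sigma"])), r2 = r2,
         usable = r2 >= r2_threshold, converged = TRUE),
    class = "gaussian_fit"
  )
}

#' @export
print.gaussian_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<gaussian_fit> failed (no convergence or degenerate profile)\n")
  } else {
    cat(sprintf(
      "<gaussian_fit> mu %.3f um, sigma %.3f um (FWHM %.3f um), amp %.3g, offset %.3g, R2 %.4f%s\n",
      x$mu, x$sigma, x$fwhm, x$amplitude, x$offset, x$r2,
      if (x$usable) "" else " [unusable]"
    ))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy gaussian_fit
#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mu", "sigma", "amplitude", "offset"),
    estimate = c(x$mu, x$sigma, x$amplitude, x$offset)
  )
}

#' @method glance gaussian_fit
#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble::tibble(fwhm = x$fwhm, r.squared = x$r2, usable = x$usable,
                 converged = x$converged)
}

#' Summarise bead fits into an OPSF estimate
#'
#' Mean FWHM and normal-approximation 95% CI per axis across usable bead
#' fits; unusable fits are excluded and counted. The summary FWHM is the
#' mean of per-bead fitted FWHMs.
#'
#' @param fits A data frame with columns `bead_id`, `axis`, and either
#'   a `fit` list-column of [gaussian_fit][fit_gaussian()] objects or the
#'   flat columns `fwhm`, `usable`.
#' @return An `opsf_summary` tibble: one row per axis with `mean_fwhm_um`,
#'   `ci_lo_um`, `ci_hi_um` (NA for a single bead), `n_beads`,
#'   `n_excluded`.
#' @export
summarize_opsf <- function(fits) {
  if ("fit" %in% names(fits)) {
    fits <- dplyr::mutate(fits,
      fwhm = purrr::map_dbl(.data$fit, "fwhm"),
      usable = purrr::map_lgl(.data$fit, "usable")
    )
  }
  stopifnot(all(c("axis", "fwhm", "usable") %in% names(fits)))
  if (!any(fits$usable))
    rlang::abort("No usable fits to summarise.")
  out <- fits |>
    dplyr::group_by(.data$axis) |>
    dplyr::summarise(
      n_excluded = sum(!.data$usable),
      n_beads = sum(.data$usable),
      mean_fwhm_um = mean(.data$fwhm[.data$usable]),
      se = stats::sd(.data$fwhm[.data$usable]) / sqrt(.data$n_beads),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ci_lo_um = .data$mean_fwhm_um - 1.96 * .data$se,
      ci_hi_um = .data$mean_fwhm_um + 1.96 * .data$se
    ) |>
    dplyr::select("axis", "mean_fwhm_um", "ci_lo_um", "ci_hi_um",
                  "n_beads", "n_excluded")
  class(out) <- c("opsf_summary", class(out))
  out
}

#' Fit every detected bead in a stack along the requested axes
#'
#' Convenience wrapper: [detect_beads()], then [extract_profile()] and
#' [fit_gaussian()] per bead and axis.
#'
#' @inheritParams detect_beads
#' @param axes Character vector of axes to fit.
#' @param half_window_axial,half_window_lateral Profile half-windows, um.
#' @param ... Passed to [fit_gaussian()].
#' @return Tibble with `bead_id`, `axis`, `fit` (list-column), `fwhm`,
#'   `r2`, `usable`.
#' @export
fit_bead_stack <- function(stack, axial_step = 1, lateral_step = 0.1,
                           axes = c("axial", "lateral_x"),
                           min_separation = 5, intensity_quantile = 0.999,
                           half_window_axial = 20, half_window_lateral = 2.5,
                           ...) {
  beads <- detect_beads(stack, min_separation = min_separation,
                        intensity_quantile = intensity_quantile,
                        axial_step = axial_step, lateral_step = lateral_step)
  if (nrow(beads) == 0)
    return(tibble::tibble(bead_id = integer(), axis = character(),
                          fit = list(), fwhm = numeric(), r2 = numeric(),
                          usable = logical()))
  tidyr::expand_grid(bead_id = beads$bead_id, axis = axes) |>
    dplyr::mutate(
      fit = purrr::map2(.data$bead_id, .data$axis, function(b, ax) {
        hw <- if (ax == "axial") half_window_axial else half_window_lateral
        cen <- beads[beads$bead_id == b, ]
        # shrink the window so it stays inside the stack for edge-ward beads
        sp <- if (ax == "axial") axial_step else lateral_step
        ax_len <- switch(ax, axial = dim(stack)[1], lateral_y = dim(stack)[2],
                         lateral_x = dim(stack)[3])
        cen_um <- switch(ax, axial = cen$z_um, lateral_y = cen$y_um,
                         lateral_x = cen$x_um)
        hw <- min(hw, cen_um - sp, (ax_len - 1) * sp - cen_um - sp)
        prof <- extract_profile(stack, cen, axis = ax, half_window = hw,
                                axial_step = axial_step,
                                lateral_step = lateral_step)
        fit_gaussian(prof, ...)
      }),
      fwhm = purrr::map_dbl(.data$fit, "fwhm"),
      r2 = purrr::map_dbl(.data$fit, "r2"),
      usable = purrr::map_lgl(.data$fit, "usable")
    )
}
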