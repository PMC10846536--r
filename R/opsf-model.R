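#' Convert between Gaussian FWHM and standard deviation
#'
#' A Gaussian with standard deviation \eqn{\sigma} has full width at half
#' maximum \eqn{2\sqrt{2\ln 2}\,\sigma \approx 2.3548\,\sigma}.
#'
#' @param fwhm Full width at half maximum (same units as `sigma`).
#' @param sigma Gaussian standard deviation.
#' @return Numeric vector of the converted quantity.
#' @export
sigma_from_fwhm <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' @rdname sigma_from_fwhm
#' @export
fwhm_from_sigma <- function(sigma) sigma * (2 * sqrt(2 * log(2)))

#' Parametric optical point spread function (OPSF)
#'
#' Describes the photostimulation focus as a separable 3D Gaussian, summarised
#' by its axial and lateral FWHM in micrometres. The axial FWHM is the quantity
#' the spatial light modulator manipulates (underfilling the objective back
#' aperture elongates the focus axially); the lateral FWHM only matters for
#' rendering bead images.
#'
#' @param axial_fwhm Axial FWHM in um (> 0).
#' @param lateral_fwhm Lateral FWHM in um (> 0).
#' @return An object of class `opsf_model` with fields `axial_fwhm`,
#'   `lateral_fwhm` and derived `axial_sigma`, `lateral_sigma`.
#' @examples
#' opsf_model(axial_fwhm = 18.6, lateral_fwhm = 1.5)
#' @export
opsf_model <- function(axial_fwhm, lateral_fwhm = 1.5) {
  stopifnot(is.numeric(axial_fwhm), length(axial_fwhm) == 1L,
            is.numeric(lateral_fwhm), length(lateral_fwhm) == 1L)
  if (!is.finite(axial_fwhm) || axial_fwhm <= 0)
    rlang::abort("`axial_fwhm` must be a positive finite length in um.")
  if (!is.finite(lateral_fwhm) || lateral_fwhm <= 0)
    rlang::abort("`lateral_fwhm` must be a positive finite length in um.")
  structure(
    list(
      axial_fwhm = axial_fwhm,
      lateral_fwhm = lateral_fwhm,
      axial_sigma = sigma_from_fwhm(axial_fwhm),
      lateral_sigma = sigma_from_fwhm(lateral_fwhm)
    ),
    class = "opsf_model"
  )
}

#' @export
print.opsf_model <- function(x, ...) {
  cat(sprintf(
    "<opsf_model> axial FWHM %.3g um (sigma %.3g), lateral FWHM %.3g um (sigma %.3g)\n",
    x$axial_fwhm, x$axial_sigma, x$lateral_fwhm, x$lateral_sigma
  ))
  invisible(x)
}
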