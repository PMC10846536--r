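#' Saturating dose-response parameters
#'
#' The forward model linking optical dose (the opsin-weighted overlap of the
#' photostimulation focus with the cell) to the calcium-indicator response
#' amplitude is a Hill function:
#' \deqn{A(q) = A_{max} \, q^n / (q^n + q_{1/2}^n).}
#' Photostimulation powers in these experiments are chosen to stay below
#' saturation, so the defaults put the working dose range on the
#' quasi-linear foot of the curve (half_dose well above the maximum
#' attainable dose of ~1 in relative units) while still producing 1-2 dF/F
#' peak responses, GCaMP6s-typical for strong direct stimulation.
#'
#' @param max_amplitude Saturating response amplitude in dF/F units.
#' @param half_dose Dose giving half-maximal response (> 0, relative dose
#'   units; the dose of a top-hat cell fully covered by the focus is < 1).
#' @param hill_coefficient Hill exponent (>= 1); large values give a
#'   threshold-like response.
#' @param tau_rise,tau_decay GCaMP transient kernel time constants in
#'   seconds (defaults 0.2 and 1.5 s, GCaMP6s-like).
#' @return A `response_params` object.
#' @export
response_params <- function(max_amplitude = 8, half_dose = 2,
                            hill_coefficient = 1,
                            tau_rise = 0.2, tau_decay = 1.5) {
  stopifnot(max_amplitude >= 0, half_dose > 0, hill_coefficient >= 1,
            tau_rise > 0, tau_decay > 0)
  structure(
    list(max_amplitude = max_amplitude, half_dose = half_dose,
         hill_coefficient = hill_coefficient,
         tau_rise = tau_rise, tau_decay = tau_decay),
    class = "response_params"
  )
}

#' Spherical cell specification
#'
#' A target neuron modelled as a sphere with an opsin distribution that
#' determines its axial excitation profile. For a sphere the membrane area
#' per unit z is constant across the diameter (the area of a spherical zone,
#' 2*pi*R*h, is independent of where the slab sits), so `membrane_shell` and
#' `square_wave` give the identical top-hat profile; `uniform_volume` weights
#' by the circular cross-section instead.
#'
#' @param center Numeric (x, y, z) position in um.
#' @param diameter Soma diameter in um (> 0). Default 15 um, a layer-2
#'   pyramidal soma.
#' @param opsin_distribution One of `"membrane_shell"`, `"uniform_volume"`,
#'   `"square_wave"`.
#' @param response A [response_params()] object.
#' @return A `cell_spec` object.
#' @export
cell_spec <- function(center = c(0, 0, 0), diameter = 15,
                      opsin_distribution = c("membrane_shell",
                                             "uniform_volume", "square_wave"),
                      response = response_params()) {
  opsin_distribution <- match.arg(opsin_distribution)
  stopifnot(is.numeric(center), length(center) == 3)
  if (!is.numeric(diameter) || diameter <= 0)
    rlang::abort("`diameter` must be > 0 um.")
  stopifnot(inherits(response, "response_params"))
  structure(
    list(center = as.numeric(center), diameter = diameter,
         opsin_distribution = opsin_distribution, response = response),
    class = "cell_spec"
  )
}

#' Axial opsin-weighted area profile of a cell
#'
#' Relative excitable area per unit z, evaluated on `z_grid` (absolute um).
#' `membrane_shell` and `square_wave` are a top-hat of width `diameter`
#' centred on the cell; `uniform_volume` is the parabolic cross-section
#' profile proportional to `R^2 - (z - z_c)^2`. Peak value 1.
#'
#' @param cell A [cell_spec()].
#' @param z_grid Numeric vector of axial positions in um.
#' @return Numeric profile, same length as `z_grid`.
#' @export
membrane_area_profile <- function(cell, z_grid) {
  stopifnot(inherits(cell, "cell_spec"), is.numeric(z_grid))
  zc <- cell$center[3]
  R <- cell$diameter / 2
  inside <- abs(z_grid - zc) <= R
  switch(cell$opsin_distribution,
    membrane_shell = ,
    square_wave = as.numeric(inside),
    uniform_volume = {
      p <- pmax(R^2 - (z_grid - zc)^2, 0) / R^2
      p * inside
    }
  )
}

#' Optical dose delivered to a cell at a photostimulation z offset
#'
#' The spiral scan tiles the soma laterally (spiral diameter ~ cell
#' diameter), so the dose reduces to the 1D axial convolution of the cell's
#' excitation profile with the axial OPSF:
#' \deqn{q(z_0) = \int p(z)\, G_{axial}(z - z_0)\, dz,}
#' with `G` the unit-area Gaussian. For a top-hat cell this is the closed
#' form `Phi((z0 - zc + R)/sigma) - Phi((z0 - zc - R)/sigma)`, so doses lie
#' in (0, 1).
#'
#' @param opsf An [opsf_model()].
#' @param cell A [cell_spec()].
#' @param z_offset Photostimulation focus z position(s) in um (absolute,
#'   same frame as the cell center).
#' @param spacing Integration grid spacing in um. Default 0.05.
#' @return Numeric dose (arbitrary units, relative), one per `z_offset`.
#' @export
excitation_dose <- function(opsf, cell, z_offset, spacing = 0.05) {
  stopifnot(inherits(opsf, "opsf_model"), inherits(cell, "cell_spec"))
  s <- opsf$axial_sigma
  zc <- cell$center[3]
  R <- cell$diameter / 2
  # midpoint quadrature on a grid symmetric about the cell center: preserves
  # the exact symmetry of the convolution and keeps the top-hat edges between
  # samples (no half-weight edge samples to bias the sum)
  half <- seq(spacing / 2, R + 5 * s, by = spacing)
  zg <- zc + c(-rev(half), half)
  prof <- membrane_area_profile(cell, zg)
  vapply(z_offset, function(z0) {
    sum(prof * stats::dnorm(zg - z0, sd = s)) * spacing
  }, numeric(1))
}

#' Response amplitude from optical dose
#'
#' Hill dose-response law: `A = max_amplitude * q^n / (q^n + half_dose^n)`.
#' Zero at zero dose, monotone non-decreasing, bounded by `max_amplitude`.
#'
#' @param dose Numeric dose(s), >= 0.
#' @param params A [response_params()].
#' @return dF/F amplitude(s).
#' @export
amplitude_from_dose <- function(dose, params) {
  stopifnot(inherits(params, "response_params"))
  if (any(dose < 0)) rlang::abort("`dose` must be non-negative.")
  n <- params$hill_coefficient
  dn <- dose^n
  out <- params$max_amplitude * dn / (dn + params$half_dose^n)
  out[dose == 0] <- 0
  out
}

#' GCaMP transient kernel
#'
#' Double-exponential calcium transient,
#' `k(t) = (1 - exp(-t/tau_rise)) * exp(-t/tau_decay)` for t >= 0, scaled to
#' peak 1 so an event of amplitude A peaks at A dF/F.
#'
#' @param t Time since event onset, seconds (values < 0 give 0).
#' @param params A [response_params()] carrying the time constants.
#' @return Kernel values in [0, 1].
#' @export
gcamp_kernel <- function(t, params = response_params()) {
  tr <- params$tau_rise
  td <- params$tau_decay
  k <- ifelse(t >= 0, (1 - exp(-t / tr)) * exp(-t / td), 0)
  # analytic peak at t* = tr * log(1 + td/tr)
  tstar <- tr * log(1 + td / tr)
  kmax <- (1 - exp(-tstar / tr)) * exp(-tstar / td)
  k / kmax
}
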