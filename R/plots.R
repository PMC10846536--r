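#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a per-neuron axial response curve
#'
#' Mean post-stimulation dF/F versus photostimulation z offset, with the
#' individual trial responses overplotted.
#'
#' @param object A [response_curve()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot response_curve
#' @export
autoplot.response_curve <- function(object, ...) {
  trials <- tibble::tibble(
    z_um = rep(object$z_um, ncol(object$responses)),
    dff = as.vector(object$responses)
  )
  means <- tidy(object)
  ggplot2::ggplot(means, ggplot2::aes(x = .data$z_um, y = .data$mean_dff)) +
    ggplot2::geom_point(data = trials,
                        ggplot2::aes(y = .data$dff),
                        alpha = 0.4, size = 1) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Photostimulation z offset (µm)",
      y = "Post-stimulation response (ΔF/F)",
      title = sprintf("Neuron %s (%s direction)",
                      as.character(object$neuron_id), object$direction)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a group curve with its 95% CI ribbon
#'
#' @param object A [combine_group()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot group_curve
#' @export
autoplot.group_curve <- function(object, ...) {
  fwhm <- fwhm_half_prominence(object$z_um, object$mean_response)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$z_um, y = .data$mean_response)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.25, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Photostimulation z offset (µm)",
      y = if (isTRUE(attr(object, "normalized")))
        "Normalized response" else "Response (ΔF/F)",
      title = if (is.na(fwhm)) "Group response curve"
              else sprintf("Group response curve (FWHM %.1f µm)", fwhm)
    ) +
    ggplot2::theme_minimal()
}

#' Plot model PPSF FWHM versus cell diameter
#'
#' One curve per OPSF condition plus the line of equality (PPSF FWHM equal
#' to cell diameter), the regime the model converges to for large cells.
#'
#' @param object A [ppsf_vs_diameter()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot model_curve
#' @export
autoplot.model_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$diameter_um, y = .data$ppsf_fwhm_um,
                               colour = factor(.data$opsf_fwhm_um))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "Cell diameter (µm)",
      y = "Model PPSF axial FWHM (µm)",
      colour = "OPSF FWHM (µm)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the fitted OPSF summary
#'
#' Mean fitted FWHM per axis with 95% CI error bars.
#'
#' @param object A [summarize_opsf()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot opsf_summary
#' @export
autoplot.opsf_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$axis, y = .data$mean_fwhm_um)) +
    ggplot2::geom_col(width = 0.6, fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo_um,
                                        ymax = .data$ci_hi_um),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "Fitted FWHM (µm)") +
    ggplot2::theme_minimal()
}
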