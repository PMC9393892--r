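# ggplot2 display helpers. The wavenumber axis is reversed on display
# (spectroscopy convention, high to low); internal storage stays ascending.

#' Plot a continuous spectrum
#'
#' @param object A `vcd_spectrum`.
#' @param ... Unused.
#' @return A ggplot object with a reversed wavenumber axis.
#' @method autoplot vcd_spectrum
#' @export
autoplot.vcd_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavenumber, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(tilde(nu) ~ (cm^-1)),
                  y = if (identical(attr(object, "modality"), "VCD"))
                    expression(Delta * epsilon) else expression(epsilon),
                  title = attr(object, "modality")) +
    ggplot2::theme_minimal()
}

#' Plot a stick spectrum
#'
#' @param object A `vcd_sticks`.
#' @param ... Unused.
#' @return A ggplot object with vertical sticks at each mode.
#' @method autoplot vcd_sticks
#' @export
autoplot.vcd_sticks <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$frequency,
                                       xend = .data$frequency,
                                       y = 0, yend = .data$strength)) +
    ggplot2::geom_segment() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(tilde(nu) ~ (cm^-1)), y = "strength",
                  title = paste(attr(object, "modality"), "sticks -",
                                attr(object, "label"))) +
    ggplot2::theme_minimal()
}

#' Plot calculated vs experimental spectra of a comparison
#'
#' Overlays the intensity-matched calculated spectra with the experimental
#' ones over the comparison region, faceted by modality, and annotates the
#' overlap estimates.
#'
#' @param object A `vcd_comparison` from [optimize_scaling()].
#' @param exp_ir,exp_vcd The experimental spectra the comparison used.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vcd_comparison
#' @export
autoplot.vcd_comparison <- function(object, exp_ir = NULL, exp_vcd = NULL,
                                    ...) {
  pieces <- list()
  add <- function(spec, modality, which) {
    if (is.null(spec)) return()
    s <- restrict_region(spec, object$region)
    pieces[[length(pieces) + 1]] <<- tibble::tibble(
      wavenumber = s$wavenumber, intensity = s$intensity,
      modality = modality, source = which)
  }
  if (!is.null(object$ir)) {
    calc <- object$ir
    if (is.finite(object$intensity_factor))
      calc$intensity <- calc$intensity * object$intensity_factor
    add(calc, "IR", "calculated")
  }
  add(object$vcd, "VCD", "calculated")
  add(exp_ir, "IR", "experimental")
  add(exp_vcd, "VCD", "experimental")
  df <- dplyr::bind_rows(pieces)
  ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$intensity,
                                   colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::facet_wrap(~modality, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = expression(tilde(nu) ~ (cm^-1)), y = NULL,
                  subtitle = sprintf("f = %.3f  S(IR) = %.2f  S(VCD) = %.2f",
                                     object$scaling_factor,
                                     object$s_ir %||% NA,
                                     object$s_vcd %||% NA)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
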