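#' Plot methods
#'
#' `autoplot()` methods render the main result types with ggplot2:
#' an `epr_spectrum` as absorption (or first-derivative) versus field, a
#' `level_diagram` as Zeeman energy levels versus field, and a
#' `spin_ladder` as a zero-field level scheme labelled by total spin.
#'
#' @param object The object to plot.
#' @param derivative Plot the first-derivative trace instead of absorption.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-oecspin
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot-oecspin
#' @export
autoplot.epr_spectrum <- function(object, derivative = FALSE, ...) {
  y <- if (derivative) "derivative" else "absorption"
  ggplot2::ggplot(object, ggplot2::aes(.data$field_G, .data[[y]])) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Magnetic field (G)",
      y = if (derivative) "dI/dB (arb. units)" else "Absorption (arb. units)"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-oecspin
#' @export
autoplot.level_diagram <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(.data$field_G, .data$energy_cm1, group = .data$level)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Magnetic field (G)", y = expression(E[n] ~ (cm^-1))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-oecspin
#' @export
autoplot.spin_ladder <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat$label <- sprintf("S = %s", format(dat$S))
  ggplot2::ggplot(dat, ggplot2::aes(x = 1, y = .data$energy_cm1)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0.8, xend = 1.2, yend = .data$energy_cm1)) +
    ggplot2::geom_text(ggplot2::aes(x = 1.3, label = .data$label), hjust = 0, size = 3) +
    ggplot2::scale_x_continuous(limits = c(0.5, 2), breaks = NULL) +
    ggplot2::labs(x = NULL, y = expression(E ~ (cm^-1))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-oecspin
#' @export
autoplot.two_spin_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$abs_j_eff, .data$g)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      yintercept = attr(object, "g_target"),
      linetype = "dashed"
    ) +
    ggplot2::labs(x = expression("|" * J[eff] * "| " * (cm^-1)), y = "effective g") +
    ggplot2::theme_minimal()
}
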