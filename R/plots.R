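#' Plot smoothed oocyte size frequency distributions
#'
#' One density curve per female over the analysis window, optionally
#' faceted, with the previtellogenic/developing split marked.
#'
#' @param osfd Output of [smoothed_osfd()].
#' @param pvo_max Diameter split to mark, um (`NULL` to omit).
#' @return A ggplot object.
#' @export
plot_osfd <- function(osfd, pvo_max = 230) {
  p <- ggplot2::ggplot(osfd, ggplot2::aes(
    x = .data$diameter_um, y = .data$density, group = .data$female_id
  )) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "Oocyte diameter (µm)", y = "Density") +
    ggplot2::theme_minimal()
  if (!is.null(pvo_max)) {
    p <- p + ggplot2::geom_vline(xintercept = pvo_max, linetype = "dashed")
  }
  p
}

#' Plot mean relative fecundity by spawning stage
#'
#' Cell means with 95% confidence intervals for one phase, split by year --
#' the panel in which de novo recruitment shows up as a decline across
#' spawning.
#'
#' @param summary Output of [rf_by_orc()].
#' @param phase Phase to display.
#' @return A ggplot object.
#' @export
plot_rf_by_orc <- function(summary, phase = "PVO4c") {
  df <- dplyr::filter(summary, .data$phase == !!phase)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$orc), y = .data$mean_rf)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::facet_wrap(~year) +
    ggplot2::labs(
      x = "Oocyte ratio category (ORC)",
      y = expression("Relative fecundity (oocytes g"^-1 * " body weight)"),
      title = phase
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_gamma_gaussian_mixture Plot the fitted mixture: data
#'   histogram, weighted component densities and the estimated threshold.
#' @param object A `gg_mixture` object.
#' @param data Optional diameter vector to histogram behind the fit.
#' @export
autoplot.gg_mixture <- function(object, data = NULL, ...) {
  xs <- seq(50, object$normal_mean + 4 * object$normal_sd, length.out = 400)
  comp <- tibble::tibble(
    diameter_um = rep(xs, 2),
    density = c(
      object$weight * dgamma(xs, object$gamma_shape,
                             scale = object$gamma_scale),
      (1 - object$weight) * dnorm(xs, object$normal_mean, object$normal_sd)
    ),
    component = rep(c("gamma (PVO)", "normal (developing)"), each = length(xs))
  )
  p <- ggplot2::ggplot()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(d = data),
      ggplot2::aes(x = .data$d, y = ggplot2::after_stat(.data$density)),
      bins = 60, fill = "grey85", colour = "grey70"
    )
  }
  p +
    ggplot2::geom_line(
      data = comp,
      ggplot2::aes(x = .data$diameter_um, y = .data$density,
                   colour = .data$component)
    ) +
    ggplot2::geom_vline(xintercept = object$threshold_um,
                        linetype = "dashed") +
    ggplot2::labs(x = "Oocyte diameter (µm)", y = "Density") +
    ggplot2::theme_minimal()
}
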