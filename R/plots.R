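# ggplot2 visualisations for ensembles and fits.

#' Plot a translocation-time ensemble
#'
#' Histogram of the successful translocation times with the fitted
#' inverse-Gaussian first-passage density overlaid (when at least `min_n`
#' successes are available).
#'
#' @param object A `poremd_ensemble`.
#' @param bins Histogram bins.
#' @param min_n Minimum successes before a density is overlaid.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.poremd_ensemble <- function(object, bins = 30, min_n = 50L, ...) {
  ok <- object[object$status == "translocated", , drop = FALSE]
  p <- ggplot2::ggplot(ok, ggplot2::aes(x = .data$tau)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "translocation time (LJ units)", y = "density")
  if (nrow(ok) >= min_n && stats::sd(ok$tau) > 0) {
    fit <- fit_first_passage(ok$tau, min_n = min_n)
    grid <- seq(min(ok$tau), max(ok$tau), length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(tau = grid,
                            dens = dinvgauss(grid, fit$mu, fit$lambda)),
      ggplot2::aes(x = .data$tau, y = .data$dens), colour = "firebrick")
  }
  p
}

#' Plot a scaling fit
#'
#' Log-log scatter of the fitted data with the power-law line.
#'
#' @param object A `poremd_scaling_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.poremd_scaling_fit <- function(object, ...) {
  d <- object$data
  slope <- if (object$type == "force") -object$exponent else object$exponent
  intercept <- mean(log10(d$y) - slope * log10(d$x))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point()
  if (any(is.finite(d$se))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$y - .data$se, ymax = .data$y + .data$se),
      width = 0)
  }
  p + ggplot2::geom_abline(slope = slope, intercept = intercept,
                           linetype = 2, colour = "firebrick") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = object$xlab, y = object$ylab,
                  subtitle = sprintf("exponent %.3f +/- %.3f",
                                     object$exponent, object$se))
}

#' Plot a first-passage fit
#'
#' Empirical cumulative distribution of the times against the fitted
#' inverse-Gaussian CDF.
#'
#' @param object A `poremd_fp_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.poremd_fp_fit <- function(object, ...) {
  grid <- seq(min(object$times), max(object$times), length.out = 200)
  ggplot2::ggplot(tibble::tibble(t = object$times),
                  ggplot2::aes(x = .data$t)) +
    ggplot2::stat_ecdf() +
    ggplot2::geom_line(data = tibble::tibble(
      t = grid, p = pinvgauss(grid, object$mu, object$lambda)),
      ggplot2::aes(x = .data$t, y = .data$p), colour = "firebrick") +
    ggplot2::labs(x = "translocation time (LJ units)", y = "CDF")
}
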