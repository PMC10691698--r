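#' Plot methods
#'
#' `autoplot()` methods for the package's result types: the weekly
#' arrival profile, hourly ensemble statistics (mean with a one-STD
#' ribbon), cohort survival (semi-log with the exponential fit), the
#' noise-likelihood MSE surface, and elasticity curves.
#'
#' @param object a package result object.
#' @param ... unused.
#' @return A ggplot object.
#' @name ed-plots
NULL

shift_gridlines <- function() {
  ggplot2::geom_vline(xintercept = seq(0, 168, by = 8), colour = "grey85",
                      linewidth = 0.2)
}

#' @rdname ed-plots
#' @method autoplot ed_profile
#' @export
autoplot.ed_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$weekly_hour, y = .data$flux)) +
    shift_gridlines() +
    ggplot2::geom_step() +
    ggplot2::labs(x = "weekly hour (0 = Sunday 07:00)",
                  y = "arrival flux (patients/hour)") +
    ggplot2::theme_minimal()
}

#' @rdname ed-plots
#' @method autoplot ed_ensemble_stats
#' @export
autoplot.ed_ensemble_stats <- function(object, ...) {
  ggplot2::ggplot(object$hourly, ggplot2::aes(x = .data$weekly_hour)) +
    shift_gridlines() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$std,
                                      ymax = .data$mean + .data$std),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "steelblue4") +
    ggplot2::labs(x = "weekly hour (0 = Sunday 07:00)",
                  y = "occupancy (patients)") +
    ggplot2::theme_minimal()
}

#' @rdname ed-plots
#' @method autoplot ed_survival
#' @export
autoplot.ed_survival <- function(object, ...) {
  cv <- object$curve
  p <- ggplot2::ggplot(cv, ggplot2::aes(x = .data$elapsed_h, y = .data$frac)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "hours since cohort arrival", y = "fraction remaining") +
    ggplot2::theme_minimal()
  if (is.finite(object$beta_hat)) {
    ref <- dplyr::filter(cv, .data$frac > 0)
    p <- p + ggplot2::geom_line(
      data = dplyr::mutate(ref, fit = exp(-object$beta_hat * (.data$elapsed_h - min(.data$elapsed_h))) *
                             .data$frac[1]),
      ggplot2::aes(y = .data$fit), colour = "red")
  }
  p
}

#' @rdname ed-plots
#' @method autoplot ed_noise_fit
#' @export
autoplot.ed_noise_fit <- function(object, ...) {
  surf <- dplyr::filter(object$surface, .data$pass == "coarse")
  ggplot2::ggplot(surf, ggplot2::aes(x = .data$sigma1, y = .data$sigma2,
                                     fill = log10(.data$mse))) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = tibble::tibble(sigma1 = object$sigma[["sigma1"]],
                                              sigma2 = object$sigma[["sigma2"]]),
                        ggplot2::aes(fill = NULL), colour = "red", shape = 4) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(sigma[1]), y = expression(sigma[2]),
                  fill = "log10 MSE") +
    ggplot2::theme_minimal()
}

#' @rdname ed-plots
#' @method autoplot ed_elasticity
#' @export
autoplot.ed_elasticity <- function(object, ...) {
  knob <- attr(object, "knob")
  xlab <- switch(knob,
                 arrival_flux = "relative change in arrival flux",
                 length_of_stay = "change in length of stay (minutes)",
                 sigma2 = "relative change in systematic noise")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delta, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, colour = "grey70") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ratio - .data$ratio_se,
                                          ymax = .data$ratio + .data$ratio_se)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab,
                  y = sprintf("P(n > %g) relative to baseline",
                              attr(object, "threshold"))) +
    ggplot2::theme_minimal()
}
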