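#' Tidy a scaling fit
#'
#' @param x A [fit_scaling_exponent()] result.
#' @param ... Unused.
#' @return A tibble with one row per fitted term (`alpha`,
#'   `log_prefactor`), columns `term`, `estimate`, `std.error`.
#' @export
tidy.scaling_fit <- function(x, ...) {
  se <- suppressWarnings(sqrt(diag(vcov(x$fit))))
  tibble(term = c("log_prefactor", "alpha"),
         estimate = c(unname(coef(x$fit)[1]), x$alpha),
         std.error = c(unname(se[1]), x$alpha_stderr))
}

#' One-row summary of a scaling fit
#'
#' @inheritParams tidy.scaling_fit
#' @return A one-row tibble: `alpha`, `alpha_stderr`, `prefactor`,
#'   `r.squared`, `n_points`.
#' @export
glance.scaling_fit <- function(x, ...) {
  tibble(alpha = x$alpha, alpha_stderr = x$alpha_stderr,
         prefactor = x$prefactor,
         r.squared = suppressWarnings(summary(x$fit)$r.squared),
         n_points = nrow(x$points))
}

#' Plot a scaling fit on log-log axes
#'
#' @param object A [fit_scaling_exponent()] result.
#' @param ... Unused.
#' @return A ggplot: mean translocation time against force on log axes
#'   with the fitted power law.
#' @export
autoplot.scaling_fit <- function(object, ...) {
  pts <- object$points
  line <- tibble(F = seq(min(pts$F), max(pts$F), length.out = 100))
  line$mean_tau <- object$prefactor * line$F^(-object$alpha)
  gg <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$F, y = .data$mean_tau)) +
    ggplot2::geom_line(data = line, colour = "grey40") +
    ggplot2::geom_point()
  if ("sem" %in% names(pts)) {
    gg <- gg + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_tau - .data$sem,
                   ymax = .data$mean_tau + .data$sem), width = 0)
  }
  gg + ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "driving force F",
      y = "mean translocation time",
      title = sprintf("tau ~ F^-alpha, alpha = %.3f +- %.3f",
                      object$alpha, object$alpha_stderr)) +
    ggplot2::theme_minimal()
}

#' Plot a per-segment profile
#'
#' Works for the outputs of [tau_per_bead()], [n_in_profile()] and
#' [delta_profile()]: the second column is drawn against `s` with a
#' standard-error ribbon.
#'
#' @param object A `crowdpore_profile` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crowdpore_profile <- function(object, ...) {
  ycol <- names(object)[2]
  y <- object[[ycol]]
  s <- object$s
  sem <- object$sem
  df <- tibble(s = s, y = y, sem = sem)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$y)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$y - .data$sem,
                                      ymax = .data$y + .data$sem),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "number of segments out of channel s",
                  y = attr(object, "label") %||% ycol,
                  subtitle = attr(object, "description")) +
    ggplot2::theme_minimal()
}
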