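# broom-style tidiers and ggplot2 autoplot methods ---------------------------

#' Tidy a fitted limits-of-agreement model
#'
#' One row per fixed-effect coefficient (basis function).
#'
#' @param x A `floa_fit`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`.
#' @export
tidy.floa_fit <- function(x, ...) {
  tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' One-row summary of a fitted limits-of-agreement model
#'
#' @param x A `floa_fit`.
#' @param ... Unused.
#' @return Tibble with the error variance, ARMA coefficients, REML
#'   log-likelihood, parameter counts and convergence flag.
#' @export
glance.floa_fit <- function(x, ...) {
  tibble(
    sigma2 = x$sigma2,
    error = error_label(x$error),
    phi = paste(signif(x$phi, 4), collapse = ","),
    theta = paste(signif(x$theta, 4), collapse = ","),
    reml_loglik = x$reml_loglik,
    n_params_psi = x$n_params$psi,
    n_params_total = x$n_params$total,
    converged = x$converged
  )
}

#' Augment difference curves with fitted values and residuals
#'
#' @param x A `floa_fit`.
#' @param data Difference curves (defaults to the fitted data).
#' @param ... Unused.
#' @return The data with `.fitted` (bias plus BLUP contributions) and
#'   `.resid` columns.
#' @export
augment.floa_fit <- function(x, data = x$data, ...) {
  data <- as_diff_tbl(data)
  fits <- fitted_curves(x)
  data %>%
    left_join(fits, by = c(curve_id_cols, "frame")) %>%
    mutate(.resid = .data$value - .data$.fitted)
}

#' Tidy a limits-of-agreement band
#'
#' @param x A `floa_band`.
#' @param ... Unused.
#' @return The band as a plain tibble.
#' @export
tidy.floa_band <- function(x, ...) as_tibble(x)

#' Plot a functional limits-of-agreement band
#'
#' Bias curve with the lower/upper limits, optionally over the observed
#' difference curves in grey.
#'
#' @param object A `floa_band`.
#' @param diffs Optional long difference-curve table to draw behind the band.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.floa_band <- function(object, diffs = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$frame))
  if (!is.null(diffs)) {
    diffs <- as_diff_tbl(diffs) %>%
      tidyr::unite("curve", all_of(curve_id_cols), remove = FALSE)
    p <- p + ggplot2::geom_line(
      data = diffs,
      ggplot2::aes(y = .data$value, group = .data$curve),
      colour = "grey70", linewidth = 0.3
    )
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$bias), colour = "red") +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper), colour = "blue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower), colour = "darkgreen") +
    ggplot2::labs(
      x = "normalized time (frame)", y = "difference (degrees)",
      title = sprintf("Functional limits of agreement (+/- %g SD)",
                      attr(object, "multiplier") %||% 2)
    )
}

#' Plot an averaged residual autocorrelation function
#'
#' @param object A `floa_acf` from [residual_acf()].
#' @param ... Unused.
#' @return A ggplot with the +/- 2/sqrt(N) reference bounds.
#' @export
autoplot.floa_acf <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$lag, y = .data$acf)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_hline(
      yintercept = c(object$lower[1], object$upper[1]),
      linetype = "dashed", colour = "blue"
    ) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$lag, yend = 0)) +
    ggplot2::labs(x = "lag (frames)", y = "average residual ACF")
}

#' Plot residuals against between-method averages
#'
#' @param object A `floa_rva` from [residual_vs_average()].
#' @param ... Unused.
#' @return A ggplot with a straight-line trend overlay.
#' @export
autoplot.floa_rva <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$average, y = .data$residual)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                         se = FALSE, colour = "red") +
    ggplot2::labs(x = "average of the two methods (degrees)",
                  y = "model residual (degrees)")
}

#' Plot the adjusted R-squared knot-selection report
#'
#' @param object A `floa_knot_selection`.
#' @param ... Unused.
#' @return A ggplot of the minimum and median adjusted R-squared per
#'   candidate, with the selection threshold.
#' @export
autoplot.floa_knot_selection <- function(object, ...) {
  long <- object$report %>%
    tidyr::pivot_longer(c("min_adj_r2", "median_adj_r2"),
                        names_to = "summary", values_to = "adj_r2")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$n_inner),
                                     y = .data$adj_r2,
                                     colour = .data$summary,
                                     group = .data$summary)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "inner knots", y = "adjusted R-squared", colour = NULL)
}
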