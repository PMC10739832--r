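# Model diagnostics ----------------------------------------------------------

#' Average autocorrelation of whitened residuals
#'
#' Whitens each subject's stacked marginal residuals `d - X beta` with the
#' Cholesky factor of the fitted marginal covariance (random effects plus
#' error), reshapes the innovations back into curves, averages the residual
#' ACF over curves, and reports +/- 2 / sqrt(N) reference bounds (N = total
#' number of residuals).  Under a correctly specified covariance model the
#' innovations are white, so the averaged ACF stays within the bounds at
#' almost all lags; an error structure that misses the serial correlation
#' (for example an iid assumption on ARMA-correlated data) leaves the early
#' lags far outside them.
#'
#' @param fit A `floa_fit`.
#' @param max_lag Largest lag to report.
#' @param type `"marginal"` (default) whitens by the full fitted covariance;
#'   `"conditional"` whitens the conditional residuals (after subtracting
#'   BLUPs) by the error covariance `sigma2 C` alone — closer to a classical
#'   residual plot, but BLUP shrinkage leaves small systematic
#'   autocorrelation of order q/T even under the true model.
#' @return A tibble of class `floa_acf` with `lag`, `acf`, `lower`, `upper`.
#' @export
residual_acf <- function(fit, max_lag = 20,
                         type = c("marginal", "conditional")) {
  stopifnot(inherits(fit, "floa_fit"))
  type <- arg_match(type)
  designs <- fit$designs
  T_ <- designs$grid$n_frames
  max_lag <- min(max_lag, T_ - 2L)
  if (type == "marginal") {
    bias <- as.numeric(designs$X %*% fit$beta)
    cols <- lapply(designs$blocks, function(b) {
      V <- marginal_covariance(fit$params, designs, b$subject)
      r <- as.vector(b$Y) - rep(bias, ncol(b$Y))
      z <- forwardsolve(chol(V), r, upper.tri = TRUE, transpose = TRUE)
      matrix(z, nrow = T_)
    })
    res <- do.call(cbind, cols)
  } else {
    res <- conditional_residuals(fit)
    C <- params_correlation(fit$params, T_)
    res <- forwardsolve(chol(fit$sigma2 * C), res,
                        upper.tri = TRUE, transpose = TRUE)
  }
  acfs <- apply(res, 2, function(e) {
    as.numeric(acf(e, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf)
  })
  avg <- rowMeans(acfs)
  bound <- 2 / sqrt(length(res))
  out <- tibble(
    lag = 0:max_lag,
    acf = avg,
    lower = -bound,
    upper = bound
  )
  class(out) <- c("floa_acf", class(out))
  out
}

# Conditional residuals per curve as a frames x curves matrix, ordered as
# the design keys.
conditional_residuals <- function(fit) {
  designs <- fit$designs
  obs <- do.call(cbind, lapply(designs$blocks, `[[`, "Y"))
  fitted_long <- fitted_curves(fit)
  T_ <- designs$grid$n_frames
  fit_mat <- matrix(fitted_long$.fitted, nrow = T_)
  obs - fit_mat
}

#' Residuals against between-method averages, ignoring the time dimension
#'
#' The functional analogue of the Bland-Altman mean-difference plot
#' assumption check: each observation's model residual is paired with the
#' average of the two methods' values at that (curve, frame), discarding the
#' frame index.  Absence of trend indicates the model has captured the
#' nonlinear bias and variance over the measurement range.  A straight-line
#' trend fit (slope, standard error, correlation) is attached as attributes
#' for a plot-free summary.
#'
#' @param fit A `floa_fit` for the difference curves.
#' @param data The paired long curve table the differences came from.
#' @param methods Optional two method labels (minuend, subtrahend).
#' @return A tibble of class `floa_rva` with keys, `frame`, `average`,
#'   `residual`; attributes `slope`, `slope_se`, `correlation`.
#' @export
residual_vs_average <- function(fit, data, methods = NULL) {
  stopifnot(inherits(fit, "floa_fit"))
  data <- as_curve_tbl(data)
  present <- sort(unique(data$method))
  if (is.null(methods)) methods <- present
  if (length(methods) != 2) abort("Need exactly two methods.")
  avg <- data %>%
    filter(.data$method %in% methods) %>%
    tidyr::pivot_wider(
      id_cols = all_of(c(intersect("scenario", names(data)), curve_id_cols, "frame")),
      names_from = "method", values_from = "value"
    ) %>%
    mutate(average = (.data[[methods[1]]] + .data[[methods[2]]]) / 2) %>%
    select(all_of(c(curve_id_cols, "frame", "average")))
  res <- augment(fit) %>%
    select(all_of(c(curve_id_cols, "frame")), residual = ".resid")
  out <- inner_join(avg, res, by = c(curve_id_cols, "frame"))
  trend <- lm(residual ~ average, data = out)
  attr(out, "slope") <- unname(coef(trend)[2])
  attr(out, "slope_se") <- summary(trend)$coefficients[2, 2]
  attr(out, "correlation") <- stats::cor(out$average, out$residual)
  class(out) <- c("floa_rva", class(out))
  out
}
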