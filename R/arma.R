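# Within-curve error correlation structures ---------------------------------
#
# The within-curve error covariance is Sigma = sigma2 * C with C a stationary
# correlation matrix on the frame grid: white noise, AR(1), continuous-time
# AR(1) evaluated at unit spacing, or a general ARMA(p, q).  During
# optimization the coefficients are carried through a partial-autocorrelation
# transform, which maps unconstrained reals onto the stationary (AR) and
# invertible (MA) regions.

#' Error-structure specifications
#'
#' Constructors for the within-curve error families understood by
#' [fit_floa_lmm()]: independent errors, first-order autoregressive,
#' continuous-time AR(1) (positive correlation decaying with lag), and
#' autoregressive-moving-average of order (p, q).  Serially correlated
#' kinematic measurement error is typically well described by a low-order
#' ARMA; ARMA(2, 1) is the package default in the full pipeline.
#'
#' @param p,q Autoregressive and moving-average orders.
#' @return A list of class `floa_error` with fields `family`, `p`, `q`.
#' @export
error_arma <- function(p = 2, q = 1) {
  if (p < 0 || q < 0 || p != round(p) || q != round(q)) {
    abort("ARMA orders must be non-negative integers.")
  }
  structure(list(family = "ARMA", p = as.integer(p), q = as.integer(q)),
            class = "floa_error")
}

#' @rdname error_arma
#' @export
error_iid <- function() {
  structure(list(family = "iid", p = 0L, q = 0L), class = "floa_error")
}

#' @rdname error_arma
#' @export
error_ar1 <- function() {
  structure(list(family = "AR1", p = 1L, q = 0L), class = "floa_error")
}

#' @rdname error_arma
#' @export
error_car1 <- function() {
  structure(list(family = "CAR1", p = 1L, q = 0L), class = "floa_error")
}

error_label <- function(x) {
  switch(x$family,
    iid = "iid", AR1 = "AR(1)", CAR1 = "CAR(1)",
    ARMA = sprintf("ARMA(%d,%d)", x$p, x$q)
  )
}

#' @export
print.floa_error <- function(x, ...) {
  cat("<floa_error>", error_label(x), "\n")
  invisible(x)
}

n_error_params <- function(spec) {
  switch(spec$family, iid = 0L, AR1 = 1L, CAR1 = 1L, ARMA = spec$p + spec$q)
}

ar_stationary <- function(phi) {
  length(phi) == 0 || all(Mod(polyroot(c(1, -phi))) > 1)
}

ma_invertible <- function(theta) {
  length(theta) == 0 || all(Mod(polyroot(c(1, theta))) > 1)
}

#' Theoretical ARMA autocorrelation matrix
#'
#' Toeplitz matrix of the stationary ARMA(p, q) autocorrelation function
#' rho(h) at lags 0 .. n_frames - 1, with rho(0) = 1 on the diagonal.
#'
#' @param phi AR coefficients (may be empty).
#' @param theta MA coefficients (may be empty).
#' @param n_frames Matrix dimension.
#' @return `n_frames` x `n_frames` correlation matrix.
#' @examples
#' arma_correlation(0.5, numeric(0), 4)[1, ] # 1, .5, .25, .125
#' @export
arma_correlation <- function(phi, theta, n_frames) {
  phi <- as.numeric(phi); theta <- as.numeric(theta)
  if (!ar_stationary(phi)) abort("AR polynomial is not stationary.")
  if (!ma_invertible(theta)) abort("MA polynomial is not invertible.")
  if (length(phi) == 0 && length(theta) == 0) return(diag(n_frames))
  rho <- ARMAacf(ar = phi, ma = theta, lag.max = n_frames - 1)
  toeplitz(as.numeric(rho))
}

# Correlation matrix for any floa_error at coefficient values.
error_correlation <- function(spec, coefs, n_frames) {
  switch(spec$family,
    iid = diag(n_frames),
    AR1 = arma_correlation(coefs, numeric(0), n_frames),
    CAR1 = {
      if (coefs <= 0 || coefs >= 1) abort("CAR(1) parameter must be in (0, 1).")
      toeplitz(coefs^(0:(n_frames - 1)))
    },
    ARMA = arma_correlation(coefs[seq_len(spec$p)],
                            coefs[spec$p + seq_len(spec$q)], n_frames)
  )
}

# Monahan-style map between unconstrained reals and stationary AR
# coefficients: z -> pacf = tanh(z) -> coefficients by the Levinson-Durbin
# step-up recursion.  MA coefficients use the dual map (theta = -ar so the
# MA polynomial 1 + theta_1 B + ... is invertible).
pacf_to_ar <- function(pac) {
  a <- numeric(0)
  for (k in seq_along(pac)) {
    if (k > 1) a <- a - pac[k] * rev(a)
    a <- c(a, pac[k])
  }
  a
}

ar_to_pacf <- function(a) {
  pac <- numeric(length(a))
  for (k in rev(seq_along(a))) {
    pac[k] <- a[k]
    if (k > 1) a <- (a[-k] + pac[k] * rev(a[-k])) / (1 - pac[k]^2)
  }
  pac
}

unconstrained_to_error <- function(spec, z) {
  switch(spec$family,
    iid = numeric(0),
    AR1 = tanh(z),
    CAR1 = plogis(z),
    ARMA = c(
      pacf_to_ar(tanh(z[seq_len(spec$p)])),
      -pacf_to_ar(tanh(z[spec$p + seq_len(spec$q)]))
    )
  )
}

error_to_unconstrained <- function(spec, coefs) {
  switch(spec$family,
    iid = numeric(0),
    AR1 = atanh(coefs),
    CAR1 = qlogis(coefs),
    ARMA = c(
      atanh(ar_to_pacf(coefs[seq_len(spec$p)])),
      atanh(ar_to_pacf(-coefs[spec$p + seq_len(spec$q)]))
    )
  )
}

# Split fitted coefficient vector into phi/theta for reporting.
error_phi_theta <- function(spec, coefs) {
  switch(spec$family,
    iid = list(phi = numeric(0), theta = numeric(0)),
    AR1 = list(phi = coefs, theta = numeric(0)),
    CAR1 = list(phi = coefs, theta = numeric(0)),
    ARMA = list(phi = coefs[seq_len(spec$p)],
                theta = coefs[spec$p + seq_len(spec$q)])
  )
}
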