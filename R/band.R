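# 95% functional limits of agreement ----------------------------------------

#' Functional limits of agreement band from a fitted model
#'
#' The bias curve is the fixed-effects mean difference `X beta`; the
#' pointwise variance is the diagonal of the model-implied covariance of a
#' single new difference curve,
#' `Z Psi1 Z' + Z Psi2 Z' + Z Psi3 Z' + sigma2 C`, so cross-curve covariance
#' terms do not enter.  The band is `bias +/- multiplier * sqrt(variance)`;
#' with the conventional multiplier 2 it is interpreted pointwise as the
#' range containing about 95% of between-method differences at each frame.
#'
#' @param fit A `floa_fit`.
#' @param multiplier Half-width in standard deviations (default 2).
#' @return A tibble of class `floa_band` with columns `frame`, `bias`,
#'   `variance`, `lower`, `upper`; the multiplier is kept as an attribute.
#' @export
floa_band <- function(fit, multiplier = 2) {
  stopifnot(inherits(fit, "floa_fit"))
  designs <- fit$designs
  bias <- as.numeric(designs$X %*% fit$beta)
  variance <- rep(fit$sigma2, designs$grid$n_frames) # diag(C) = 1
  for (l in names(designs$random)) {
    Z <- designs$random[[l]]$basis$matrix
    variance <- variance + rowSums((Z %*% fit$psi[[l]]) * Z)
  }
  out <- tibble(
    frame = 0:(designs$grid$n_frames - 1L),
    bias = bias,
    variance = variance,
    lower = bias - multiplier * sqrt(variance),
    upper = bias + multiplier * sqrt(variance)
  )
  attr(out, "multiplier") <- multiplier
  class(out) <- c("floa_band", class(out))
  out
}

#' Fraction of difference values inside a band
#'
#' Pointwise empirical coverage: the share of all (curve, frame) difference
#' values lying within `[lower, upper]` at their frame.  With a correctly
#' calibrated +/- 2 SD band on Gaussian differences this is about 0.954.
#'
#' @param band A `floa_band` (or data frame with `frame`, `lower`, `upper`).
#' @param diffs Long difference-curve table on the same grid.
#' @return A single number in `[0, 1]`.
#' @export
empirical_coverage <- function(band, diffs) {
  diffs <- as_diff_tbl(diffs)
  joined <- inner_join(diffs, as_tibble(band)[c("frame", "lower", "upper")],
                       by = "frame")
  if (!nrow(joined)) abort("Band and differences share no frames.")
  mean(joined$value >= joined$lower & joined$value <= joined$upper)
}
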