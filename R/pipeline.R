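# End-to-end agreement pipeline ----------------------------------------------

#' Pipeline configuration
#'
#' Assembles and validates the configuration of the end-to-end agreement
#' pipeline [floa()].  Defaults follow the package's recommended recipe:
#' adjusted R-squared knot selection over the candidate set
#' {0, 1, 3, 9, 19, 32} at threshold 0.95, eigenbasis random effects kept at
#' 99% of variance with a diagonal covariance, a fixed ARMA(2,1) error, and
#' a +/- 2 SD band.
#'
#' @param ... Overrides as nested lists, e.g.
#'   `fixed = list(n_inner = 9)`, `random = list(basis = "bspline")`,
#'   `error = list(family = "AR1")`, `multiplier = 1.96`.  Unknown keys are
#'   rejected.
#' @return A list of class `floa_config`.
#' @export
floa_config <- function(...) {
  defaults <- list(
    fixed = list(
      auto = TRUE, n_inner = NULL,
      candidates = c(0, 1, 3, 9, 19, 32),
      threshold = 0.95, degree = 3
    ),
    random = list(
      basis = "eigen",            # "eigen" or "bspline"
      covariance = NULL,          # default: diagonal for eigen, unstructured otherwise
      variance_fraction = 0.99,
      levels = c("subject", "session", "replicate")
    ),
    error = list(family = "ARMA", p = 2, q = 1, select = "fixed"),
    optim = list(n_starts = 2, seed = NULL),
    multiplier = 2,
    preprocess = list(range_of_motion = FALSE, sign_rules = NULL)
  )
  overrides <- list(...)
  cfg <- merge_config(defaults, overrides, path = "")
  if (!cfg$random$basis %in% c("eigen", "bspline")) {
    abort("`random$basis` must be 'eigen' or 'bspline'.")
  }
  if (is.null(cfg$random$covariance)) {
    cfg$random$covariance <-
      if (cfg$random$basis == "eigen") "diagonal" else "unstructured"
  }
  if (!cfg$error$family %in% c("iid", "AR1", "CAR1", "ARMA")) {
    abort("Unknown error family.")
  }
  if (!cfg$error$select %in% c("fixed", "auto")) {
    abort("`error$select` must be 'fixed' or 'auto'.")
  }
  structure(cfg, class = "floa_config")
}

merge_config <- function(defaults, overrides, path) {
  if (!length(overrides)) return(defaults)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    abort(sprintf("Unknown config key%s: %s",
                  if (length(bad) > 1) "s" else "",
                  paste0(path, bad, collapse = ", ")))
  }
  for (k in names(overrides)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(overrides[[k]])) {
        abort(sprintf("Config key %s%s must be a list.", path, k))
      }
      defaults[[k]] <- merge_config(defaults[[k]], overrides[[k]],
                                    paste0(path, k, "$"))
    } else {
      defaults[[k]] <- overrides[[k]]
    }
  }
  defaults
}

config_error_spec <- function(cfg_err) {
  switch(cfg_err$family,
    iid = error_iid(),
    AR1 = error_ar1(),
    CAR1 = error_car1(),
    ARMA = error_arma(cfg_err$p, cfg_err$q)
  )
}

#' Run the full functional limits-of-agreement analysis for one scenario
#'
#' Executes the whole recipe on a paired-method curve dataset: optional
#' preprocessing (sign alignment, range-of-motion baselining), frame-wise
#' differences, knot selection for the fixed-effects B-spline basis by the
#' adjusted R-squared rule, construction of the random-effects basis
#' (covariance eigenbasis with diagonal covariance by default, or the same
#' B-spline system with an unstructured covariance), REML fitting with the
#' configured error structure (optionally chosen automatically from the
#' whitened residual ACF and BIC), and finally the limits-of-agreement band
#' with diagnostics.
#'
#' @param data Long paired curve table (see [as_curve_tbl()]), or an
#'   already-differenced table (no `method` column).
#' @param config A [floa_config()].
#' @param methods Optional two method labels (minuend, subtrahend).
#' @return An object of class `floa_result`: list with `fit`, `band`,
#'   `diagnostics` (ACF tibble, empirical coverage, residual-vs-average when
#'   paired data were given), `knots` (selection report), and a one-row
#'   `report` tibble echoing the model specification.
#' @export
floa <- function(data, config = floa_config(), methods = NULL) {
  stopifnot(inherits(config, "floa_config"))
  paired <- "method" %in% names(data)
  if (paired) {
    data <- as_curve_tbl(data)
    if (!is.null(config$preprocess$sign_rules)) {
      data <- align_sign(data, config$preprocess$sign_rules)
    }
    if (isTRUE(config$preprocess$range_of_motion)) {
      data <- range_of_motion(data)
    }
    diffs <- compute_differences(data, methods)
  } else {
    diffs <- as_diff_tbl(data)
  }
  grid <- grid_from_frames(diffs$frame)

  # fixed-effects basis
  knots <- NULL
  if (isTRUE(config$fixed$auto) && is.null(config$fixed$n_inner)) {
    knots <- select_knots(diffs,
      candidates = config$fixed$candidates,
      threshold = config$fixed$threshold,
      degree = config$fixed$degree
    )
    fixed_basis <- knots$basis
  } else {
    fixed_basis <- bspline_basis(grid, n_inner = config$fixed$n_inner,
                                 degree = config$fixed$degree)
  }

  # random-effects basis
  random_basis <- if (config$random$basis == "eigen") {
    eigen_basis(diffs, variance_fraction = config$random$variance_fraction)
  } else {
    fixed_basis
  }

  fit_with <- function(error) {
    fit_floa_lmm(
      diffs, fixed_basis,
      random_basis = random_basis,
      covariance = config$random$covariance,
      error = error,
      levels = config$random$levels,
      n_starts = config$optim$n_starts
    )
  }

  if (config$error$select == "auto") {
    cands <- list(error_iid(), error_ar1(), error_car1(),
                  error_arma(1, 1), error_arma(2, 1), error_arma(2, 2))
    fits <- lapply(cands, function(e) tryCatch(fit_with(e), error = function(err) NULL))
    keep <- !vapply(fits, is.null, TRUE)
    fits <- fits[keep]; cands <- cands[keep]
    if (!length(fits)) abort("No error structure could be fitted.")
    score <- vapply(fits, function(f) {
      a <- residual_acf(f)
      exceed <- sum(abs(a$acf[-1]) > a$upper[-1])
      k <- f$n_params$total
      bic <- -2 * f$reml_loglik + k * log(f$designs$N)
      exceed * 1e6 + bic
    }, 0)
    fit <- fits[[which.min(score)]]
  } else {
    fit <- fit_with(config_error_spec(config$error))
  }

  band <- floa_band(fit, multiplier = config$multiplier)
  acf_tbl <- residual_acf(fit)
  diagnostics <- list(
    acf = acf_tbl,
    coverage = empirical_coverage(band, diffs),
    residual_vs_average = if (paired) residual_vs_average(fit, data, methods)
  )
  rb_kind <- random_basis$kind
  q_random <- ncol(random_basis$matrix)
  report <- tibble(
    scenario = if (paired && "scenario" %in% names(data)) {
      paste(unique(data$scenario), collapse = "+")
    } else NA_character_,
    n_diff_curves = nrow(fit$designs$keys),
    fixed_n_inner = if (fixed_basis$kind == "bspline") fixed_basis$n_inner else NA_integer_,
    p_fixed = length(fit$beta),
    random_basis = rb_kind,
    q_random = q_random,
    covariance = fit$covariance,
    error = error_label(fit$error),
    n_variance_params = fit$n_params$total,
    sigma2 = fit$sigma2,
    reml_loglik = fit$reml_loglik,
    converged = fit$converged,
    coverage = diagnostics$coverage
  )
  structure(
    list(fit = fit, band = band, diagnostics = diagnostics,
         knots = knots, report = report, config = config),
    class = "floa_result"
  )
}

#' @export
print.floa_result <- function(x, ...) {
  cat("<floa_result>\n")
  print(x$fit)
  cat(sprintf("  band: +/- %g SD; empirical coverage %.3f\n",
              attr(x$band, "multiplier"), x$diagnostics$coverage))
  invisible(x)
}
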