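# File formats ---------------------------------------------------------------
#
# Curves travel as long CSV: one row per (method, subject, session,
# replicate, frame) with a numeric value in degrees and an optional scenario
# label; frames are 0-based integers 0..n_frames-1.  Bands are CSV with one
# row per frame.  Configurations are YAML/JSON mirroring floa_config().

#' Read a long-format curve CSV
#'
#' @param path CSV file with columns `method`, `subject`, `session`,
#'   `replicate`, `frame`, `value` (plus optional `scenario`).  A file
#'   without `method` is read as difference curves.
#' @param validation `"strict"` errors on duplicate keys or incomplete
#'   frame ranges; `"permissive"` drops incomplete curves with a warning.
#' @return A long tibble (see [as_curve_tbl()]).
#' @export
read_curves <- function(path, validation = c("strict", "permissive")) {
  validation <- arg_match(validation)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  has_method <- "method" %in% names(raw)
  data <- if (has_method) as_curve_tbl(raw) else as_diff_tbl(raw)
  id_cols <- intersect(c("scenario", "method", curve_id_cols), names(data))
  dup <- data %>%
    count(across(all_of(c(id_cols, "frame")))) %>%
    filter(.data$n > 1)
  n_frames <- max(data$frame) + 1L
  status <- data %>%
    group_by(across(all_of(id_cols))) %>%
    summarise(
      complete = identical(sort(unique(.data$frame)), 0:(n_frames - 1L)) &&
        dplyr::n() == n_frames,
      .groups = "drop"
    )
  if (validation == "strict") {
    if (nrow(dup)) {
      abort(sprintf("Duplicate (curve, frame) rows, e.g. %s",
                    paste(unlist(dup[1, id_cols]), collapse = "/")))
    }
    bad <- status %>% filter(!.data$complete)
    if (nrow(bad)) {
      abort(sprintf("Curve %s has an incomplete frame range.",
                    paste(unlist(bad[1, id_cols]), collapse = "/")))
    }
  } else {
    bad <- status %>% filter(!.data$complete)
    if (nrow(dup) || nrow(bad)) {
      warn(sprintf("Dropping %d incomplete/duplicated curve(s).",
                   dplyr::n_distinct(bind_rows(dup[id_cols], bad[id_cols]))))
      data <- data %>%
        anti_join(bind_rows(dup[id_cols], bad[id_cols]), by = id_cols)
    }
  }
  data
}

#' Write curves to a long-format CSV
#'
#' @param data Long curve (or difference-curve) tibble.
#' @param path Output file.
#' @return The data, invisibly.
#' @export
write_curves <- function(data, path) {
  readr::write_csv(as_tibble(data), path)
  invisible(data)
}

#' Write a limits-of-agreement band to CSV
#'
#' One row per frame with columns `frame`, `bias`, `lower`, `upper`,
#' `variance`, at full floating-point precision.
#'
#' @param band A `floa_band`.
#' @param path Output file.
#' @return The band, invisibly.
#' @export
write_band <- function(band, path) {
  cols <- c("frame", "bias", "lower", "upper", "variance")
  stopifnot(all(cols %in% names(band)))
  readr::write_csv(as_tibble(band)[cols], path)
  invisible(band)
}

#' Read a band CSV written by [write_band()]
#'
#' @param path CSV file.
#' @param multiplier Band multiplier to record on the object.
#' @return A `floa_band` tibble.
#' @export
read_band <- function(path, multiplier = 2) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  attr(out, "multiplier") <- multiplier
  class(out) <- c("floa_band", class(out))
  out
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Reads the file, applies [floa_config()] defaults, and rejects unknown
#' keys with field-level messages.
#'
#' @param path YAML (or JSON) configuration file; `NULL` returns defaults.
#' @return A `floa_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(floa_config())
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  # YAML reads candidate vectors as lists; flatten leaf lists of scalars
  cfg <- rapply(cfg, function(x) x, how = "replace")
  do.call(floa_config, cfg)
}

#' Serialize a fitted model summary to JSON
#'
#' Writes the fixed effects, per-level covariance matrices, error variance,
#' ARMA coefficients, REML value and convergence information.
#'
#' @param fit A `floa_fit`.
#' @param path Output JSON file.
#' @return The fit, invisibly.
#' @export
write_model_json <- function(fit, path) {
  stopifnot(inherits(fit, "floa_fit"))
  out <- list(
    beta = unname(fit$beta),
    psi = lapply(fit$psi, unname),
    psi_diagonals = lapply(fit$psi, function(m) unname(diag(m))),
    sigma2 = fit$sigma2,
    phi = fit$phi, theta = fit$theta,
    error = list(family = fit$error$family, p = fit$error$p, q = fit$error$q),
    reml_loglik = fit$reml_loglik,
    converged = fit$converged,
    n_params = fit$n_params,
    fixed_basis = list(
      kind = fit$fixed_basis$kind,
      n_inner = fit$fixed_basis$n_inner,
      n_basis = ncol(fit$fixed_basis$matrix)
    ),
    random_basis = list(
      kind = fit$random_basis$kind,
      n_basis = ncol(fit$random_basis$matrix)
    )
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' Export a knot-selection report as JSON
#'
#' @param selection A `floa_knot_selection` from [select_knots()].
#' @param path Output JSON file.
#' @return The selection, invisibly.
#' @export
write_knot_report <- function(selection, path) {
  stopifnot(inherits(selection, "floa_knot_selection"))
  jsonlite::write_json(
    list(
      chosen_n_inner = selection$n_inner,
      attained = selection$attained,
      threshold = selection$threshold,
      report = selection$report
    ),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(selection)
}
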