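# Long-format curve tables -----------------------------------------------
#
# Paired-method curve data live in a long tibble with columns
#   method, subject, session, replicate, frame (0-based integer), value
# and optionally `scenario` (joint x plane label).  Difference curves use the
# same layout without `method`.

curve_id_cols <- c("subject", "session", "replicate")

#' Validate a long paired-method curve table
#'
#' @param data Data frame with columns `method`, `subject`, `session`,
#'   `replicate`, `frame`, `value` (and optionally `scenario`).
#' @return The data as a tibble, with key columns as character and `frame`
#'   as integer.
#' @export
as_curve_tbl <- function(data) {
  need <- c("method", curve_id_cols, "frame", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("Missing columns: ", paste(miss, collapse = ", "), "."))
  }
  out <- as_tibble(data)
  if (!is.numeric(out$value)) abort("`value` must be numeric.")
  out %>%
    mutate(
      across(all_of(c("method", curve_id_cols)), as.character),
      frame = as.integer(.data$frame)
    )
}

as_diff_tbl <- function(data) {
  need <- c(curve_id_cols, "frame", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("Missing columns: ", paste(miss, collapse = ", "), "."))
  }
  as_tibble(data) %>%
    mutate(
      across(all_of(curve_id_cols), as.character),
      frame = as.integer(.data$frame)
    )
}

curve_keys <- function(diffs) {
  diffs %>%
    distinct(across(all_of(curve_id_cols))) %>%
    arrange(.data$subject, .data$session, .data$replicate)
}

# Frames-by-curves matrix, columns ordered as curve_keys().
curves_matrix <- function(diffs, grid = grid_from_frames(diffs$frame)) {
  keys <- curve_keys(diffs)
  wide <- diffs %>%
    arrange(.data$subject, .data$session, .data$replicate, .data$frame) %>%
    tidyr::pivot_wider(
      id_cols = "frame",
      names_from = all_of(curve_id_cols),
      values_from = "value"
    ) %>%
    arrange(.data$frame)
  if (nrow(wide) != grid$n_frames || anyNA(wide)) {
    abort("Curves must be complete on a common frame grid.")
  }
  m <- as.matrix(wide[, -1, drop = FALSE])
  dimnames(m) <- NULL
  m
}

# Preprocessing ------------------------------------------------------------

#' Resample a movement curve onto a normalized time grid
#'
#' Linear interpolation of a raw-length curve onto `n_frames` equally spaced
#' points spanning the whole movement, preserving the first and last raw
#' values exactly.  The method for data frames resamples every
#' (method, subject, session, replicate) curve.
#'
#' @param x Numeric curve vector, or a long curve data frame.
#' @param n_frames Target grid size (101 for percent-of-movement curves).
#' @param ... Unused.
#' @return A numeric vector of length `n_frames`, or a long tibble whose
#'   `frame` column runs 0..`n_frames - 1` per curve.
#' @export
time_normalize <- function(x, n_frames = 101, ...) UseMethod("time_normalize")

#' @export
time_normalize.numeric <- function(x, n_frames = 101, ...) {
  if (length(x) < 2) abort("A curve needs at least 2 points to resample.")
  approx(seq(0, 1, length.out = length(x)), x,
         xout = seq(0, 1, length.out = n_frames))$y
}

#' @export
time_normalize.data.frame <- function(x, n_frames = 101, ...) {
  x <- as_curve_tbl(x)
  grp <- intersect(c("scenario", "method", curve_id_cols), names(x))
  x %>%
    arrange(.data$frame) %>%
    group_by(across(all_of(grp))) %>%
    dplyr::reframe(
      frame = 0:(n_frames - 1L),
      value = time_normalize(.data$value, n_frames)
    )
}

#' Convert angle curves to range of motion
#'
#' Subtracts the initial angle from the whole curve, so every curve starts at
#' zero; this is the "range of motion" convention of the biomechanics
#' literature and removes between-system offsets in the resting pose.
#'
#' @param x Numeric curve vector, or a long curve data frame (each curve is
#'   re-baselined separately).
#' @param ... Unused.
#' @return Same shape as the input.
#' @export
range_of_motion <- function(x, ...) UseMethod("range_of_motion")

#' @export
range_of_motion.numeric <- function(x, ...) {
  if (!length(x)) abort("Empty curve.")
  x - x[[1]]
}

#' @export
range_of_motion.data.frame <- function(x, ...) {
  x <- as_curve_tbl(x)
  grp <- intersect(c("scenario", "method", curve_id_cols), names(x))
  x %>%
    arrange(.data$frame) %>%
    group_by(across(all_of(grp))) %>%
    mutate(value = .data$value - first(.data$value)) %>%
    ungroup()
}

#' Align the sign convention of one method's curves
#'
#' Two motion-capture systems can report an angle with opposite positive
#' directions (in the study that motivated this package, low-spine angles
#' from the markerless system were multiplied by -1).  `rules` gives one
#' multiplier per (scenario, method) pair; all other curves are untouched.
#'
#' @param data Long curve data frame with a `scenario` column.
#' @param rules Data frame with columns `scenario`, `method`, `multiplier`
#'   (each multiplier +1 or -1).
#' @return The data with adjusted `value`s.
#' @export
align_sign <- function(data, rules) {
  data <- as_curve_tbl(data)
  if (!"scenario" %in% names(data)) abort("`data` must have a `scenario` column.")
  rules <- as_tibble(rules) %>%
    mutate(scenario = as.character(.data$scenario), method = as.character(.data$method))
  if (!all(rules$multiplier %in% c(-1, 1))) abort("Multipliers must be +1 or -1.")
  unknown <- setdiff(rules$scenario, unique(data$scenario))
  if (length(unknown)) {
    abort(paste0("Unknown scenario in rules: ", paste(unknown, collapse = ", "), "."))
  }
  data %>%
    left_join(rules, by = c("scenario", "method")) %>%
    mutate(
      value = .data$value * dplyr::coalesce(.data$multiplier, 1),
      multiplier = NULL
    )
}

#' Frame-wise differences between two methods' curves
#'
#' For every (subject, session, replicate) with curves from both methods,
#' computes the difference curve `method_1 - method_2` frame by frame; these
#' difference curves are the response of the agreement model.  Unpaired
#' curves are dropped with a warning.
#'
#' @param data Long paired curve data frame.
#' @param methods Character vector of length 2: the minuend and subtrahend
#'   method labels.  Defaults to the two methods present, in sorted order.
#' @return Long tibble of difference curves (`subject`, `session`,
#'   `replicate`, `frame`, `value`, and `scenario` if present).
#' @export
compute_differences <- function(data, methods = NULL) {
  data <- as_curve_tbl(data)
  present <- sort(unique(data$method))
  if (is.null(methods)) {
    if (length(present) != 2) {
      abort("`data` must contain exactly two methods, or give `methods`.")
    }
    methods <- present
  }
  if (length(methods) != 2 || !all(methods %in% present)) {
    abort("`methods` must name two methods present in the data.")
  }
  keys <- intersect(c("scenario", curve_id_cols), names(data))
  wide <- data %>%
    filter(.data$method %in% methods) %>%
    tidyr::pivot_wider(
      id_cols = all_of(c(keys, "frame")),
      names_from = "method", values_from = "value"
    )
  unpaired <- !stats::complete.cases(wide[, methods])
  if (any(unpaired)) {
    warn(sprintf("Dropping %d unpaired curve(s).",
                 nrow(distinct(wide[unpaired, ], across(all_of(keys))))))
    wide <- wide[!unpaired, , drop = FALSE]
  }
  wide %>%
    mutate(value = .data[[methods[1]]] - .data[[methods[2]]]) %>%
    select(all_of(c(keys, "frame", "value"))) %>%
    arrange(.data$subject, .data$session, .data$replicate, .data$frame)
}
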