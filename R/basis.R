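#' Equally spaced interior knots on a frame grid
#'
#' Interior knots for a regression spline are placed at equal spacing in the
#' open interval between the grid endpoints; the boundary knots themselves are
#' supplied by the evaluator (clamped, with multiplicity degree + 1) and are
#' not part of this sequence.
#'
#' @param n_inner Number of interior knots (non-negative integer).
#' @param grid A [frame_grid()].
#'
#' @return Numeric vector of `n_inner` strictly interior knot positions
#'   (empty when `n_inner = 0`).
#' @examples
#' make_inner_knots(3, frame_grid(101)) # quartiles of [0, 100]
#' @export
make_inner_knots <- function(n_inner, grid = frame_grid()) {
  if (!is.numeric(n_inner) || length(n_inner) != 1L || n_inner < 0 ||
      n_inner != round(n_inner)) {
    abort("`n_inner` must be a single non-negative integer.")
  }
  if (n_inner == 0) return(numeric(0))
  seq(grid$t_min, grid$t_max, length.out = n_inner + 2)[-c(1, n_inner + 2)]
}

#' Evaluate a cubic (or other degree) B-spline basis system on a grid
#'
#' Builds the matrix of B-spline basis functions evaluated at the grid points,
#' with equally spaced interior knots and clamped boundary knots at the grid
#' endpoints.  Two dialects are supported: without an intercept column the
#' basis has `n_inner + degree` functions (the count used when the basis is
#' combined with a model intercept or when curves have been baselined); with
#' the intercept column it has `n_inner + degree + 1` functions and its rows
#' sum to one (partition of unity).
#'
#' @param grid A [frame_grid()].
#' @param n_inner Number of equally spaced interior knots.
#' @param degree Spline degree; 3 (cubic) is the default used for movement
#'   curves, whose derivatives are not of interest here.
#' @param intercept Logical; include the first basis function so the system
#'   spans constants.
#' @param orthonormal Logical; orthonormalize the columns (Gram-Schmidt) so
#'   they span the same spline space with `B'B = I`.  Useful as a truth
#'   basis for simulation, where a diagonal coefficient covariance on an
#'   orthonormal basis is invariant to within-span rotations.
#'
#' @return An object of class `floa_basis`: a list with the evaluated
#'   `matrix` (`n_frames` rows), `kind = "bspline"`, the knots and the grid.
#' @examples
#' b <- bspline_basis(frame_grid(101), n_inner = 9)
#' ncol(b$matrix) # 12 basis functions
#' @export
bspline_basis <- function(grid = frame_grid(), n_inner = 9, degree = 3,
                          intercept = FALSE, orthonormal = FALSE) {
  stopifnot(is_frame_grid(grid))
  if (degree < 1 || degree != round(degree)) abort("`degree` must be an integer >= 1.")
  n_basis <- n_inner + degree + as.integer(intercept)
  if (n_basis > grid$n_frames) {
    abort("Degenerate basis: more basis functions than grid points.")
  }
  knots <- make_inner_knots(n_inner, grid)
  mat <- splines::bs(
    grid$points,
    knots = knots, degree = degree, intercept = intercept,
    Boundary.knots = c(grid$t_min, grid$t_max)
  )
  mat <- unclass(mat)[, , drop = FALSE]
  attributes(mat)[setdiff(names(attributes(mat)), "dim")] <- NULL
  if (any(colSums(abs(mat)) == 0)) {
    abort("Degenerate basis: a basis function is zero on the whole grid.")
  }
  if (orthonormal) {
    mat <- qr.Q(qr(mat))
    # deterministic signs: largest-magnitude entry of each column positive
    sgn <- apply(mat, 2, function(col) sign(col[which.max(abs(col))]))
    mat <- sweep(mat, 2, sgn, `*`)
  }
  colnames(mat) <- paste0("bs", seq_len(ncol(mat)))
  structure(
    list(
      matrix = mat, kind = "bspline", degree = as.integer(degree),
      n_inner = as.integer(n_inner), knots = knots,
      intercept = isTRUE(intercept), orthonormal = isTRUE(orthonormal),
      grid = grid
    ),
    class = "floa_basis"
  )
}

#' @export
print.floa_basis <- function(x, ...) {
  if (x$kind == "bspline") {
    cat(sprintf(
      "<floa_basis> B-spline: degree %d, %d inner knots, %d functions%s on %d frames\n",
      x$degree, x$n_inner, ncol(x$matrix),
      if (x$intercept) " (with intercept)" else "", x$grid$n_frames
    ))
  } else {
    cat(sprintf(
      "<floa_basis> eigenbasis: %d of %d eigenvectors (%.1f%% of variance) on %d frames\n",
      ncol(x$matrix), length(x$eigenvalues),
      100 * sum(x$eigenvalues[seq_len(ncol(x$matrix))]) / sum(x$eigenvalues),
      x$grid$n_frames
    ))
  }
  invisible(x)
}

is_floa_basis <- function(x) inherits(x, "floa_basis")

#' Wrap an arbitrary evaluated basis matrix
#'
#' Escape hatch for non-spline designs (a constant column for a classical
#' random-intercept model, polynomial columns, externally computed bases).
#' The matrix is used as-is for fixed or random effects.
#'
#' @param matrix Numeric matrix with one row per grid frame.
#' @param grid Matching [frame_grid()].
#' @param intercept Does the column span include constants?  Controls
#'   whether smoothing fits add an intercept.
#' @return A `floa_basis` with `kind = "custom"`.
#' @export
custom_basis <- function(matrix, grid = frame_grid(nrow(matrix)),
                         intercept = TRUE) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != grid$n_frames) abort("Row count must match the grid.")
  if (is.null(colnames(matrix))) colnames(matrix) <- paste0("c", seq_len(ncol(matrix)))
  structure(
    list(matrix = matrix, kind = "custom", intercept = isTRUE(intercept),
         grid = grid),
    class = "floa_basis"
  )
}

# Design matrix for least-squares smoothing of a single curve: the basis
# columns plus an explicit intercept when the basis does not span constants.
smoothing_design <- function(basis) {
  if (basis$intercept %||% FALSE || basis$kind == "eigen_intercept") {
    basis$matrix
  } else {
    cbind(`(Intercept)` = 1, basis$matrix)
  }
}

#' Adjusted R-squared of a spline (or other basis) fit to one curve
#'
#' Fits the curve on the basis functions by ordinary least squares (adding an
#' intercept when the basis does not span constants) and returns the adjusted
#' R-squared, `1 - (RSS / (n - q)) / (TSS / (n - 1))`, with `q` the number of
#' fitted coefficients.
#'
#' @param values Numeric vector of curve values, one per grid frame.
#' @param basis A [bspline_basis()] (or eigenbasis) on the same grid.
#'
#' @return Adjusted R-squared in `(-Inf, 1]`.
#' @export
adjusted_r2 <- function(values, basis) {
  stopifnot(is_floa_basis(basis))
  n <- basis$grid$n_frames
  if (length(values) != n) abort("`values` length must equal the grid size.")
  tss <- sum((values - mean(values))^2)
  if (tss <= 0) abort("Adjusted R-squared is undefined for a constant curve.")
  X <- smoothing_design(basis)
  q <- ncol(X)
  if (n <= q) abort("Fit is not well-posed: need more frames than coefficients.")
  rss <- sum(stats::lm.fit(X, values)$residuals^2)
  1 - (rss / (n - q)) / (tss / (n - 1))
}

# Per-curve adjusted R-squared for a long difference-curve table.
curve_adjusted_r2 <- function(diffs, basis) {
  diffs <- as_diff_tbl(diffs)
  keys <- curve_keys(diffs)
  mats <- curves_matrix(diffs, basis$grid)
  tibble(keys, adj_r2 = apply(mats, 2, adjusted_r2, basis = basis))
}

#' Select the number of interior knots by the adjusted R-squared rule
#'
#' Fits a regression spline to every individual difference curve for each
#' candidate number of equally spaced interior knots, and returns the smallest
#' candidate for which all curves reach the adjusted R-squared threshold.
#' When no candidate qualifies the largest candidate is returned with
#' `attained = FALSE` and a warning, so pipelines can proceed.
#'
#' @param diffs Difference curves in long form (columns `subject`, `session`,
#'   `replicate`, `frame`, `value`), e.g. from [compute_differences()].
#' @param candidates Ascending candidate numbers of interior knots.
#' @param threshold Adjusted R-squared that every curve must reach.
#' @param degree,intercept Passed to [bspline_basis()].
#'
#' @return A list of class `floa_knot_selection`: `n_inner` (chosen),
#'   `attained`, the chosen `basis`, and a `report` tibble with the minimum
#'   and median adjusted R-squared per candidate.
#' @export
select_knots <- function(diffs, candidates = c(0, 1, 3, 9, 19, 32),
                         threshold = 0.95, degree = 3, intercept = FALSE) {
  if (length(candidates) == 0) abort("`candidates` must be non-empty.")
  if (is.unsorted(candidates, strictly = TRUE)) {
    abort("`candidates` must be strictly ascending.")
  }
  diffs <- as_diff_tbl(diffs)
  if (nrow(diffs) == 0) abort("Empty curve set.")
  grid <- grid_from_frames(diffs$frame)
  report <- purrr::map_dfr(candidates, function(k) {
    basis <- bspline_basis(grid, n_inner = k, degree = degree, intercept = intercept)
    r2 <- curve_adjusted_r2(diffs, basis)$adj_r2
    tibble(n_inner = k, n_basis = ncol(basis$matrix),
           min_adj_r2 = min(r2), median_adj_r2 = stats::median(r2))
  })
  ok <- report$min_adj_r2 >= threshold
  attained <- any(ok)
  n_inner <- if (attained) report$n_inner[which(ok)[1]] else max(candidates)
  if (!attained) {
    warn(sprintf(
      "No candidate reaches adjusted R-squared >= %.3f on every curve; using the largest (%d inner knots).",
      threshold, n_inner
    ))
  }
  structure(
    list(
      n_inner = n_inner, attained = attained, threshold = threshold,
      basis = bspline_basis(grid, n_inner = n_inner, degree = degree,
                            intercept = intercept),
      report = report
    ),
    class = "floa_knot_selection"
  )
}

#' @export
print.floa_knot_selection <- function(x, ...) {
  cat(sprintf(
    "<floa_knot_selection> %d inner knots (threshold %.2f%s)\n",
    x$n_inner, x$threshold, if (x$attained) "" else ", not attained"
  ))
  print(x$report)
  invisible(x)
}

#' Export a basis matrix as CSV
#'
#' Writes the evaluated basis (one row per frame, one column per basis
#' function) with a leading `frame` column.
#'
#' @param basis A `floa_basis`.
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_basis <- function(basis, path) {
  stopifnot(is_floa_basis(basis))
  out <- as_tibble(basis$matrix)
  out <- dplyr::bind_cols(tibble(frame = seq_len(basis$grid$n_frames) - 1L), out)
  readr::write_csv(out, path)
  invisible(basis)
}
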