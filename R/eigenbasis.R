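# Karhunen-Loeve eigenbasis for the random-effects design --------------------
#
# The sample covariance of the difference curves is eigendecomposed
# S = Q Lambda Q'; the leading eigenvectors explaining a stated fraction of
# the variance form an orthonormal basis on the frame grid.  Because the
# coefficients of a zero-mean process on the eigenfunctions of its covariance
# are uncorrelated, a diagonal random-effects covariance becomes a natural
# choice on this basis, which is what makes the fast fitting path cheap.

#' Sample covariance matrix of a set of curves
#'
#' Pools all curves (across subjects, sessions and replicates of one
#' scenario) and computes the unbiased (n - 1 denominator) frame-by-frame
#' covariance, after subtracting the pointwise mean curve by default.
#'
#' @param diffs Long difference-curve table.
#' @param center `"sample_mean"` (default) subtracts the mean curve;
#'   `"none"` uses raw cross-products.
#' @return A list of class `floa_covariance`: `matrix` (frames x frames),
#'   `n_curves`, `center`, `grid`.
#' @export
curve_covariance <- function(diffs, center = c("sample_mean", "none")) {
  center <- arg_match(center)
  diffs <- as_diff_tbl(diffs)
  grid <- grid_from_frames(diffs$frame)
  Y <- t(curves_matrix(diffs, grid)) # curves x frames
  if (nrow(Y) < 2) abort("Need at least 2 curves to form a covariance.")
  S <- if (center == "sample_mean") {
    cov(Y)
  } else {
    crossprod(Y) / (nrow(Y) - 1)
  }
  dimnames(S) <- NULL
  structure(
    list(matrix = S, n_curves = nrow(Y), center = center, grid = grid),
    class = "floa_covariance"
  )
}

#' Eigendecomposition of a curve covariance matrix
#'
#' @param S A `floa_covariance` (or a symmetric matrix).
#' @param tol Relative symmetry tolerance.
#' @return A list of class `floa_eigen`: descending `values`, orthogonal
#'   `vectors` (frames x frames), and the grid when available.  Eigenvalues
#'   below `1e-10 * max` are floored at zero.
#' @export
eigen_decompose <- function(S, tol = 1e-8) {
  grid <- NULL
  if (inherits(S, "floa_covariance")) {
    grid <- S$grid
    S <- S$matrix
  }
  if (!is.matrix(S) || nrow(S) != ncol(S)) abort("`S` must be square.")
  if (max(abs(S - t(S))) > tol * max(1, max(abs(S)))) {
    abort("`S` is not symmetric within tolerance.")
  }
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- e$values
  vals[vals < 1e-10 * max(vals, 0)] <- 0
  structure(
    list(values = vals, vectors = e$vectors, grid = grid),
    class = "floa_eigen"
  )
}

#' Truncate an eigendecomposition to a variance fraction
#'
#' Keeps the smallest leading set of eigenvectors whose eigenvalues sum to at
#' least `variance_fraction` of the total, and returns them as an orthonormal
#' basis system usable for the random-effects design.
#'
#' @param E A `floa_eigen` from [eigen_decompose()].
#' @param variance_fraction Fraction of total variance to retain (in (0, 1]).
#' @param grid Frame grid (taken from `E` when available).
#' @return A `floa_basis` with `kind = "eigen"`, carrying the full
#'   `eigenvalues` vector and the `variance_fraction` used.
#' @export
truncate_eigen <- function(E, variance_fraction = 0.99, grid = E$grid) {
  stopifnot(inherits(E, "floa_eigen"))
  if (variance_fraction <= 0 || variance_fraction > 1) {
    abort("`variance_fraction` must be in (0, 1].")
  }
  total <- sum(E$values)
  if (total <= 0) abort("All-zero covariance: no eigenbasis to keep.")
  cum <- cumsum(E$values) / total
  n_keep <- which(cum >= variance_fraction - 1e-12)[1]
  if (variance_fraction == 1) n_keep <- sum(E$values > 0)
  if (is.null(grid)) grid <- frame_grid(nrow(E$vectors), 0, nrow(E$vectors) - 1)
  mat <- E$vectors[, seq_len(n_keep), drop = FALSE]
  colnames(mat) <- paste0("ef", seq_len(n_keep))
  structure(
    list(
      matrix = mat, kind = "eigen", eigenvalues = E$values,
      variance_fraction = variance_fraction, n_kept = n_keep,
      intercept = FALSE, grid = grid
    ),
    class = "floa_basis"
  )
}

#' Eigenbasis of the difference curves in one call
#'
#' Convenience wrapper: [curve_covariance()], [eigen_decompose()], then
#' [truncate_eigen()] at the requested variance fraction.
#'
#' @inheritParams curve_covariance
#' @inheritParams truncate_eigen
#' @return A `floa_basis` with `kind = "eigen"`.
#' @export
eigen_basis <- function(diffs, variance_fraction = 0.99,
                        center = c("sample_mean", "none")) {
  S <- curve_covariance(diffs, center = center)
  truncate_eigen(eigen_decompose(S), variance_fraction, grid = S$grid)
}

#' Scree summary of an eigendecomposition
#'
#' @param E A `floa_eigen` or eigen-kind `floa_basis`.
#' @return Tibble with `component`, `eigenvalue`, `cumulative_fraction`.
#' @export
scree <- function(E) {
  vals <- if (inherits(E, "floa_eigen")) E$values else E$eigenvalues
  if (is.null(vals)) abort("No eigenvalues found.")
  tibble(
    component = seq_along(vals),
    eigenvalue = vals,
    cumulative_fraction = cumsum(vals) / sum(vals)
  )
}
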