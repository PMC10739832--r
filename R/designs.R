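# Design bundles for the three-level functional mixed model -----------------
#
# Difference curves d_ijk (subject i, session j, replicate k) on a common
# frame grid are modelled as
#   d_ijk = X beta + Z b_i + Z b_ij + Z b_ijk + eps_ijk,
# with X a fixed-effects basis evaluated on the grid, one random-effects
# basis per nesting level, and eps an ARMA-correlated error.  Subjects are
# independent, so everything downstream works on per-subject blocks.  For
# fully balanced designs (every subject has the complete session x replicate
# crossing and all curves share the same bases) an orthogonal contrast
# transform across a subject's curves block-diagonalizes the covariance into
# three frame-sized blocks, which is what makes REML evaluations cheap; the
# transform is precomputed here.

level_names <- c("subject", "session", "replicate")

#' Random-effects level specifications
#'
#' Builds the per-level random-effects specification used by
#' [build_designs()] and [fit_floa_lmm()]: the same basis system at each
#' requested nesting level (the strategy used throughout this package), with
#' either an unstructured or a diagonal coefficient covariance.  A diagonal
#' covariance is the natural companion of an orthonormal eigenbasis; an
#' unstructured covariance is the safe default for a B-spline basis.
#'
#' @param basis A `floa_basis` shared by all levels.
#' @param covariance `"unstructured"` or `"diagonal"`.
#' @param levels Which nesting levels get random effects.
#' @return Named list of per-level specs (`basis`, `covariance`).
#' @export
random_levels <- function(basis,
                          covariance = c("unstructured", "diagonal"),
                          levels = c("subject", "session", "replicate")) {
  covariance <- arg_match(covariance)
  stopifnot(is_floa_basis(basis))
  levels <- match.arg(levels, level_names, several.ok = TRUE)
  setNames(
    lapply(levels, function(l) list(basis = basis, covariance = covariance)),
    levels
  )
}

#' Assemble stacked designs for the difference-curve mixed model
#'
#' Groups the difference curves into per-subject blocks, attaches the fixed
#' and random-effects basis matrices, and detects whether the design is
#' balanced (identical complete session-by-replicate layout for every
#' subject), in which case the orthogonal-contrast transform of each
#' subject's curves is precomputed.
#'
#' @param diffs Long difference-curve table.
#' @param fixed_basis `floa_basis` for the mean (bias) curve.
#' @param random Named per-level list from [random_levels()] (may omit
#'   levels; omitted levels carry no random effects).
#' @return An object of class `floa_designs`.
#' @export
build_designs <- function(diffs, fixed_basis, random) {
  diffs <- as_diff_tbl(diffs)
  grid <- grid_from_frames(diffs$frame)
  stopifnot(is_floa_basis(fixed_basis))
  if (fixed_basis$grid$n_frames != grid$n_frames) {
    abort("Fixed basis grid does not match the data grid.")
  }
  if (!all(names(random) %in% level_names)) {
    abort("`random` names must be among subject/session/replicate.")
  }
  random <- random[intersect(level_names, names(random))] # canonical order
  for (spec in random) {
    if (spec$basis$grid$n_frames != grid$n_frames) {
      abort("A random-effects basis grid does not match the data grid.")
    }
    if (!spec$covariance %in% c("unstructured", "diagonal")) {
      abort("Covariance must be 'unstructured' or 'diagonal'.")
    }
  }

  X <- fixed_basis$matrix
  keys <- curve_keys(diffs)
  counts <- keys %>%
    group_by(.data$subject, .data$session) %>%
    summarise(K = n(), .groups = "drop")

  # identifiability warnings
  if ("subject" %in% names(random) && dplyr::n_distinct(keys$subject) < 2) {
    warn("Subject-level random effects are unidentifiable with < 2 subjects.")
  }
  J_per <- keys %>%
    group_by(.data$subject) %>%
    summarise(J = dplyr::n_distinct(.data$session), .groups = "drop")
  if ("session" %in% names(random) && all(J_per$J < 2)) {
    warn("Session-level random effects are unidentifiable with < 2 sessions per subject.")
  }
  if ("replicate" %in% names(random) && all(counts$K < 2)) {
    warn("Replicate-level random effects are unidentifiable with < 2 replicates per session.")
  }

  T_ <- grid$n_frames
  subjects <- keys %>% dplyr::group_split(.data$subject)
  blocks <- lapply(subjects, function(k) {
    k <- arrange(k, .data$session, .data$replicate)
    sub_diffs <- diffs %>% filter(.data$subject == k$subject[1])
    Y <- curves_matrix(sub_diffs, grid) # ordered as curve_keys: session, replicate
    list(subject = k$subject[1], keys = k, Y = Y,
         session = k$session, replicate = k$replicate)
  })

  sess_sets <- lapply(blocks, function(b) sort(unique(b$session)))
  J <- length(sess_sets[[1]])
  same_sessions <- all(vapply(sess_sets, function(s) identical(s, sess_sets[[1]]), TRUE))
  Ks <- counts$K
  balanced <- same_sessions && length(unique(Ks)) == 1 &&
    all(vapply(blocks, function(b) {
      identical(as.integer(table(b$session)), rep(Ks[1], length(sess_sets[[1]])))
    }, TRUE))
  K <- if (balanced) Ks[1] else NA_integer_

  des <- list(
    grid = grid, X = X, fixed_basis = fixed_basis, random = random,
    blocks = blocks, keys = keys,
    n_subjects = length(blocks),
    N = nrow(diffs), p = ncol(X),
    balanced = balanced, J = if (balanced) J else NA_integer_, K = K
  )

  if (balanced) {
    des$transforms <- balanced_transforms(blocks, J, K, T_)
  }
  structure(des, class = "floa_designs")
}

#' @export
print.floa_designs <- function(x, ...) {
  cat(sprintf(
    "<floa_designs> %d subjects, %d curves, %d frames; levels: %s; %s\n",
    x$n_subjects, nrow(x$keys), x$grid$n_frames,
    paste(names(x$random), collapse = "/"),
    if (x$balanced) sprintf("balanced %dx%d", x$J, x$K) else "unbalanced"
  ))
  invisible(x)
}

# Orthonormal rows contrasting n items (n-1 x n), plus implied mean row.
helmert_rows <- function(n) {
  if (n < 2) return(matrix(0, 0, n))
  H <- t(stats::contr.helmert(n))
  H / sqrt(rowSums(H^2))
}

# Precompute contrast-transformed curves for the balanced fast path.
# Columns of each subject's Y are ordered session-major, replicate-minor.
balanced_transforms <- function(blocks, J, K, T_) {
  hK <- helmert_rows(K)                       # (K-1) x K
  hJ <- helmert_rows(J)                       # (J-1) x J
  U3 <- U2 <- NULL
  U1 <- matrix(0, T_, length(blocks))
  U3l <- list(); U2l <- list()
  for (b in seq_along(blocks)) {
    Y <- blocks[[b]]$Y                        # T x (J*K)
    if (K > 1) {
      # within-session replicate contrasts, session by session
      u3 <- matrix(0, T_, J * (K - 1))
      for (j in seq_len(J)) {
        cols <- (j - 1) * K + seq_len(K)
        u3[, (j - 1) * (K - 1) + seq_len(K - 1)] <- Y[, cols] %*% t(hK)
      }
      U3l[[b]] <- u3
    }
    if (J > 1) {
      sess_means <- sapply(seq_len(J), function(j) {
        rowMeans(Y[, (j - 1) * K + seq_len(K), drop = FALSE])
      })
      U2l[[b]] <- (sess_means %*% t(hJ)) * sqrt(K)
    }
    U1[, b] <- rowMeans(Y) * sqrt(J * K)
  }
  list(
    U3 = if (K > 1) do.call(cbind, U3l) else matrix(0, T_, 0),
    U2 = if (J > 1) do.call(cbind, U2l) else matrix(0, T_, 0),
    U1 = U1
  )
}

#' Count variance parameters of a model specification
#'
#' Bookkeeping for the size of the variance-parameter space: each
#' unstructured level covariance of dimension q contributes q(q+1)/2
#' parameters and each diagonal one contributes q; the error adds one
#' variance plus its ARMA coefficients.
#'
#' @param q Integer vector of random-effects basis sizes, one per level.
#' @param covariance `"unstructured"` or `"diagonal"`, recycled over levels.
#' @param error A `floa_error` specification.
#' @return List with `psi` (level subtotal), `error` (1 + p + q), `total`.
#' @examples
#' count_variance_parameters(rep(12, 3))$psi # 234
#' @export
count_variance_parameters <- function(q, covariance = "unstructured",
                                      error = error_arma(2, 1)) {
  covariance <- rep_len(covariance, length(q))
  psi <- sum(ifelse(covariance == "unstructured", q * (q + 1) / 2, q))
  err <- 1L + n_error_params(error)
  list(psi = as.integer(psi), error = as.integer(err),
       total = as.integer(psi + err))
}
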