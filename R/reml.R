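# Restricted maximum likelihood for the hierarchical functional model -------
#
# The marginal covariance of a subject's stacked curves is
#   V_i = Z1 Psi1 Z1' (all curves) + Z2 Psi2 Z2' (within session)
#       + Z3 Psi3 Z3' (within curve) + sigma2 * C (within curve),
# with C the ARMA correlation matrix on the frame grid.  Internally the
# level covariances are carried *relative* to sigma2 (Psi_l = sigma2 * D_l),
# so that both beta (by GLS) and sigma2 can be profiled out of the
# restricted likelihood; the optimizer then works on the unconstrained
# log-Cholesky / log-variance / partial-autocorrelation scale only.
#
# Two evaluation paths produce identical results: a dense per-subject path
# (always correct) and a fast path for balanced designs that uses the
# precomputed contrast transform, under which the subject covariance
# block-diagonalizes into
#   M3 = C + G3                (within-session replicate contrasts)
#   M2 = M3 + K G2             (session contrasts)
#   M1 = M2 + J K G1           (subject mean curve)
# with G_l = Z_l D_l Z_l'.  Only the mean block carries the fixed effects,
# because X is shared by all of a subject's curves.

#' Variance-parameter sets for the difference-curve model
#'
#' Bundles the per-level random-effect covariances (degrees squared), the
#' error variance, and the error-correlation coefficients into one object,
#' used by [reml_criterion()], [marginal_covariance()] and the synthetic
#' generator.
#'
#' @param psi Named list (`subject`, `session`, `replicate`; any subset) of
#'   covariance matrices, or numeric vectors interpreted as diagonals.
#' @param sigma2 Error variance (> 0).
#' @param phi,theta AR and MA coefficients of the error correlation (empty
#'   for white noise).  For a CAR(1) structure give `error = error_car1()`
#'   and the decay parameter in `phi`.
#' @param error Optional `floa_error`; inferred as ARMA/iid from `phi`,
#'   `theta` when missing.
#' @return An object of class `floa_params`.
#' @export
floa_params <- function(psi = list(), sigma2, phi = numeric(0),
                        theta = numeric(0), error = NULL) {
  if (!is.list(psi) || (length(psi) && is.null(names(psi)))) {
    abort("`psi` must be a named list.")
  }
  if (!all(names(psi) %in% level_names)) {
    abort("`psi` names must be among subject/session/replicate.")
  }
  psi <- lapply(psi, function(m) {
    if (is.numeric(m) && is.null(dim(m))) m <- diag(m, nrow = length(m))
    if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
      abort("Each `psi` must be symmetric.")
    }
    ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(sum(diag(m)), 1)) {
      abort("Each `psi` must be positive semi-definite.")
    }
    m
  })
  if (!is.numeric(sigma2) || sigma2 <= 0) abort("`sigma2` must be positive.")
  if (is.null(error)) {
    error <- if (length(phi) || length(theta)) {
      error_arma(length(phi), length(theta))
    } else {
      error_iid()
    }
  }
  if (error$family %in% c("ARMA", "AR1")) {
    if (!ar_stationary(phi)) abort("AR coefficients are not stationary.")
    if (!ma_invertible(theta)) abort("MA coefficients are not invertible.")
  }
  structure(
    list(psi = psi[intersect(level_names, names(psi))],
         sigma2 = sigma2, phi = as.numeric(phi), theta = as.numeric(theta),
         error = error),
    class = "floa_params"
  )
}

params_correlation <- function(params, n_frames) {
  coefs <- c(params$phi, params$theta)
  error_correlation(params$error, coefs, n_frames)
}

# G matrices (Z D Z') per level for given level covariances `cov_list`
# (NULL entries mean the level is absent -> zero contribution).
level_outer <- function(designs, cov_list) {
  out <- lapply(level_names, function(l) {
    if (is.null(cov_list[[l]]) || is.null(designs$random[[l]])) return(NULL)
    Z <- designs$random[[l]]$basis$matrix
    Z %*% cov_list[[l]] %*% t(Z)
  })
  setNames(out, level_names)
}

#' Marginal covariance of one subject's stacked curves
#'
#' Builds the dense model-implied covariance matrix of all curves of one
#' subject stacked end to end (curves ordered by session then replicate):
#' the subject-level term couples all the subject's curves, the
#' session-level term couples curves within a session, and the
#' replicate-level term and the error act within a curve.
#'
#' @param params A [floa_params()] on the natural (absolute) scale.
#' @param designs A [build_designs()] bundle.
#' @param subject Subject identifier (defaults to the first).
#' @return A symmetric positive semi-definite matrix of dimension
#'   curves-times-frames.
#' @export
marginal_covariance <- function(params, designs, subject = NULL) {
  stopifnot(inherits(params, "floa_params"), inherits(designs, "floa_designs"))
  ids <- vapply(designs$blocks, `[[`, "", "subject")
  idx <- if (is.null(subject)) 1L else match(as.character(subject), ids)
  if (is.na(idx)) abort("Unknown subject.")
  b <- designs$blocks[[idx]]
  T_ <- designs$grid$n_frames
  G <- level_outer(designs, params$psi)
  Sig <- params$sigma2 * params_correlation(params, T_)
  m <- ncol(b$Y)
  V <- matrix(0, m * T_, m * T_)
  for (a in seq_len(m)) {
    for (cc in seq_len(m)) {
      blk <- matrix(0, T_, T_)
      if (!is.null(G$subject)) blk <- blk + G$subject
      if (!is.null(G$session) && b$session[a] == b$session[cc]) blk <- blk + G$session
      if (a == cc) {
        if (!is.null(G$replicate)) blk <- blk + G$replicate
        blk <- blk + Sig
      }
      V[(a - 1) * T_ + 1:T_, (cc - 1) * T_ + 1:T_] <- blk
    }
  }
  (V + t(V)) / 2
}

# --- core evaluation (relative scale) ---------------------------------------

safe_chol <- function(M) tryCatch(chol(M), error = function(e) NULL)

chol_fsolve <- function(R, B) {
  forwardsolve(R, B, upper.tri = TRUE, transpose = TRUE)
}

# Dlist: named list of relative covariances (Psi_l / sigma2) for present
# levels; C: error correlation matrix.  Returns logdetW = sum_i log|W_i|,
# logdetB = log|sum_i X'W^-1 X|, the profiled-beta quadratic form Q, and
# beta; or NULL when a Cholesky fails (singular covariance).
reml_core <- function(designs, Dlist, C,
                      method = c("auto", "balanced", "dense")) {
  method <- match.arg(method)
  if (designs$balanced && method != "dense") {
    reml_core_balanced(designs, Dlist, C)
  } else {
    reml_core_dense(designs, Dlist, C)
  }
}

reml_core_balanced <- function(designs, Dlist, C) {
  T_ <- designs$grid$n_frames
  J <- designs$J; K <- designs$K; n <- designs$n_subjects
  G <- level_outer(designs, Dlist)
  zero <- matrix(0, T_, T_)
  G1 <- G$subject %||% zero
  G2 <- G$session %||% zero
  G3 <- G$replicate %||% zero
  M3 <- C + G3
  M2 <- M3 + K * G2
  M1 <- M2 + J * K * G1
  tr <- designs$transforms
  logdetW <- 0; Q <- 0
  if (ncol(tr$U3) > 0) {
    R3 <- safe_chol(M3); if (is.null(R3)) return(NULL)
    logdetW <- logdetW + n * J * (K - 1) * 2 * sum(log(diag(R3)))
    Q <- Q + sum(chol_fsolve(R3, tr$U3)^2)
  }
  if (ncol(tr$U2) > 0) {
    R2 <- safe_chol(M2); if (is.null(R2)) return(NULL)
    logdetW <- logdetW + n * (J - 1) * 2 * sum(log(diag(R2)))
    Q <- Q + sum(chol_fsolve(R2, tr$U2)^2)
  }
  R1 <- safe_chol(M1); if (is.null(R1)) return(NULL)
  logdetW <- logdetW + n * 2 * sum(log(diag(R1)))
  Xt <- sqrt(J * K) * designs$X
  AX <- chol_fsolve(R1, Xt)
  AU <- chol_fsolve(R1, tr$U1)
  B <- n * crossprod(AX)
  RB <- safe_chol(B); if (is.null(RB)) return(NULL)
  v <- crossprod(AX, rowSums(AU))
  beta <- backsolve(RB, chol_fsolve(RB, v))
  Q <- Q + sum((AU - as.vector(AX %*% beta))^2)
  list(
    logdetW = logdetW, logdetB = 2 * sum(log(diag(RB))),
    Q = Q, beta = as.numeric(beta)
  )
}

reml_core_dense <- function(designs, Dlist, C) {
  T_ <- designs$grid$n_frames
  p <- designs$p
  G <- level_outer(designs, Dlist)
  zero <- matrix(0, T_, T_)
  G1 <- G$subject %||% zero
  G2 <- G$session %||% zero
  G3 <- G$replicate %||% zero
  Glocal <- G3 + C
  B <- matrix(0, p, p); v <- numeric(p); qy <- 0; logdetW <- 0
  for (b in designs$blocks) {
    m <- ncol(b$Y)
    W <- matrix(0, m * T_, m * T_)
    for (a in seq_len(m)) {
      for (cc in seq_len(m)) {
        blk <- G1
        if (b$session[a] == b$session[cc]) blk <- blk + G2
        if (a == cc) blk <- blk + Glocal
        W[(a - 1) * T_ + 1:T_, (cc - 1) * T_ + 1:T_] <- blk
      }
    }
    R <- safe_chol(W); if (is.null(R)) return(NULL)
    logdetW <- logdetW + 2 * sum(log(diag(R)))
    Xs <- designs$X[rep(seq_len(T_), m), , drop = FALSE]
    A <- chol_fsolve(R, cbind(Xs, as.vector(b$Y)))
    AX <- A[, seq_len(p), drop = FALSE]
    Ay <- A[, p + 1]
    B <- B + crossprod(AX)
    v <- v + crossprod(AX, Ay)
    qy <- qy + sum(Ay^2)
  }
  RB <- safe_chol(B); if (is.null(RB)) return(NULL)
  beta <- backsolve(RB, chol_fsolve(RB, v))
  list(
    logdetW = logdetW, logdetB = 2 * sum(log(diag(RB))),
    Q = qy - sum(v * beta), beta = as.numeric(beta)
  )
}

#' Restricted log-likelihood of the difference-curve model
#'
#' Evaluates the REML criterion at given variance parameters, with the fixed
#' effects profiled out by generalized least squares.  The value includes
#' all constants, so on shared-capability models it is directly comparable
#' with the REML log-likelihood reported by general-purpose mixed-model
#' software.
#'
#' @param params A [floa_params()] on the natural scale.
#' @param designs A [build_designs()] bundle.
#' @param method Evaluation path: `"auto"` uses the balanced fast path when
#'   the design allows it, `"dense"` forces the per-subject dense path
#'   (results are identical).
#' @return The restricted log-likelihood; `-Inf` when the implied covariance
#'   is numerically singular.
#' @export
reml_criterion <- function(params, designs,
                           method = c("auto", "balanced", "dense")) {
  stopifnot(inherits(params, "floa_params"), inherits(designs, "floa_designs"))
  method <- match.arg(method)
  T_ <- designs$grid$n_frames
  Dlist <- lapply(params$psi, function(m) m / params$sigma2)
  C <- params_correlation(params, T_)
  core <- reml_core(designs, Dlist, C, method = method)
  if (is.null(core)) return(-Inf)
  N <- designs$N; p <- designs$p
  -0.5 * ((N - p) * log(2 * pi) + (N - p) * log(params$sigma2) +
            core$logdetW + core$logdetB + core$Q / params$sigma2)
}

# Profiled (over beta and sigma2) -2 restricted log-likelihood from a core.
profiled_neg2 <- function(core, N, p) {
  sigma2 <- core$Q / (N - p)
  (N - p) * (log(2 * pi * sigma2) + 1) + core$logdetW + core$logdetB
}
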