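# REML fitting of the three-level functional mixed model --------------------
#
# Unconstrained parameter vector layout (sigma2 and beta are profiled out):
#   for each random level, in subject/session/replicate order:
#     diagonal covariance    -> q log relative standard deviations
#     unstructured covariance-> q(q+1)/2 log-Cholesky entries (log diagonal,
#                               free sub-diagonal, column major)
#   then the error-correlation parameters on the unconstrained scale
#   (partial autocorrelations through atanh for ARMA/AR1, logistic for CAR1).

theta_layout <- function(designs, error) {
  lv <- lapply(names(designs$random), function(l) {
    q <- ncol(designs$random[[l]]$basis$matrix)
    type <- designs$random[[l]]$covariance
    list(level = l, q = q, type = type,
         n = if (type == "diagonal") q else q * (q + 1) / 2)
  })
  list(levels = lv, n_error = n_error_params(error),
       n = sum(vapply(lv, `[[`, 0, "n")) + n_error_params(error))
}

# theta segment -> relative covariance matrix D = L L'
segment_to_cov <- function(z, q, type) {
  if (type == "diagonal") return(diag(exp(2 * z), nrow = q))
  L <- matrix(0, q, q)
  L[lower.tri(L, diag = TRUE)] <- z
  diag(L) <- exp(diag(L))
  tcrossprod(L)
}

cov_to_segment <- function(D, type) {
  if (type == "diagonal") return(0.5 * log(diag(as.matrix(D))))
  L <- t(safe_chol(D + diag(1e-10 * max(diag(D)), nrow(D))))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

unpack_theta <- function(theta, layout, error) {
  pos <- 0L
  Dlist <- list()
  for (lv in layout$levels) {
    z <- theta[pos + seq_len(lv$n)]
    pos <- pos + lv$n
    Dlist[[lv$level]] <- segment_to_cov(z, lv$q, lv$type)
  }
  coefs <- unconstrained_to_error(error, theta[pos + seq_len(layout$n_error)])
  list(Dlist = Dlist, coefs = coefs)
}

# Moment-based starting values: smooth each curve on the fixed basis for a
# residual-variance scale, project curve deviations from the mean curve on
# each level's basis, and split the between-curve coefficient variance
# evenly across the levels (relative to the residual variance).  Perturbed
# starts cover the inevitable misscaling.
start_values <- function(designs, layout, error) {
  X <- designs$X
  curves <- do.call(cbind, lapply(designs$blocks, `[[`, "Y"))
  fits <- stats::lm.fit(X, curves)
  df <- max(nrow(X) - ncol(X), 1)
  sigma2_0 <- max(sum(fits$residuals^2) / (df * ncol(curves)), 1e-8)

  n_levels <- max(1, length(layout$levels))
  theta <- numeric(0)
  for (lv in layout$levels) {
    Z <- designs$random[[lv$level]]$basis$matrix
    co <- qr.coef(qr(Z), sweep(curves, 1, rowMeans(curves)))
    co <- matrix(co, nrow = ncol(Z))
    co[is.na(co)] <- 0
    d0 <- apply(co, 1, var)
    d0[!is.finite(d0)] <- 0
    d_rel <- pmax(d0 / sigma2_0 / n_levels, 1e-3)
    theta <- c(theta, cov_to_segment(diag(d_rel, nrow = lv$q), lv$type))
  }
  c(theta, rep(0.05, layout$n_error))
}

# Positions of the log-diagonal entries inside a lower-triangular
# column-major log-Cholesky segment.
diag_positions <- function(q) {
  if (q == 1) return(1L)
  cumsum(c(1L, rev(seq_len(q - 1)) + 1L))
}

perturb_start <- function(theta0, layout, fac) {
  th <- theta0
  off <- 0L
  for (lv in layout$levels) {
    pos <- if (lv$type == "diagonal") seq_len(lv$q) else diag_positions(lv$q)
    th[off + pos] <- th[off + pos] + 0.5 * log(fac)
    off <- off + lv$n
  }
  th
}

#' Fit the functional limits-of-agreement mixed model by REML
#'
#' Estimates the three-level (subject / session / replicate) mixed model for
#' difference curves: fixed-effects bias curve on a B-spline basis, random
#' smooth deviations at each nesting level on a shared basis (B-spline with
#' unstructured covariance, or covariance eigenbasis with diagonal
#' covariance), and ARMA-correlated within-curve errors.  The fixed effects
#' and the error variance are profiled out; the remaining variance
#' parameters are maximized on an unconstrained scale by quasi-Newton
#' optimization with multiple starts.
#'
#' @param diffs Long difference-curve table (see [compute_differences()]).
#' @param fixed_basis `floa_basis` for the bias curve.
#' @param random_basis `floa_basis` shared by the random-effects levels
#'   (defaults to `fixed_basis`).
#' @param covariance Random-effects covariance structure per level.
#' @param error A `floa_error` specification ([error_arma()] and friends).
#' @param levels Nesting levels that receive random effects.
#' @param n_starts Number of optimizer starts (moment-based start plus
#'   perturbations).
#' @param method REML evaluation path, see [reml_criterion()].
#' @param control Passed to [stats::nlminb()]'s `control`.
#' @return An object of class `floa_fit`; see [tidy.floa_fit()],
#'   [glance.floa_fit()], [floa_band()], [residual_acf()].
#' @export
fit_floa_lmm <- function(diffs, fixed_basis, random_basis = fixed_basis,
                         covariance = c("diagonal", "unstructured"),
                         error = error_arma(2, 1),
                         levels = c("subject", "session", "replicate"),
                         n_starts = 2,
                         method = c("auto", "balanced", "dense"),
                         control = list()) {
  covariance <- arg_match(covariance)
  method <- match.arg(method)
  stopifnot(inherits(error, "floa_error"))
  random <- if (length(levels)) {
    random_levels(random_basis, covariance, levels)
  } else {
    list() # pure fixed-effects + correlated-error model
  }
  designs <- build_designs(diffs, fixed_basis, random)
  layout <- theta_layout(designs, error)
  N <- designs$N; p <- designs$p

  objective <- function(theta) {
    up <- tryCatch(unpack_theta(theta, layout, error), error = function(e) NULL)
    if (is.null(up)) return(1e10)
    C <- tryCatch(error_correlation(error, up$coefs, designs$grid$n_frames),
                  error = function(e) NULL)
    if (is.null(C)) return(1e10)
    core <- reml_core(designs, up$Dlist, C, method = method)
    if (is.null(core) || !is.finite(core$Q) || core$Q <= 0) return(1e10)
    profiled_neg2(core, N, p)
  }

  theta0 <- start_values(designs, layout, error)
  scales <- c(0.25, 4, 0.0625, 16)
  starts <- c(
    list(theta0),
    lapply(seq_len(max(0, n_starts - 1)), function(s) {
      perturb_start(theta0, layout, scales[min(s, length(scales))])
    })
  )

  ctrl <- modifyList(list(iter.max = 500, eval.max = 4000), control)
  if (layout$n == 0) {
    # no free variance parameters beyond sigma2: a single evaluation suffices
    runs <- list(list(par = numeric(0), objective = objective(numeric(0)),
                      convergence = 0L, iterations = 0L, message = "direct"))
  } else {
    runs <- lapply(starts, function(th) {
      stats::nlminb(th, objective, control = ctrl)
    })
  }
  best <- runs[[which.min(vapply(runs, `[[`, 0, "objective"))]]

  up <- unpack_theta(best$par, layout, error)
  C <- error_correlation(error, up$coefs, designs$grid$n_frames)
  core <- reml_core(designs, up$Dlist, C, method = method)
  if (is.null(core)) abort("REML evaluation failed at the optimum.")
  sigma2 <- core$Q / (N - p)
  psi <- lapply(up$Dlist, function(D) sigma2 * D)
  pt <- error_phi_theta(error, up$coefs)
  params <- floa_params(psi = psi, sigma2 = sigma2,
                        phi = pt$phi, theta = pt$theta, error = error)
  reml <- -0.5 * profiled_neg2(core, N, p)
  converged <- best$convergence == 0
  if (!converged) {
    warn(paste0("Optimizer did not report convergence: ", best$message))
  }

  fit <- structure(
    list(
      beta = setNames(core$beta, colnames(designs$X)),
      params = params,
      sigma2 = sigma2, psi = psi, phi = pt$phi, theta = pt$theta,
      error = error,
      reml_loglik = reml,
      converged = converged,
      designs = designs,
      fixed_basis = fixed_basis,
      random_basis = random_basis,
      covariance = covariance,
      n_params = count_variance_parameters(
        vapply(layout$levels, `[[`, 0, "q"),
        vapply(layout$levels, function(l) l$type, ""),
        error
      ),
      optim = tibble(
        start = seq_along(runs),
        objective = vapply(runs, `[[`, 0, "objective"),
        convergence = vapply(runs, `[[`, 0L, "convergence"),
        iterations = vapply(runs, `[[`, 0L, "iterations")
      ),
      data = as_diff_tbl(diffs)
    ),
    class = "floa_fit"
  )
  fit$blups <- compute_blups(fit)
  fit
}

#' @export
print.floa_fit <- function(x, ...) {
  q <- vapply(x$designs$random, function(r) ncol(r$basis$matrix), 0)
  cat("<floa_fit> functional limits-of-agreement mixed model (REML)\n")
  cat(sprintf("  fixed basis: %d functions; random basis: %s (%s), q = %s\n",
              length(x$beta),
              x$random_basis$kind, x$covariance,
              paste(q, collapse = "/")))
  cat(sprintf("  error: %s; sigma2 = %.4g; REML logLik = %.3f%s\n",
              error_label(x$error), x$sigma2, x$reml_loglik,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Best linear unbiased predictions of the random effects
#'
#' Standard conditional-mean predictors `Psi_l Z_l' V^-1 (d - X beta)`
#' accumulated over the curves each random effect loads on.  As the level
#' covariance shrinks to zero so do its BLUPs.
#'
#' @param fit A `floa_fit`.
#' @return Named list (per level) with `keys` (group labels) and `coef`
#'   (groups x q matrix).
#' @export
blup <- function(fit) {
  stopifnot(inherits(fit, "floa_fit"))
  fit$blups
}

compute_blups <- function(fit) {
  designs <- fit$designs
  T_ <- designs$grid$n_frames
  X <- designs$X
  out <- lapply(names(designs$random), function(l) {
    q <- ncol(designs$random[[l]]$basis$matrix)
    list(level = l, rows = list(), coef = list())
  })
  names(out) <- names(designs$random)
  res <- list()
  for (b in designs$blocks) {
    m <- ncol(b$Y)
    V <- marginal_covariance(fit$params, designs, b$subject)
    r <- as.vector(b$Y) - rep(X %*% fit$beta, m)
    w <- solve(V, r)
    wmat <- matrix(w, nrow = T_) # columns follow b's curve order
    for (l in names(designs$random)) {
      Z <- designs$random[[l]]$basis$matrix
      Psi <- fit$psi[[l]]
      groups <- switch(l,
        subject = rep(b$subject, m),
        session = b$session,
        replicate = paste(b$session, b$replicate, sep = ".")
      )
      for (g in unique(groups)) {
        cols <- which(groups == g)
        coef_g <- Psi %*% (t(Z) %*% rowSums(wmat[, cols, drop = FALSE]))
        key <- switch(l,
          subject = tibble(subject = b$subject),
          session = tibble(subject = b$subject,
                           session = b$session[cols[1]]),
          replicate = tibble(subject = b$subject,
                             session = b$session[cols[1]],
                             replicate = b$replicate[cols[1]])
        )
        out[[l]]$rows <- c(out[[l]]$rows, list(key))
        out[[l]]$coef <- c(out[[l]]$coef, list(as.numeric(coef_g)))
      }
    }
  }
  lapply(out, function(o) {
    list(keys = bind_rows(o$rows), coef = do.call(rbind, o$coef))
  })
}

# Per-curve fitted values X beta + sum_l Z_l bhat_l; long tibble.
fitted_curves <- function(fit) {
  designs <- fit$designs
  T_ <- designs$grid$n_frames
  bias <- as.numeric(designs$X %*% fit$beta)
  keys <- designs$keys
  fits <- matrix(bias, T_, nrow(keys))
  for (l in names(designs$random)) {
    Z <- designs$random[[l]]$basis$matrix
    bl <- fit$blups[[l]]
    idx <- switch(l,
      subject = match(keys$subject, bl$keys$subject),
      session = match(paste(keys$subject, keys$session),
                      paste(bl$keys$subject, bl$keys$session)),
      replicate = match(
        paste(keys$subject, keys$session, keys$replicate),
        paste(bl$keys$subject, bl$keys$session, bl$keys$replicate)
      )
    )
    fits <- fits + Z %*% t(bl$coef[idx, , drop = FALSE])
  }
  dplyr::bind_cols(
    keys[rep(seq_len(nrow(keys)), each = T_), ],
    tibble(frame = rep(0:(T_ - 1L), nrow(keys)), .fitted = as.vector(fits))
  )
}
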