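test_that("design bookkeeping matches the hierarchical layout", {
  sim <- simulate_differences(sim_config(seed = 41))
  b <- sim$truth$basis
  des <- build_designs(sim$diffs, b, random_levels(b, "diagonal"))
  expect_equal(des$n_subjects, 9)
  expect_equal(des$N, 5454)                      # 9 * 606
  expect_equal(ncol(des$blocks[[1]]$Y) * 101, 606) # 2 * 3 * 101 per subject
  expect_true(des$balanced)
  expect_equal(c(des$J, des$K), c(2L, 3L))

  fit <- fit_quietly(sim$diffs, b, b, covariance = "diagonal",
                     error = error_iid(), n_starts = 1)
  expect_equal(nrow(fit$blups$subject$keys), 9)
  expect_equal(nrow(fit$blups$session$keys), 18)
  expect_equal(nrow(fit$blups$replicate$keys), 54)
})

test_that("degenerate grouping structures are flagged unidentifiable", {
  cfg <- sim_config(n_subjects = 1, n_sessions = 1, n_replicates = 1,
                    n_frames = 21, basis_n_inner = 0, seed = 42)
  sim <- suppressWarnings(simulate_differences(cfg))
  b <- sim$truth$basis
  w <- capture_warnings(build_designs(sim$diffs, b, random_levels(b, "diagonal")))
  expect_true(any(grepl("Subject-level", w)))
  expect_true(any(grepl("Session-level", w)))
  expect_true(any(grepl("Replicate-level", w)))
})

test_that("variance-parameter counts follow the covariance structure", {
  expect_equal(count_variance_parameters(12)$psi, 78L)
  expect_equal(count_variance_parameters(rep(12, 3))$psi, 234L)
  expect_equal(count_variance_parameters(12, "diagonal")$psi, 12L)
  full <- count_variance_parameters(rep(12, 3), "diagonal", error_arma(2, 1))
  expect_equal(full$total, 36L + 1L + 3L)
})

test_that("marginal covariance reduces to closed forms in degenerate cases", {
  sim <- simulate_differences(tiny_cfg(seed = 43))
  b <- sim$truth$basis
  q <- ncol(b$matrix)
  des <- build_designs(sim$diffs, b, random_levels(b, "diagonal"))

  p0 <- floa_params(psi = list(subject = rep(0, q), session = rep(0, q),
                               replicate = rep(0, q)), sigma2 = 2.5)
  expect_equal(marginal_covariance(p0, des), 2.5 * diag(4 * 31))

  p1 <- floa_params(psi = list(subject = rep(1.5, q)), sigma2 = 1)
  V <- marginal_covariance(p1, des)
  G1 <- b$matrix %*% diag(1.5, q) %*% t(b$matrix)
  expect_lt(max(abs(V[1:31, 32:62] - G1)), 1e-12)       # cross-curve block
  expect_lt(max(abs(V[1:31, 1:31] - G1 - diag(31))), 1e-12)
})

test_that("marginal covariance matches a generative Monte-Carlo oracle", {
  cfg <- sim_config(n_subjects = 1, n_sessions = 2, n_replicates = 2,
                    n_frames = 9, basis_n_inner = 0,
                    psi_subject = c(2, 1, 0.5), psi_session = c(1, 0.5, 0.25),
                    psi_replicate = c(0.5, 0.25, 0.1), sigma2 = 0.4,
                    phi = c(0.5, 0.2), theta = 0.3)
  set.seed(44)
  nsim <- 6000
  acc <- matrix(0, 36, 36); mu_acc <- numeric(36)
  sim1 <- suppressWarnings(simulate_differences(cfg, seed = 1))
  for (s in seq_len(nsim)) {
    sim <- suppressWarnings(simulate_differences(cfg, seed = NULL))
    v <- sim$diffs$value
    mu_acc <- mu_acc + v
    acc <- acc + tcrossprod(v)
  }
  emp <- acc / nsim - tcrossprod(mu_acc / nsim)
  des <- suppressWarnings(
    build_designs(sim1$diffs, sim1$truth$basis,
                  random_levels(sim1$truth$basis, "diagonal"))
  )
  V <- marginal_covariance(sim1$truth$params, des)
  # Monte-Carlo error at 6000 draws: a few percent of the leading scale
  expect_lt(max(abs(emp - V)) / max(abs(V)), 0.06)
})

test_that("marginal covariance is PSD across random parameter draws", {
  sim <- simulate_differences(tiny_cfg(seed = 45))
  b <- sim$truth$basis
  q <- ncol(b$matrix)
  des <- build_designs(sim$diffs, b, random_levels(b, "unstructured"))
  set.seed(45)
  for (r in 1:5) {
    L <- matrix(rnorm(q * q), q); psi1 <- tcrossprod(L)
    psi2 <- diag(rexp(q)); psi3 <- diag(rexp(q))
    p <- floa_params(psi = list(subject = psi1, session = psi2, replicate = psi3),
                     sigma2 = rexp(1) + 0.1, phi = c(0.4, 0.1), theta = 0.2)
    V <- marginal_covariance(p, des)
    expect_silent(chol(V + diag(1e-10, nrow(V))))
  }
})

test_that("balanced and dense REML paths agree to near machine precision", {
  sim <- simulate_differences(tiny_cfg(seed = 46))
  b <- sim$truth$basis
  q <- ncol(b$matrix)
  des <- build_designs(sim$diffs, b, random_levels(b, "diagonal"))
  set.seed(46)
  for (r in 1:5) {
    p <- floa_params(
      psi = list(subject = rexp(q), session = rexp(q), replicate = rexp(q)),
      sigma2 = rexp(1) + 0.05, phi = c(0.3, 0.15), theta = 0.25
    )
    lb <- reml_criterion(p, des, method = "balanced")
    ld <- reml_criterion(p, des, method = "dense")
    expect_equal(lb, ld, tolerance = 1e-9)
  }
})

test_that("REML matches the closed-form ANOVA estimators on a balanced toy", {
  # 20 groups x 5 observations, random intercept, iid error
  set.seed(47)
  n_g <- 20; n_per <- 5
  g_eff <- rnorm(n_g, sd = sqrt(3))
  y <- 10 + rep(g_eff, each = n_per) + rnorm(n_g * n_per, sd = sqrt(1.5))
  diffs <- diffs_from_matrix(matrix(y, nrow = n_per))
  cb <- custom_basis(matrix(1, n_per, 1), frame_grid(n_per))
  fit <- fit_quietly(diffs, cb, cb, covariance = "diagonal",
                     error = error_iid(), levels = "subject", n_starts = 2)

  grp <- rep(seq_len(n_g), each = n_per)
  msb <- n_per * var(tapply(y, grp, mean))
  msw <- sum((y - ave(y, grp))^2) / (n_g * (n_per - 1))
  expect_equal(fit$sigma2, msw, tolerance = 1e-6)
  expect_equal(fit$psi$subject[1, 1], (msb - msw) / n_per, tolerance = 1e-6)

  # criterion agrees with nlme's REML log-likelihood at nlme's estimates
  df <- data.frame(y = y, g = factor(grp))
  m <- nlme::lme(y ~ 1, random = ~ 1 | g, data = df, method = "REML")
  p_nlme <- floa_params(
    psi = list(subject = as.numeric(nlme::VarCorr(m)[1, 1])),
    sigma2 = m$sigma^2
  )
  des <- build_designs(diffs, cb, random_levels(cb, "diagonal", "subject"))
  expect_equal(reml_criterion(p_nlme, des), as.numeric(logLik(m)),
               tolerance = 1e-6)
  expect_equal(fit$reml_loglik, as.numeric(logLik(m)), tolerance = 1e-6)
})

test_that("with no random effects the criterion is the closed-form RSS REML", {
  set.seed(48)
  T_ <- 11; n <- 8
  Y <- matrix(rnorm(T_ * n, sd = 2), T_)
  diffs <- diffs_from_matrix(Y)
  g <- frame_grid(T_)
  X <- cbind(1, g$points)
  cb <- custom_basis(X, g)
  des <- build_designs(diffs, cb, random = list())
  N <- T_ * n; p <- 2
  Xs <- X[rep(1:T_, n), ]
  qrX <- qr(Xs)
  rss <- sum(qr.resid(qrX, as.vector(Y))^2)
  s2 <- rss / (N - p)
  # -2 l_R = (N-p) log 2pi + N log s2 + log|X'X| - p log s2 + rss/s2
  ll_closed <- -0.5 * ((N - p) * log(2 * pi) + (N - p) * log(s2) +
                         determinant(crossprod(Xs))$modulus[1] +
                         rss / s2)
  p0 <- floa_params(psi = list(), sigma2 = s2)
  expect_equal(reml_criterion(p0, des), as.numeric(ll_closed), tolerance = 1e-8)
})

test_that("variance estimates are invariant to adding a constant", {
  sim <- simulate_differences(tiny_cfg(seed = 49))
  b <- sim$truth$basis
  # intercept-spanning fixed design
  fb <- custom_basis(cbind(1, b$matrix), b$grid)
  fit1 <- fit_quietly(sim$diffs, fb, b, covariance = "diagonal",
                      error = error_iid(), n_starts = 1)
  shifted <- dplyr::mutate(sim$diffs, value = value + 100)
  fit2 <- fit_quietly(shifted, fb, b, covariance = "diagonal",
                      error = error_iid(), n_starts = 1)
  expect_equal(fit1$sigma2, fit2$sigma2, tolerance = 1e-6)
  expect_equal(diag(fit1$psi$replicate), diag(fit2$psi$replicate),
               tolerance = 1e-4)
  expect_equal(unname(fit2$beta[1] - fit1$beta[1]), 100, tolerance = 1e-6)
})

test_that("profiled beta solves the GLS normal equations at the optimum", {
  sim <- simulate_differences(tiny_cfg(seed = 50))
  b <- sim$truth$basis
  fit <- fit_quietly(sim$diffs, b, b, covariance = "diagonal",
                     error = error_arma(2, 1), n_starts = 1)
  des <- fit$designs
  T_ <- 31
  A <- matrix(0, ncol(des$X), ncol(des$X)); v <- numeric(ncol(des$X))
  for (blk in des$blocks) {
    V <- marginal_covariance(fit$params, des, blk$subject)
    m <- ncol(blk$Y)
    Xs <- des$X[rep(1:T_, m), , drop = FALSE]
    Vi_X <- solve(V, Xs)
    A <- A + crossprod(Xs, Vi_X)
    v <- v + crossprod(Vi_X, as.vector(blk$Y))
  }
  expect_equal(as.numeric(A %*% fit$beta), as.numeric(v), tolerance = 1e-6)
})

test_that("REML fits are deterministic given data and configuration", {
  sim <- simulate_differences(tiny_cfg(seed = 51))
  b <- sim$truth$basis
  f1 <- fit_quietly(sim$diffs, b, b, covariance = "diagonal",
                    error = error_arma(2, 1), n_starts = 2)
  f2 <- fit_quietly(sim$diffs, b, b, covariance = "diagonal",
                    error = error_arma(2, 1), n_starts = 2)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$sigma2, f2$sigma2)
  expect_identical(f1$phi, f2$phi)
})

test_that("likelihood is invariant to orthogonal rotation with rotated covariance", {
  sim <- simulate_differences(tiny_cfg(seed = 52))
  b <- sim$truth$basis
  q <- ncol(b$matrix)
  des1 <- build_designs(sim$diffs, b, random_levels(b, "unstructured"))
  set.seed(52)
  R <- qr.Q(qr(matrix(rnorm(q * q), q)))
  b_rot <- custom_basis(b$matrix %*% R, b$grid, intercept = FALSE)
  des2 <- build_designs(sim$diffs, b, random_levels(b_rot, "unstructured"))
  D <- diag(rexp(q, rate = 0.5), q)
  p1 <- floa_params(psi = list(subject = D, session = D / 2, replicate = D / 4),
                    sigma2 = 0.3, phi = 0.4, theta = numeric(0))
  p2 <- floa_params(psi = list(subject = t(R) %*% D %*% R,
                               session = t(R) %*% D %*% R / 2,
                               replicate = t(R) %*% D %*% R / 4),
                    sigma2 = 0.3, phi = 0.4, theta = numeric(0))
  expect_equal(reml_criterion(p1, des1), reml_criterion(p2, des2),
               tolerance = 1e-8)
})

test_that("BLUPs shrink to zero with the level variance and recover truth without noise", {
  # shrinkage limit: a level with (near) zero variance has (near) zero BLUPs
  cfg0 <- tiny_cfg(seed = 53, psi_session = 0)
  sim0 <- simulate_differences(cfg0)
  b <- sim0$truth$basis
  fit0 <- fit_quietly(sim0$diffs, b, b, covariance = "diagonal",
                      error = error_iid(), n_starts = 1)
  expect_lt(max(abs(fit0$blups$session$coef)),
            0.05 * max(abs(fit0$blups$replicate$coef)))

  # vanishing noise: replicate-level BLUPs approach the generating coefficients
  cfg1 <- sim_config(n_subjects = 6, n_sessions = 1, n_replicates = 3,
                     n_frames = 31, basis_n_inner = 1,
                     psi_subject = 4, psi_session = 0, psi_replicate = 6,
                     sigma2 = 1e-6, seed = 53)
  sim1 <- simulate_differences(cfg1)
  fit1 <- fit_quietly(sim1$diffs, sim1$truth$basis, sim1$truth$basis,
                      covariance = "diagonal", error = error_iid(),
                      levels = c("subject", "replicate"), n_starts = 1)
  # reconstruct per-curve smooth deviations from BLUPs and compare with data
  aug <- augment(fit1)
  expect_lt(sd(aug$.resid), 0.01)

  # balance: subject BLUP curves average out over subjects
  Zc <- sim0$truth$basis$matrix
  subj_curves <- Zc %*% t(fit0$blups$subject$coef)
  expect_lt(max(abs(rowMeans(subj_curves))),
            0.25 * max(abs(subj_curves)))
})

test_that("a zero-variance level shrinks toward the boundary in the fit", {
  # needs the full complement of session draws (9 x 2) for the estimate to
  # reach the boundary; at toy scale the estimate is sampling-noise limited
  cfg <- sim_config(seed = 54, psi_session = 0, sigma2 = 1)
  sim <- simulate_differences(cfg)
  b <- sim$truth$basis
  fit <- fit_quietly(sim$diffs, b, b, covariance = "diagonal",
                     error = error_iid(), n_starts = 1)
  sess_var <- mean(rowSums((b$matrix %*% fit$psi$session) * b$matrix))
  expect_lt(sess_var, 0.05 * fit$sigma2)
})

test_that("parameter recovery at study scale with the truth basis", {
  sim <- simulate_differences(sim_config(seed = 55))
  b <- sim$truth$basis
  fit <- fit_quietly(sim$diffs, b, b, covariance = "diagonal",
                     error = error_arma(2, 1), n_starts = 1)
  expect_lt(abs(fit$sigma2 / 0.015 - 1), 0.15)
  # replicate-level diagonals (54 draws) within 30% in the median
  rel <- abs(diag(fit$psi$replicate) / 24 - 1)
  expect_lt(median(rel), 0.30)
  expect_lt(abs(fit$phi[1] - 0.7), 0.15)
})
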