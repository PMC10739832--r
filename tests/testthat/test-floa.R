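test_that("time normalization preserves endpoints and hits 101 frames", {
  expect_equal(time_normalize(1:101), as.numeric(1:101))      # identity
  ramp <- seq(0, 10, length.out = 57)
  out <- time_normalize(ramp, 101)
  expect_equal(length(out), 101)
  expect_equal(out[c(1, 101)], c(0, 10))
  expect_equal(out, seq(0, 10, length.out = 101))              # linear stays linear
  expect_equal(length(time_normalize(rnorm(250), 101)), 101)
  expect_error(time_normalize(5), "at least 2")

  # data-frame method: every curve lands on the 0..100 grid
  raw <- tibble::tibble(
    method = rep(c("m1", "m2"), each = 37),
    subject = "S01", session = "1", replicate = "1",
    frame = rep(0:36, 2), value = rnorm(74)
  )
  norm <- time_normalize(raw, 101)
  expect_equal(nrow(norm), 202)
  expect_equal(range(norm$frame), c(0, 100))
})

test_that("range of motion subtracts the initial angle", {
  expect_equal(range_of_motion(c(10, 12, 9)), c(0, 2, -1))
  expect_equal(range_of_motion(rep(4.2, 5)), rep(0, 5))
  x <- rnorm(20)
  expect_equal(range_of_motion(range_of_motion(x)), range_of_motion(x))

  d <- tibble::tibble(method = "m1", subject = "S01", session = "1",
                      replicate = "1", frame = 0:4, value = c(3, 4, 5, 4, 3))
  expect_equal(range_of_motion(d)$value, c(0, 1, 2, 1, 0))
})

test_that("sign alignment negates only the ruled method/scenario", {
  sim <- simulate_paired_methods(sim_config(n_subjects = 2, n_frames = 11,
                                            seed = 61))
  curves <- sim$curves
  rules <- tibble::tibble(scenario = "synthetic", method = "m2", multiplier = -1)
  flipped <- align_sign(curves, rules)
  expect_equal(flipped$value[flipped$method == "m2"],
               -curves$value[curves$method == "m2"])
  expect_equal(flipped$value[flipped$method == "m1"],
               curves$value[curves$method == "m1"])
  # involution
  expect_equal(align_sign(flipped, rules)$value, curves$value)
  # identity rule
  rules1 <- dplyr::mutate(rules, multiplier = 1)
  expect_equal(align_sign(curves, rules1)$value, curves$value)
  expect_error(align_sign(curves, dplyr::mutate(rules, scenario = "nope")),
               "Unknown scenario")
})

test_that("difference curves pair correctly and are antisymmetric", {
  sim <- simulate_paired_methods(sim_config(seed = 62))
  d12 <- compute_differences(sim$curves, c("m1", "m2"))
  expect_equal(nrow(dplyr::distinct(d12, subject, session, replicate)), 54)
  d21 <- compute_differences(sim$curves, c("m2", "m1"))
  expect_equal(d12$value, -d21$value)

  same <- dplyr::mutate(sim$curves, value = ifelse(method == "m1",
                                                   value, value))
  same$value[same$method == "m1"] <-
    same$value[same$method == "m2"] # make methods identical
  expect_equal(max(abs(compute_differences(same)$value)), 0)

  # unpaired curves are dropped with a warning
  broken <- dplyr::filter(sim$curves,
                          !(method == "m1" & subject == "S01" &
                              session == "1" & replicate == "1"))
  expect_warning(dd <- compute_differences(broken), "unpaired")
  expect_equal(nrow(dplyr::distinct(dd, subject, session, replicate)), 53)
})

test_that("the band reduces to classical limits of agreement", {
  # iid errors, no random effects, constant fixed design: mean +/- 2 sd
  set.seed(63)
  vals <- rnorm(240, mean = 5, sd = 2)
  diffs <- diffs_from_matrix(matrix(vals, nrow = 2))
  cb <- custom_basis(matrix(1, 2, 1), frame_grid(2))
  fit <- fit_quietly(diffs, cb, levels = NULL, error = error_iid(),
                     n_starts = 1)
  band <- floa_band(fit)
  expect_equal(band$bias, rep(mean(vals), 2), tolerance = 1e-8)
  expect_equal(band$upper - band$bias, rep(2 * sd(vals), 2), tolerance = 1e-6)

  # multiplier 0 collapses the band onto the bias
  b0 <- floa_band(fit, multiplier = 0)
  expect_equal(b0$lower, b0$bias)
  expect_equal(b0$upper, b0$bias)
})

test_that("band variance matches fresh simulation from the fitted parameters", {
  sim <- simulate_differences(sim_config(seed = 64))
  b <- sim$truth$basis
  fit <- fit_quietly(sim$diffs, b, b, covariance = "diagonal",
                     error = error_arma(2, 1), n_starts = 1)
  band <- floa_band(fit)
  # simulate many fresh single curves from the *fitted* parameters
  cfg_fit <- sim_config(
    n_subjects = 3000, n_sessions = 1, n_replicates = 1, n_frames = 101,
    bias = "zero",
    psi_subject = diag(fit$psi$subject), psi_session = diag(fit$psi$session),
    psi_replicate = diag(fit$psi$replicate),
    sigma2 = fit$sigma2, phi = fit$phi, theta = fit$theta,
    basis_n_inner = 3, seed = 640
  )
  fresh <- simulate_differences(cfg_fit)
  emp_var <- apply(matrix(fresh$diffs$value, nrow = 101), 1, var)
  rel <- sqrt(mean((emp_var / band$variance - 1)^2))
  expect_lt(rel, 0.10) # Monte-Carlo error at 3000 draws is ~2.6% per frame
})

test_that("empirical coverage behaves at its extremes and at Gaussian truth", {
  sim <- simulate_differences(sim_config(seed = 65))
  inf_band <- tibble::tibble(frame = 0:100, lower = -Inf, upper = Inf)
  expect_equal(empirical_coverage(inf_band, sim$diffs), 1)
  zero_band <- tibble::tibble(frame = 0:100, lower = 0, upper = 0)
  expect_lt(empirical_coverage(zero_band, sim$diffs), 0.01)

  # band built from the generating truth covers ~95.45% of fresh draws
  tr <- sim$truth
  true_var <- rowSums((tr$basis$matrix %*%
                         (tr$psi$subject + tr$psi$session + tr$psi$replicate)) *
                        tr$basis$matrix) + tr$sigma2
  true_band <- tibble::tibble(
    frame = 0:100,
    lower = tr$mu - 2 * sqrt(true_var),
    upper = tr$mu + 2 * sqrt(true_var)
  )
  big <- simulate_differences(
    sim_config(n_subjects = 2000, n_sessions = 1, n_replicates = 1, seed = 66)
  )
  cov_hat <- empirical_coverage(true_band, big$diffs)
  expect_lt(abs(cov_hat - 0.9545), 0.01)
})

test_that("whitened residual ACF is clean under the correct error model", {
  sim <- simulate_differences(sim_config(seed = 67))
  b <- sim$truth$basis
  fit_ok <- fit_quietly(sim$diffs, b, b, covariance = "diagonal",
                        error = error_arma(2, 1), n_starts = 1)
  a_ok <- residual_acf(fit_ok, max_lag = 20)
  inside <- abs(a_ok$acf[-1]) <= a_ok$upper[-1]
  expect_gte(mean(inside), 0.95)

  fit_iid <- fit_quietly(sim$diffs, b, b, covariance = "diagonal",
                         error = error_iid(), n_starts = 1)
  a_iid <- residual_acf(fit_iid, max_lag = 20)
  expect_gt(abs(a_iid$acf[2]), a_iid$upper[2]) # lag-1 far outside the bounds
})

test_that("residual-vs-average diagnostic flags an omitted bias", {
  sim <- simulate_paired_methods(sim_config(seed = 68))
  diffs <- compute_differences(sim$curves)
  b9 <- bspline_basis(frame_grid(101), 3)
  fit <- fit_quietly(diffs, b9, sim$truth$basis, covariance = "diagonal",
                     error = error_arma(2, 1), n_starts = 1)
  rva <- residual_vs_average(fit, sim$curves)
  expect_true(all(is.finite(rva$average)) && all(is.finite(rva$residual)))
  expect_lt(abs(attr(rva, "slope")), 2 * attr(rva, "slope_se") + 0.01)

  # proportional bias left unmodelled: a rigid (constant-only) model cannot
  # absorb it and the trend slope becomes significant
  prop <- sim$curves
  prop$value[prop$method == "m1"] <- prop$value[prop$method == "m1"] +
    0.3 * prop$value[prop$method == "m2"]
  dprop <- compute_differences(prop)
  cb <- custom_basis(matrix(1, 101, 1), frame_grid(101))
  fit_bad <- fit_quietly(dprop, cb, cb, covariance = "diagonal",
                         error = error_iid(), levels = "subject",
                         n_starts = 1)
  rva_bad <- residual_vs_average(fit_bad, prop)
  expect_gt(abs(attr(rva_bad, "slope")), 2 * attr(rva_bad, "slope_se"))
})

test_that("the full pipeline runs the eigen recipe and reports its choices", {
  sim <- simulate_paired_methods(sim_config(seed = 69))
  res <- floa(sim$curves)
  expect_s3_class(res, "floa_result")
  expect_equal(res$report$n_diff_curves, 54)
  expect_equal(res$report$random_basis, "eigen")
  expect_equal(res$report$error, "ARMA(2,1)")
  expect_true(res$report$fixed_n_inner %in% c(0, 1, 3, 9, 19, 32))
  expect_gt(res$diagnostics$coverage, 0.9)
  expect_s3_class(res$band, "floa_band")
  expect_true(all(res$band$upper >= res$band$bias))
  expect_true(all(res$band$lower <= res$band$bias))

  # parameter-count echo: fixed 9 knots + unstructured q = 12 at 3 levels
  cfg234 <- floa_config(fixed = list(auto = FALSE, n_inner = 9),
                        random = list(basis = "bspline",
                                      covariance = "unstructured"))
  des234 <- count_variance_parameters(rep(12, 3), "unstructured")
  expect_equal(des234$psi, 234L)
})

test_that("near-identical methods give a narrow band around zero bias", {
  sim <- simulate_paired_methods(
    sim_config(psi_subject = 0, psi_session = 0, psi_replicate = 0,
               bias = "zero", sigma2 = 1e-4, seed = 70)
  )
  cfg <- floa_config(fixed = list(auto = FALSE, n_inner = 3),
                     error = list(family = "iid", select = "fixed"))
  res <- floa(sim$curves, cfg)
  expect_lt(max(abs(res$band$bias)), 0.05)
  expect_lt(max(res$band$upper - res$band$lower), 0.2)
})

test_that("eigen and B-spline random-effects paths estimate the same band", {
  cfg <- sim_config(n_subjects = 6, n_sessions = 2, n_replicates = 3,
                    n_frames = 51, basis_n_inner = 1,
                    psi_subject = 4, psi_session = 4, psi_replicate = 9,
                    sigma2 = 0.015, seed = 71)
  sim <- simulate_differences(cfg)
  fb <- bspline_basis(frame_grid(51), 1)
  fit_bs <- fit_quietly(sim$diffs, fb, fb, covariance = "unstructured",
                        error = error_arma(2, 1), n_starts = 1)
  fit_ei <- fit_quietly(sim$diffs, fb, eigen_basis(sim$diffs),
                        covariance = "diagonal",
                        error = error_arma(2, 1), n_starts = 1)
  band_bs <- floa_band(fit_bs)
  band_ei <- floa_band(fit_ei)
  expect_lt(sqrt(mean((band_bs$bias - band_ei$bias)^2)), 0.5)
  expect_lt(median(abs(band_ei$variance / band_bs$variance - 1)), 0.15)
})
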