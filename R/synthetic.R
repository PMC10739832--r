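# Synthetic paired-method curve data -----------------------------------------
#
# The generator draws difference curves from exactly the model the package
# fits: a smooth bias curve, independent Gaussian random smooth deviations
# at the subject, session and replicate levels (coefficients on a stated
# truth B-spline basis with diagonal covariances), and an ARMA error path
# scaled so its marginal variance is sigma2.  The default configuration
# emulates a desk-scale motion-capture agreement study: 9 subjects, 2
# sessions, 3 replicates, 101 frames.

#' Configuration for the synthetic curve generator
#'
#' Defaults mirror the hierarchical motion-capture study design that
#' motivates the package and provide a plateau-shaped bias of 20 degrees
#' over the middle half of the movement (stated as coefficients on the
#' truth basis: the named shape is projected onto it).  Level variances are
#' diagonal on the truth basis - an orthonormalized cubic B-spline system
#' with `basis_n_inner` inner knots, so that equal diagonal values make
#' each level covariance a scalar multiple of the projection onto the
#' spline space and the generating model is invariant to within-span
#' rotations of the basis.  Defaults give pointwise smooth deviation SDs of
#' roughly 0.6 / 0.6 / 1.2 degrees at the subject / session / replicate
#' levels, concentrated in a 6-dimensional smooth space.  The error is an
#' ARMA(2,1) with complex AR roots (spectral peak near a 6-frame period,
#' marginal SD 0.12 degrees): measurement noise contributes under one
#' percent of the total curve variance and is spectrally separated from the
#' smooth deviation space, the regime in which a 99%-variance eigenbasis
#' truncation retains exactly the smooth between-curve variation (as in
#' the motion-capture study) and the error variance remains identified
#' next to it.
#'
#' @param n_subjects,n_sessions,n_replicates,n_frames Design dimensions.
#' @param bias Bias-curve shape: a name understood by [make_bias_shape()]
#'   or a numeric vector of length `n_frames`.
#' @param bias_level,bias_window Level (degrees) and frame window of the
#'   plateau shapes.
#' @param psi_subject,psi_session,psi_replicate Diagonal values (degrees
#'   squared) of the level covariances on the truth basis; scalars are
#'   recycled.
#' @param sigma2 Marginal error variance (degrees squared).
#' @param phi,theta ARMA coefficients of the error (must be stationary /
#'   invertible).
#' @param basis_n_inner Inner knots of the cubic truth basis.
#' @param seed Optional integer seed used by the simulators.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 9, n_sessions = 2, n_replicates = 3,
                       n_frames = 101,
                       bias = "hipabd", bias_level = 20,
                       bias_window = c(25, 75),
                       psi_subject = 6, psi_session = 6,
                       psi_replicate = 24,
                       sigma2 = 0.015, phi = c(0.7, -0.49), theta = 0.2,
                       basis_n_inner = 3, seed = NULL) {
  stopifnot(
    n_subjects >= 1, n_sessions >= 1, n_replicates >= 1, n_frames >= 2,
    sigma2 >= 0, all(psi_subject >= 0), all(psi_session >= 0),
    all(psi_replicate >= 0)
  )
  if (!ar_stationary(phi)) abort("`phi` is not stationary.")
  if (!ma_invertible(theta)) abort("`theta` is not invertible.")
  structure(
    list(
      n_subjects = n_subjects, n_sessions = n_sessions,
      n_replicates = n_replicates, n_frames = n_frames,
      bias = bias, bias_level = bias_level, bias_window = bias_window,
      psi_subject = psi_subject, psi_session = psi_session,
      psi_replicate = psi_replicate,
      sigma2 = sigma2, phi = as.numeric(phi), theta = as.numeric(theta),
      basis_n_inner = basis_n_inner, seed = seed
    ),
    class = "sim_config"
  )
}

#' Named smooth bias-curve shapes
#'
#' `"zero"` is the no-bias reference; `"plateau"` rises smoothly from zero
#' to `level` inside the frame `window` and back (smoothstep shoulders of a
#' fifth of the window width); `"hipabd"` is the plateau with a 20-degree
#' level over frames 25-75, echoing the magnitude of mid-movement bias seen
#' between markerless and marker-based hip-abduction measurements.
#'
#' @param name Shape name.
#' @param grid A [frame_grid()].
#' @param level Plateau level in degrees.
#' @param window Two frame positions delimiting the raised region.
#' @return Numeric vector on the grid.
#' @export
make_bias_shape <- function(name = c("zero", "plateau", "hipabd"),
                            grid = frame_grid(), level = 20,
                            window = c(25, 75)) {
  name <- arg_match(name)
  t <- grid$points
  if (name == "zero") return(rep(0, grid$n_frames))
  if (name == "hipabd") {
    level <- 20
    window <- c(25, 75)
  }
  a <- window[1]; b <- window[2]
  w <- (b - a) / 5
  smoothstep <- function(x) {
    x <- pmin(pmax(x, 0), 1)
    x^3 * (x * (6 * x - 15) + 10)
  }
  level * smoothstep((t - a) / w) * smoothstep((b - t) / w)
}

# Vectorized stationary ARMA paths scaled to a marginal variance: columns
# are independent series.  Innovations are filtered (MA then recursive AR)
# and a burn-in of 500 steps is discarded.
arma_paths <- function(n, m, phi, theta, sigma2, burn = 500) {
  if (sigma2 == 0) return(matrix(0, n, m))
  if (length(phi) == 0 && length(theta) == 0) {
    return(matrix(rnorm(n * m, sd = sqrt(sigma2)), n, m))
  }
  gamma0 <- 1 + sum(ARMAtoMA(ar = phi, ma = theta, lag.max = 2000)^2)
  innov_sd <- sqrt(sigma2 / gamma0)
  e <- matrix(rnorm((n + burn) * m, sd = innov_sd), n + burn, m)
  x <- e
  if (length(theta)) {
    x <- stats::filter(e, c(1, theta), method = "convolution", sides = 1)
    x[seq_along(theta), ] <- e[seq_along(theta), , drop = FALSE]
  }
  if (length(phi)) {
    x <- stats::filter(x, phi, method = "recursive")
  }
  x <- as.matrix(x)
  x[burn + seq_len(n), , drop = FALSE]
}

#' Simulate difference curves from the hierarchical model
#'
#' Draws `d_ijk = mu + Z b_i + Z b_ij + Z b_ijk + eps_ijk` with independent
#' Gaussian coefficient vectors at each level (diagonal covariances on the
#' truth basis) and an ARMA error path scaled so the marginal error variance
#' equals `sigma2`.  The generating truth is returned alongside the data so
#' recovery can be assessed.
#'
#' @param cfg A [sim_config()].
#' @param seed Overrides `cfg$seed` when given.
#' @return List with `diffs` (long tibble) and `truth` (list: `mu`, `basis`,
#'   `psi`, `sigma2`, `phi`, `theta`, `params`, `grid`).
#' @export
simulate_differences <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  grid <- frame_grid(cfg$n_frames)
  basis <- bspline_basis(grid, n_inner = cfg$basis_n_inner, orthonormal = TRUE)
  Z <- basis$matrix
  q <- ncol(Z)
  mu_shape <- if (is.numeric(cfg$bias)) {
    if (length(cfg$bias) != cfg$n_frames) abort("`bias` vector has wrong length.")
    cfg$bias
  } else {
    make_bias_shape(cfg$bias, grid, cfg$bias_level, cfg$bias_window)
  }
  # The generating bias is stated as coefficients on the truth basis: the
  # named shape is projected onto the basis so the true mean lies exactly in
  # the span a correctly sized fixed-effects design can represent.
  beta_truth <- qr.coef(qr(Z), mu_shape)
  beta_truth[is.na(beta_truth)] <- 0
  mu <- as.numeric(Z %*% beta_truth)
  d1 <- rep_len(cfg$psi_subject, q)
  d2 <- rep_len(cfg$psi_session, q)
  d3 <- rep_len(cfg$psi_replicate, q)

  n_i <- cfg$n_subjects; n_j <- cfg$n_sessions; n_k <- cfg$n_replicates
  n_curves <- n_i * n_j * n_k
  subj_of <- rep(seq_len(n_i), each = n_j * n_k)
  sess_of <- rep(rep(seq_len(n_j), each = n_k), times = n_i)

  b1 <- matrix(rnorm(q * n_i), q) * sqrt(d1)             # per subject
  b2 <- matrix(rnorm(q * n_i * n_j), q) * sqrt(d2)       # per subject x session
  b3 <- matrix(rnorm(q * n_curves), q) * sqrt(d3)        # per curve
  eps <- arma_paths(cfg$n_frames, n_curves, cfg$phi, cfg$theta, cfg$sigma2)

  sess_idx <- (subj_of - 1) * n_j + sess_of
  curves <- mu +
    Z %*% (b1[, subj_of, drop = FALSE] + b2[, sess_idx, drop = FALSE] + b3) +
    eps

  keys <- tibble(
    subject = sprintf("S%02d", subj_of),
    session = as.character(sess_of),
    replicate = as.character(rep(rep(seq_len(n_k), n_j), n_i))
  )
  diffs <- dplyr::bind_cols(
    keys[rep(seq_len(n_curves), each = cfg$n_frames), ],
    tibble(
      frame = rep(0:(cfg$n_frames - 1L), n_curves),
      value = as.vector(curves)
    )
  )
  psi <- list(subject = diag(d1, q), session = diag(d2, q),
              replicate = diag(d3, q))
  truth <- list(
    mu = mu, beta = beta_truth, basis = basis, psi = psi,
    sigma2 = cfg$sigma2, phi = cfg$phi, theta = cfg$theta,
    params = if (cfg$sigma2 > 0) {
      floa_params(psi = psi, sigma2 = cfg$sigma2,
                  phi = cfg$phi, theta = cfg$theta)
    },
    grid = grid
  )
  list(diffs = diffs, truth = truth)
}

#' Simulate paired-method curve datasets
#'
#' The second method's curves are a smooth reference process (a named
#' reference mean curve plus subject-level smooth variation and its own
#' ARMA noise); the first method adds the simulated difference process, so
#' `compute_differences()` on the result reproduces the embedded difference
#' process exactly.  At default dimensions this yields 108 curves
#' (2 methods x 9 subjects x 2 sessions x 3 replicates).
#'
#' @param cfg A [sim_config()].
#' @param reference_mean Numeric vector (length `n_frames`) for the
#'   reference method's mean curve; default is a smooth flexion-like arc
#'   rising to 60 degrees mid-movement.
#' @param reference_psi_subject Diagonal value of the reference process's
#'   subject-level covariance on the truth basis.
#' @param reference_sigma2 Marginal variance of the reference method's own
#'   measurement noise.
#' @param methods Labels for (method 1, method 2).
#' @param seed Overrides `cfg$seed` when given.
#' @return List with `curves` (long tibble with `method` and `scenario`
#'   columns) and the difference-process `truth`.
#' @export
simulate_paired_methods <- function(cfg, reference_mean = NULL,
                                    reference_psi_subject = 9,
                                    reference_sigma2 = 0.25,
                                    methods = c("m1", "m2"),
                                    seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_differences(cfg, seed = NULL)
  grid <- sim$truth$grid
  Z <- sim$truth$basis$matrix
  q <- ncol(Z)
  if (is.null(reference_mean)) {
    reference_mean <- 60 * sin(pi * (grid$points - grid$t_min) /
                                 (grid$t_max - grid$t_min))^2
  }
  n_curves <- cfg$n_subjects * cfg$n_sessions * cfg$n_replicates
  subj_of <- rep(seq_len(cfg$n_subjects), each = cfg$n_sessions * cfg$n_replicates)
  bref <- matrix(rnorm(q * cfg$n_subjects), q) *
    sqrt(rep_len(reference_psi_subject, q))
  ref <- reference_mean + Z %*% bref[, subj_of, drop = FALSE] +
    arma_paths(cfg$n_frames, n_curves, cfg$phi, cfg$theta, reference_sigma2)

  d_mat <- matrix(sim$diffs$value, nrow = cfg$n_frames)
  keys <- sim$diffs %>% distinct(.data$subject, .data$session, .data$replicate)
  long_one <- function(mat, label) {
    dplyr::bind_cols(
      keys[rep(seq_len(n_curves), each = cfg$n_frames), ],
      tibble(frame = rep(0:(cfg$n_frames - 1L), n_curves),
             value = as.vector(mat))
    ) %>%
      mutate(method = label, scenario = "synthetic", .before = 1)
  }
  curves <- bind_rows(
    long_one(ref + d_mat, methods[1]),
    long_one(ref, methods[2])
  )
  list(curves = curves, truth = sim$truth)
}
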