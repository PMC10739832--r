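# Shared test fixtures, all generated in code.

# Small balanced difference-curve table from explicit curve vectors.
diffs_from_matrix <- function(Y, n_sessions = 1, n_replicates = 1) {
  T_ <- nrow(Y)
  n_curves <- ncol(Y)
  n_subjects <- n_curves / (n_sessions * n_replicates)
  stopifnot(n_subjects == round(n_subjects))
  keys <- expand.grid(
    replicate = as.character(seq_len(n_replicates)),
    session = as.character(seq_len(n_sessions)),
    subject = sprintf("S%02d", seq_len(n_subjects)),
    stringsAsFactors = FALSE
  )[, 3:1]
  tibble::tibble(
    subject = rep(keys$subject, each = T_),
    session = rep(keys$session, each = T_),
    replicate = rep(keys$replicate, each = T_),
    frame = rep(0:(T_ - 1L), n_curves),
    value = as.vector(Y)
  )
}

# Desk-scale simulation config for quick model fits; ... overrides defaults.
tiny_cfg <- function(seed = 1, ...) {
  defaults <- list(
    n_subjects = 4, n_sessions = 2, n_replicates = 2, n_frames = 31,
    basis_n_inner = 1, psi_subject = 4, psi_session = 3, psi_replicate = 6,
    sigma2 = 0.05, seed = seed
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

fit_quietly <- function(...) suppressWarnings(fit_floa_lmm(...))
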