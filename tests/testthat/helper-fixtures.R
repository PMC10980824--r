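# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data.

# Small two-state configuration with well-separated spatial patterns.
two_state_cfg <- function(n_subjects = 1L, n_sessions = 1L, T_ = 2000L,
                          n_nodes = 6L, stay = 0.9, scale = 3, seed = 42L) {
  A <- matrix(1 - stay, 2, 2); diag(A) <- stay
  M <- rbind(c(rep(scale, n_nodes %/% 2), rep(0, n_nodes - n_nodes %/% 2)),
             c(rep(0, n_nodes %/% 2), rep(scale, n_nodes - n_nodes %/% 2)))
  sim_config(n_subjects = n_subjects, n_sessions = n_sessions,
             n_nodes = n_nodes, n_states = 2L, samples_per_session = T_,
             fs = 40, transition_matrix = A, initial_probs = c(0.5, 0.5),
             state_patterns = M, noise_sd = 1, seed = seed)
}

# Exhaustive maximum-probability path: the brute-force Viterbi oracle.
brute_force_viterbi <- function(logB, logpi, logA) {
  Tn <- nrow(logB); K <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))[, Tn:1, drop = FALSE]
  lp <- apply(paths, 1, function(p) {
    s <- logpi[p[1]] + logB[1, p[1]]
    if (Tn > 1) for (t in 2:Tn) s <- s + logA[p[t - 1], p[t]] + logB[t, p[t]]
    s
  })
  paths[which.max(lp), ]
}

# Random valid HMM parameters for decoding tests.
random_hmm_pars <- function(K, Tn, d = 2L) {
  A <- matrix(stats::rexp(K * K), K, K); A <- A / rowSums(A)
  pi0 <- stats::rexp(K); pi0 <- pi0 / sum(pi0)
  logB <- matrix(stats::rnorm(Tn * K), Tn, K)
  list(A = A, pi = pi0, logB = logB)
}

# Wrap hand-set parameters into an env_hmm object for decoding.
manual_hmm <- function(pi0, A, means, covs) {
  structure(list(K = length(pi0), d = ncol(means), pi = pi0, A = A,
                 means = means, covariances = covs, cov_type = "full",
                 boundaries = NULL, n_samples = NA_integer_,
                 n_restarts = 1L, restart_index = 1L, loglik = NA_real_,
                 score = NA_real_, n_iter = 0L, converged = TRUE),
            class = "env_hmm")
}

# Long-format null table for the mixed ANOVA design (2 groups, 3 sessions,
# 2 induction levels), i.i.d. Gaussian values.
null_design_table <- function(n_per_group = 15, sd = 1, session_shift = 0) {
  grid <- expand.grid(session = c("T1", "T2", "T3"),
                      induction = c("pre", "post"),
                      subject = sprintf("s%02d", seq_len(2 * n_per_group)))
  grid$group <- ifelse(as.integer(sub("s", "", grid$subject)) <= n_per_group,
                       "Wake", "Nap")
  shift <- session_shift * (grid$session == "T2")
  grid$value <- stats::rnorm(nrow(grid), sd = sd) + shift
  grid
}
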