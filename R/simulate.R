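#' Configuration of the Markov-switching envelope generator
#'
#' Bundles every parameter of the synthetic resting-state envelope generator:
#' a hidden Markov chain over `n_states` recurring network states, a spatial
#' mean-power pattern per state, additive Gaussian node noise, and an optional
#' instantaneous linear mixing matrix emulating source-space spatial leakage.
#' Defaults mirror a typical multi-session resting-state design: 30 subjects,
#' 7 sessions, a 126-node connectome, 8 transient states whose mean dwell time
#' at 40 Hz is in the 100-200 ms range, and 5-minute sessions (12000 samples
#' at 40 Hz).
#'
#' @param n_subjects,n_sessions,n_nodes,n_states,samples_per_session counts.
#' @param fs sampling rate of the generated envelopes, Hz.
#' @param transition_matrix `n_states x n_states` row-stochastic matrix; the
#'   default is a sticky chain with self-transition probability `1 - 1/6`
#'   (expected dwell 6 samples = 150 ms at 40 Hz) and uniform off-diagonal mass.
#' @param initial_probs length-`n_states` simplex vector (default uniform).
#' @param state_patterns `n_states x n_nodes` matrix of per-state mean power
#'   offsets added to the baseline when the state is active. The default
#'   assigns each state a distinct contiguous block of nodes raised by
#'   `pattern_scale`.
#' @param pattern_scale amplitude of the default block patterns (ignored when
#'   `state_patterns` is supplied).
#' @param baseline scalar baseline envelope level.
#' @param noise_sd per-node Gaussian noise SD (scalar, > 0).
#' @param noise_cov optional `n_nodes x n_nodes` noise covariance; overrides
#'   `noise_sd` and is the hook for slow inter-node amplitude coupling.
#' @param mixing optional `n_nodes x n_nodes` linear mixing matrix applied to
#'   each time sample (leakage emulation); `NULL` means identity.
#' @param seed integer master seed; all per-recording random streams are
#'   derived from it (see [stream_seed()]).
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_subjects = 30L, n_sessions = 7L, n_nodes = 126L,
                       n_states = 8L, samples_per_session = 12000L, fs = 40,
                       transition_matrix = NULL, initial_probs = NULL,
                       state_patterns = NULL, pattern_scale = 1,
                       baseline = 0, noise_sd = 1, noise_cov = NULL,
                       mixing = NULL, seed = 1L) {
  K <- as.integer(n_states)
  if (is.null(transition_matrix)) {
    stay <- 1 - 1 / 6
    transition_matrix <- matrix(if (K > 1) (1 - stay) / (K - 1) else 0, K, K)
    diag(transition_matrix) <- if (K > 1) stay else 1
  }
  if (is.null(initial_probs)) initial_probs <- rep(1 / K, K)
  if (is.null(state_patterns)) {
    state_patterns <- matrix(0, K, n_nodes)
    block <- split(seq_len(n_nodes), cut(seq_len(n_nodes), K, labels = FALSE))
    for (k in seq_len(K)) state_patterns[k, block[[min(k, length(block))]]] <- pattern_scale
  }
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects), n_sessions = as.integer(n_sessions),
    n_nodes = as.integer(n_nodes), n_states = K,
    samples_per_session = as.integer(samples_per_session), fs = fs,
    transition_matrix = transition_matrix, initial_probs = initial_probs,
    state_patterns = state_patterns, baseline = baseline,
    noise_sd = noise_sd, noise_cov = noise_cov, mixing = mixing,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param cfg a `"sim_config"` object.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  K <- cfg$n_states
  A <- cfg$transition_matrix
  if (!is.matrix(A) || any(dim(A) != K))
    stop("transition_matrix must be ", K, "x", K, call. = FALSE)
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-12))
    stop("transition_matrix rows must be non-negative and sum to 1", call. = FALSE)
  p <- cfg$initial_probs
  if (length(p) != K || any(p < 0) || abs(sum(p) - 1) > 1e-12)
    stop("initial_probs must be a length-", K, " probability vector", call. = FALSE)
  if (!is.matrix(cfg$state_patterns) ||
      nrow(cfg$state_patterns) != K || ncol(cfg$state_patterns) != cfg$n_nodes)
    stop("state_patterns must be n_states x n_nodes", call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (cfg$samples_per_session < 2) stop("samples_per_session must be >= 2", call. = FALSE)
  if (K < 1) stop("n_states must be >= 1", call. = FALSE)
  if (!is.null(cfg$mixing) &&
      (!is.matrix(cfg$mixing) || any(dim(cfg$mixing) != cfg$n_nodes)))
    stop("mixing must be n_nodes x n_nodes", call. = FALSE)
  if (!is.null(cfg$noise_cov) &&
      (!is.matrix(cfg$noise_cov) || any(dim(cfg$noise_cov) != cfg$n_nodes)))
    stop("noise_cov must be n_nodes x n_nodes", call. = FALSE)
  if (is.na(cfg$seed)) stop("a seed is required", call. = FALSE)
  invisible(cfg)
}

#' Deterministic per-stream seed derivation
#'
#' Every independent random stream (one per subject x session recording, plus
#' named auxiliary streams) gets its own seed derived from the master seed by
#' a fixed counter scheme, so any single recording can be regenerated in
#' isolation and full runs are bit-reproducible.
#'
#' @param seed integer master seed.
#' @param counter non-negative integer stream counter.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stream_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 1000003 + as.double(counter)) %% 2147483647)
}

#' Simulate hidden state paths from the Markov chain
#'
#' Draws one state sequence per subject and session from the chain
#' `(initial_probs, transition_matrix)`. Stream seeds are derived from
#' `cfg$seed` with counter `(subject - 1) * n_sessions + session`.
#'
#' @param cfg a [sim_config()].
#' @return A list (subjects) of lists (sessions) of integer vectors in
#'   `1..n_states`, each of length `samples_per_session`.
#' @export
simulate_state_paths <- function(cfg) {
  validate_sim_config(cfg)
  K <- cfg$n_states
  Tn <- cfg$samples_per_session
  cumA <- t(apply(cfg$transition_matrix, 1, cumsum))
  cum0 <- cumsum(cfg$initial_probs)
  lapply(seq_len(cfg$n_subjects), function(s) {
    lapply(seq_len(cfg$n_sessions), function(j) {
      set.seed(stream_seed(cfg$seed, (s - 1) * cfg$n_sessions + j))
      u <- stats::runif(Tn)
      path <- integer(Tn)
      path[1] <- findInterval(u[1], cum0) + 1L
      if (Tn > 1) for (t in 2:Tn)
        path[t] <- findInterval(u[t], cumA[path[t - 1], ]) + 1L
      path
    })
  })
}

#' Simulate envelope data given state paths
#'
#' Node `n` at sample `t` takes value
#' `baseline + state_patterns[path[t], n] + noise`, with Gaussian noise of SD
#' `noise_sd` (or covariance `noise_cov`), optionally followed by linear
#' mixing across nodes. Envelopes are not constrained positive: they are
#' demeaned and rescaled downstream anyway.
#'
#' @param paths output of [simulate_state_paths()].
#' @param cfg the same [sim_config()].
#' @return An `"envelope_dataset"`: list with `subjects`, `sessions`, `fs`,
#'   `band`, and `data[[subject]][[session]]`, each a `n_nodes x T` matrix.
#' @export
simulate_envelopes <- function(paths, cfg) {
  validate_sim_config(cfg)
  if (length(paths) != cfg$n_subjects ||
      any(vapply(paths, length, 1L) != cfg$n_sessions))
    stop("paths do not match cfg (subjects x sessions)", call. = FALSE)
  Rchol <- if (!is.null(cfg$noise_cov)) chol(cfg$noise_cov) else NULL
  n_off <- cfg$n_subjects * cfg$n_sessions  # noise streams follow path streams
  data <- lapply(seq_len(cfg$n_subjects), function(s) {
    lapply(seq_len(cfg$n_sessions), function(j) {
      path <- paths[[s]][[j]]
      if (length(path) != cfg$samples_per_session)
        stop("path length does not match cfg$samples_per_session", call. = FALSE)
      set.seed(stream_seed(cfg$seed, n_off + (s - 1) * cfg$n_sessions + j))
      Tn <- length(path)
      E <- matrix(stats::rnorm(Tn * cfg$n_nodes), Tn, cfg$n_nodes)
      E <- if (is.null(Rchol)) E * cfg$noise_sd else E %*% Rchol
      E <- E + cfg$baseline + cfg$state_patterns[path, , drop = FALSE]
      if (!is.null(cfg$mixing)) E <- E %*% t(cfg$mixing)
      t(E)  # nodes x time
    })
  })
  structure(list(
    subjects = sprintf("S%02d", seq_len(cfg$n_subjects)),
    sessions = sprintf("RS%d", seq_len(cfg$n_sessions)),
    fs = cfg$fs, band = c(4, 30), data = data
  ), class = "envelope_dataset")
}

#' Simulate a full envelope dataset with ground truth
#'
#' Convenience wrapper: draws state paths, generates envelopes, and computes
#' ground-truth temporal parameters (fractional occupancy, number of
#' occurrences, mean lifetime, mean interval length) directly from the paths
#' by transition counting -- an implementation independent of
#' [temporal_params()], usable as a cross-module oracle.
#'
#' @param cfg a [sim_config()].
#' @return List with `dataset`, `paths`, and `truth` (a long data.frame of
#'   per subject/session/state temporal parameters).
#' @export
simulate_envelope_dataset <- function(cfg) {
  paths <- simulate_state_paths(cfg)
  dataset <- simulate_envelopes(paths, cfg)
  rows <- list()
  for (s in seq_along(paths)) for (j in seq_along(paths[[s]])) {
    tp <- path_truth_params(paths[[s]][[j]], cfg$n_states, cfg$fs)
    tp$subject <- dataset$subjects[s]
    tp$session <- dataset$sessions[j]
    rows[[length(rows) + 1L]] <- tp
  }
  list(dataset = dataset, paths = paths, truth = do.call(rbind, rows))
}

# Ground-truth temporal parameters by transition counting (deliberately not
# the rle-based route used by temporal_params()).
path_truth_params <- function(path, K, fs) {
  Tn <- length(path)
  out <- data.frame(state = seq_len(K), NO = 0L, FO = 0,
                    MLT_s = NA_real_, MIL_s = NA_real_)
  for (k in seq_len(K)) {
    act <- path == k
    entries <- sum(diff(act) == 1) + act[1]
    total <- sum(act)
    out$NO[k] <- entries
    out$FO[k] <- total / Tn
    if (entries > 0) out$MLT_s[k] <- total / entries / fs
    starts <- which(diff(act) == 1) + 1L
    ends <- which(diff(act) == -1)
    if (entries >= 2) {
      s2 <- if (act[1]) c(1L, starts) else starts
      e2 <- if (act[Tn]) c(ends, Tn) else ends
      gaps <- s2[-1] - e2[-length(e2)] - 1L
      out$MIL_s[k] <- mean(gaps) / fs
    }
  }
  out
}

#' Plant a connectivity effect on connectome matrices
#'
#' Increases the listed edges by `delta` in the matrices of flagged subjects
#' (or sessions), re-symmetrizes, and clips to `[-1, 1]`. Used to create a
#' known suprathreshold network component for permutation-statistics power
#' and FWER checks.
#'
#' @param base_matrices list of symmetric matrices (one per subject).
#' @param edges two-column integer matrix of node pairs.
#' @param delta effect size in correlation units.
#' @param mask logical vector, one per matrix; `TRUE` entries receive the
#'   effect. Default: all.
#' @return List of modified matrices.
#' @export
plant_connectome_effect <- function(base_matrices, edges, delta,
                                    mask = rep(TRUE, length(base_matrices))) {
  edges <- as.matrix(edges)
  stopifnot(ncol(edges) == 2, length(mask) == length(base_matrices))
  lapply(seq_along(base_matrices), function(i) {
    M <- base_matrices[[i]]
    if (max(edges) > nrow(M) || min(edges) < 1)
      stop("edge index out of range", call. = FALSE)
    if (!mask[i] || delta == 0) return(M)
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      v <- min(1, max(-1, M[a, b] + delta))
      M[a, b] <- v; M[b, a] <- v
    }
    M
  })
}

#' Simulate null connectome matrices
#'
#' One symmetric null matrix per subject. `type = "correlation"` computes a
#' proper correlation matrix from `n_time` i.i.d. Gaussian samples over
#' `n_nodes` channels (edge values carry genuine sampling noise);
#' `type = "gaussian"` draws i.i.d. Gaussian edge values with SD
#' `1 / sqrt(n_time)` (matching the correlation sampling scale), an
#' exchangeable null that is much cheaper at large node counts.
#'
#' @param n_subjects,n_nodes,n_time counts.
#' @param seed integer seed.
#' @param type `"correlation"` (default) or `"gaussian"`.
#' @return List of `n_nodes x n_nodes` symmetric matrices (unit diagonal).
#' @export
simulate_connectomes <- function(n_subjects, n_nodes, n_time = 100, seed = 1L,
                                 type = c("correlation", "gaussian")) {
  type <- match.arg(type)
  lapply(seq_len(n_subjects), function(i) {
    set.seed(stream_seed(seed, i))
    if (type == "correlation") {
      stats::cor(matrix(stats::rnorm(n_time * n_nodes), n_time, n_nodes))
    } else {
      M <- matrix(0, n_nodes, n_nodes)
      v <- stats::rnorm(n_nodes * (n_nodes - 1) / 2, sd = 1 / sqrt(n_time))
      M[lower.tri(M)] <- v
      M <- M + t(M)
      diag(M) <- 1
      M
    }
  })
}

#' Simulate finger-tapping keypress streams
#'
#' Emulates a sequential finger-tapping task: within each 30-s block the
#' subject cyclically reproduces the fixed 5-element sequence 4-1-3-2-4 (keys
#' 1 = index .. 4 = little finger). Inter-press intervals are exponential with
#' per-block mean `1 / rate`; each press is independently corrupted with
#' probability `error_rate` (replaced by a uniformly drawn different key).
#' With `learning_curve = TRUE` the press rate rises exponentially across the
#' learning blocks, emulating within-session improvement.
#'
#' @param n_blocks number of blocks (default 26: 20 learning + 3 x 2 test).
#' @param mean_rate asymptotic press rate, presses per second.
#' @param error_rate probability a press is corrupted, in `[0, 1)`.
#' @param seed integer seed.
#' @param block_duration block length in seconds.
#' @param learning_curve logical; scale rate by `1 - 0.3 exp(-(b-1)/5)`.
#' @return A data.frame with columns `block`, `t_ms`, `key` and attribute
#'   `n_correct_true` (per-block count of uncorrupted presses).
#' @export
simulate_ftt_blocks <- function(n_blocks = 26L, mean_rate = 3, error_rate = 0.05,
                                seed = 1L, block_duration = 30,
                                learning_curve = TRUE) {
  stopifnot(mean_rate > 0, error_rate >= 0, error_rate < 1)
  seq5 <- c(4L, 1L, 3L, 2L, 4L)
  out <- vector("list", n_blocks)
  n_true <- integer(n_blocks)
  for (b in seq_len(n_blocks)) {
    set.seed(stream_seed(seed, b))
    rate <- if (learning_curve) mean_rate * (1 - 0.3 * exp(-(b - 1) / 5)) else mean_rate
    # oversample gaps, then truncate to the block duration
    gaps <- stats::rexp(ceiling(rate * block_duration * 3) + 20, rate = rate)
    tt <- cumsum(gaps)
    tt <- tt[tt < block_duration]
    n <- length(tt)
    keys <- seq5[(seq_len(n) - 1L) %% 5L + 1L]
    err <- stats::runif(n) < error_rate
    if (any(err)) {
      wrong <- vapply(keys[err], function(k) sample(setdiff(1:4, k), 1L), 1L)
      keys[err] <- wrong
    }
    n_true[b] <- sum(!err)
    out[[b]] <- data.frame(block = b, t_ms = round(tt * 1000, 3), key = keys)
  }
  res <- do.call(rbind, out)
  attr(res, "n_correct_true") <- n_true
  res
}
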