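#' Fit a Gaussian-observation hidden Markov model to envelope data
#'
#' The core model of the package: a K-state HMM with (full- or diagonal-
#' covariance) Gaussian emissions, fitted by expectation-maximisation
#' (Baum-Welch) on the standardized, concatenated, PCA-reduced envelope
#' matrix. The EM is restarted `n_restarts` times from different random
#' initialisations and the restart with the best model-selection score
#' (negative log-likelihood; lower is better) is retained. Recordings listed
#' in `boundaries` are treated as independent segments: the chain restarts at
#' the initial distribution at every recording onset.
#'
#' @param X samples-by-dimensions numeric matrix (typically the 40
#'   unit-variance principal components), or a `"concatenated_envelope"`
#'   passed through [prewhiten_pca()] beforehand.
#' @param K number of states (default 8).
#' @param n_restarts number of EM restarts (default 10).
#' @param seed integer; restart `r` uses the derived seed
#'   `stream_seed(seed, r)`, so fits are bit-reproducible.
#' @param boundaries optional data.frame with 0-based half-open `start`/`end`
#'   rows delimiting independent recordings; default: one segment.
#' @param tol EM convergence tolerance on the relative log-likelihood change
#'   (default 1e-6).
#' @param max_iter EM iteration cap per restart (default 500).
#' @param cov_type `"full"` (default) or `"diagonal"` emission covariances.
#' @param verbose print per-restart progress.
#'
#' @return An object of class `"env_hmm"`: list with `K`, `pi`, `A`, `means`
#'   (K x d), `covariances` (list of K matrices), `loglik`, `score`
#'   (= -loglik), `restart_index`, `n_iter`, `converged`, `boundaries`.
#' @seealso [viterbi_decode()], [model_score()], [temporal_params()]
#' @export
env_hmm <- function(X, K = 8L, n_restarts = 10L, seed = 1L, boundaries = NULL,
                    tol = 1e-6, max_iter = 500L, cov_type = c("full", "diagonal"),
                    verbose = FALSE) {
  cov_type <- match.arg(cov_type)
  X <- as.matrix(X)
  stopifnot(all(is.finite(X)), K >= 1, n_restarts >= 1)
  segs <- .segments(boundaries, nrow(X))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- tryCatch(
      .em_once(X, K, segs, stream_seed(seed, r), tol, max_iter, cov_type),
      error = function(e) {
        warning("restart ", r, " failed: ", conditionMessage(e))
        NULL
      })
    if (verbose && !is.null(fit))
      message(sprintf("restart %d: loglik %.3f (%d iterations)", r, fit$loglik, fit$n_iter))
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
      fit$restart_index <- r
      best <- fit
    }
  }
  if (is.null(best)) stop("all EM restarts failed", call. = FALSE)
  best$score <- -best$loglik
  best$K <- K
  best$d <- ncol(X)
  best$cov_type <- cov_type
  best$n_restarts <- n_restarts
  best$seed <- seed
  best$boundaries <- boundaries
  best$n_samples <- nrow(X)
  best$call <- match.call()
  class(best) <- "env_hmm"
  best
}

# boundaries data.frame (0-based half-open) -> 1-based inclusive segment matrix
.segments <- function(boundaries, n) {
  if (is.null(boundaries)) return(matrix(c(1L, n), 1))
  segs <- cbind(as.integer(boundaries$start) + 1L, as.integer(boundaries$end))
  if (segs[1, 1] != 1L || segs[nrow(segs), 2] != n ||
      (nrow(segs) > 1 && any(segs[-1, 1] != segs[-nrow(segs), 2] + 1L)))
    stop("boundaries must partition the sample axis", call. = FALSE)
  storage.mode(segs) <- "integer"
  segs
}

# One EM run from a random initialisation: a short seeded k-means from
# random centers supplies the initial means (a few Lloyd iterations on a
# subsample), which avoids most merged-state local optima while keeping the
# restarts random and reproducible.
.em_once <- function(X, K, segs, seed, tol, max_iter, cov_type) {
  Tn <- nrow(X); d <- ncol(X)
  set.seed(seed)
  mu <- X[sample.int(Tn, K), , drop = FALSE]
  if (K > 1) {
    sub <- if (Tn > 20000) X[sample.int(Tn, 20000), , drop = FALSE] else X
    km <- tryCatch(suppressWarnings(
      stats::kmeans(sub, centers = mu, iter.max = 10)), error = function(e) NULL)
    if (!is.null(km)) mu <- km$centers
  }
  S0 <- stats::cov(X) + diag(1e-6, d)
  covs <- replicate(K, S0, simplify = FALSE)
  A <- matrix(0.1 / max(K - 1, 1), K, K); diag(A) <- if (K > 1) 0.9 else 1
  pi0 <- rep(1 / K, K)
  ll_prev <- -Inf; ll <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    logB <- .gauss_logdens(X, mu, covs, cov_type)
    e <- .fb_cpp(logB, pi0, A, segs)
    ll <- e$loglik
    g <- e$gamma
    w <- colSums(g)
    mu <- crossprod(g, X) / w
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2, mu[k, ])
      Sk <- crossprod(Xc * g[, k], Xc) / w[k]
      if (cov_type == "diagonal") Sk <- diag(diag(Sk), d)
      # diagonal loading against degeneracy
      if (inherits(tryCatch(chol(Sk), error = identity), "error") ||
          min(diag(Sk)) < 1e-10) {
        warning("degenerate covariance regularized by diagonal loading")
        Sk <- Sk + diag(1e-6 * mean(diag(Sk)) + 1e-10, d)
      }
      covs[[k]] <- Sk
    }
    if (K > 1) {
      A <- e$xi / pmax(rowSums(e$xi), .Machine$double.xmin)
      pi0 <- colMeans(g[segs[, 1], , drop = FALSE])
      pi0 <- pi0 / sum(pi0)
    }
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  list(pi = pi0, A = A, means = mu, covariances = covs,
       loglik = ll, n_iter = it, converged = converged)
}

# T x K Gaussian log-densities, vectorized per state through Cholesky solves.
.gauss_logdens <- function(X, means, covs, cov_type = "full") {
  Tn <- nrow(X); d <- ncol(X); K <- nrow(means)
  out <- matrix(0, Tn, K)
  for (k in seq_len(K)) {
    R <- chol(covs[[k]])
    Xc <- sweep(X, 2, means[k, ])
    Y <- Xc %*% backsolve(R, diag(d))
    out[, k] <- -0.5 * (d * log(2 * pi) + rowSums(Y * Y)) - sum(log(diag(R)))
  }
  out
}

#' Viterbi decoding of the state sequence
#'
#' Maximum-probability state path under a fitted model: a temporally
#' exclusive state-activation record (exactly one active state per sample).
#' Ties are broken toward the lower state index. Each recording in
#' `boundaries` is decoded independently.
#'
#' @param model a fitted [env_hmm()].
#' @param X the observation matrix the model was fitted on (or compatible
#'   new data in the same component space).
#' @param boundaries optional boundary table (defaults to the one stored in
#'   the model).
#' @return A `"state_sequence"`: list with integer `path` (values `1..K`)
#'   and `boundaries`.
#' @export
viterbi_decode <- function(model, X, boundaries = NULL) {
  stopifnot(inherits(model, "env_hmm"))
  X <- as.matrix(X)
  if (ncol(X) != model$d) stop("dimension mismatch with model", call. = FALSE)
  if (is.null(boundaries)) boundaries <- model$boundaries
  segs <- .segments(boundaries, nrow(X))
  logB <- .gauss_logdens(X, model$means, model$covariances, model$cov_type)
  path <- .viterbi_cpp(logB, log(pmax(model$pi, .Machine$double.xmin)),
                       log(pmax(model$A, .Machine$double.xmin)), segs)
  structure(list(path = path, K = model$K, boundaries = boundaries),
            class = "state_sequence")
}

#' Model-selection score of a fitted HMM on data
#'
#' The criterion used to pick among restarts: the negative log-likelihood of
#' the data under the model (lower is better), deterministic given model and
#' data, invariant to state relabelling, and additive over independent
#' segments.
#'
#' @inheritParams viterbi_decode
#' @return Scalar score.
#' @export
model_score <- function(model, X, boundaries = NULL) {
  stopifnot(inherits(model, "env_hmm"))
  X <- as.matrix(X)
  if (ncol(X) != model$d) stop("dimension mismatch with model", call. = FALSE)
  if (is.null(boundaries)) boundaries <- model$boundaries
  segs <- .segments(boundaries, nrow(X))
  logB <- .gauss_logdens(X, model$means, model$covariances, model$cov_type)
  -.fb_cpp(logB, model$pi, model$A, segs)$loglik
}

#' Match states between two labelings
#'
#' State labels of an HMM are arbitrary; cross-run comparisons must first
#' align states. Finds the permutation of `B`'s rows maximizing the summed
#' absolute cosine similarity with `A`'s rows (exact assignment by
#' enumeration, K <= 9).
#'
#' @param A,B K-by-p matrices of state patterns (means or power maps).
#' @param method `"cosine"` (default; maximal absolute cosine similarity,
#'   sign- and scale-blind, suited to power maps) or `"euclidean"` (minimal
#'   summed distance, suited to signed state means).
#' @return Integer permutation `perm` such that `B[perm[k], ]` matches
#'   `A[k, ]`.
#' @export
match_states <- function(A, B, method = c("cosine", "euclidean")) {
  method <- match.arg(method)
  stopifnot(nrow(A) == nrow(B), ncol(A) == ncol(B))
  K <- nrow(A)
  if (K > 9) stop("exact enumeration supports K <= 9", call. = FALSE)
  if (method == "cosine") {
    nA <- sqrt(rowSums(A^2)); nB <- sqrt(rowSums(B^2))
    C <- abs(A %*% t(B)) / (pmax(nA, 1e-300) %o% pmax(nB, 1e-300))
  } else {
    C <- -outer(seq_len(K), seq_len(K),
                Vectorize(function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))))
  }
  perms <- .permutations(K)
  sc <- apply(perms, 1, function(p) sum(C[cbind(seq_len(K), p)]))
  perms[which.max(sc), ]
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' @export
print.env_hmm <- function(x, ...) {
  cat(sprintf("Gaussian-observation envelope HMM (K = %d states, %d dims)\n",
              x$K, x$d))
  cat(sprintf("  fitted on %d samples (%d segments); %s after %d EM iterations\n",
              x$n_samples, nrow(.segments(x$boundaries, x$n_samples)),
              if (x$converged) "converged" else "iteration cap reached", x$n_iter))
  cat(sprintf("  best of %d restarts (restart %d); score (-logLik) = %.2f\n",
              x$n_restarts, x$restart_index, x$score))
  invisible(x)
}

#' @export
summary.env_hmm <- function(object, ...) {
  dwell <- 1 / pmax(1 - diag(object$A), .Machine$double.eps)
  out <- list(model = object,
              table = data.frame(state = seq_len(object$K),
                                 self_transition = diag(object$A),
                                 expected_dwell_samples = dwell,
                                 mean_norm = sqrt(rowSums(object$means^2))))
  class(out) <- "summary.env_hmm"
  out
}

#' @export
print.summary.env_hmm <- function(x, ...) {
  print(x$model)
  cat("\nPer-state parameters:\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.env_hmm <- function(object, ...) {
  list(pi = object$pi, A = object$A, means = object$means,
       covariances = object$covariances)
}

#' @export
logLik.env_hmm <- function(object, ...) {
  p <- object$K - 1 + object$K * (object$K - 1) + object$K * object$d +
    object$K * (if (object$cov_type == "full") object$d * (object$d + 1) / 2 else object$d)
  structure(object$loglik, df = p, nobs = object$n_samples, class = "logLik")
}

#' Decode states or posteriors from a fitted envelope HMM
#'
#' @param object a fitted [env_hmm()].
#' @param newdata observation matrix (defaults must be supplied; the model
#'   does not store its training data).
#' @param type `"viterbi"` for the maximum-probability path,
#'   `"posterior"` for the T-by-K smoothed state probabilities.
#' @param boundaries optional boundary table.
#' @param ... unused.
#' @export
predict.env_hmm <- function(object, newdata, type = c("viterbi", "posterior"),
                            boundaries = NULL, ...) {
  type <- match.arg(type)
  if (type == "viterbi") return(viterbi_decode(object, newdata, boundaries))
  X <- as.matrix(newdata)
  if (ncol(X) != object$d) stop("dimension mismatch with model", call. = FALSE)
  if (is.null(boundaries)) boundaries <- object$boundaries
  segs <- .segments(boundaries, nrow(X))
  logB <- .gauss_logdens(X, object$means, object$covariances, object$cov_type)
  .fb_cpp(logB, object$pi, object$A, segs)$gamma
}

#' Simulate observations from a fitted envelope HMM
#'
#' @param object a fitted [env_hmm()].
#' @param nsim number of samples to draw.
#' @param seed integer seed.
#' @param ... unused.
#' @return List with `X` (nsim-by-d draws) and `path` (hidden states).
#' @export
simulate.env_hmm <- function(object, nsim = 1000L, seed = 1L, ...) {
  set.seed(seed)
  K <- object$K; d <- object$d
  cum0 <- cumsum(object$pi)
  cumA <- t(apply(object$A, 1, cumsum))
  path <- integer(nsim)
  u <- stats::runif(nsim)
  path[1] <- findInterval(u[1], cum0) + 1L
  if (nsim > 1) for (t in 2:nsim)
    path[t] <- findInterval(u[t], cumA[path[t - 1], ]) + 1L
  X <- matrix(0, nsim, d)
  for (k in seq_len(K)) {
    idx <- which(path == k)
    if (length(idx))
      X[idx, ] <- matrix(stats::rnorm(length(idx) * d), length(idx), d) %*%
        chol(object$covariances[[k]]) +
        matrix(object$means[k, ], length(idx), d, byrow = TRUE)
  }
  list(X = X, path = path)
}

#' @export
plot.env_hmm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(t(x$means), type = "l", lty = 1, xlab = "component",
                    ylab = "state mean", main = "State means", ...)
  graphics::image(seq_len(x$K), seq_len(x$K), t(x$A)[, rev(seq_len(x$K))],
                  xlab = "to state", ylab = "from state",
                  main = "Transition matrix", axes = FALSE)
  graphics::axis(1, at = seq_len(x$K))
  graphics::axis(2, at = seq_len(x$K), labels = rev(seq_len(x$K)))
  invisible(x)
}
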