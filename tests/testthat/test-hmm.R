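test_that("K = 1 fit recovers the sample moments with a unit transition", {
  set.seed(8)
  X <- matrix(stats::rnorm(500 * 3, mean = 2), 500, 3)
  fit <- env_hmm(X, K = 1, n_restarts = 1, seed = 1)
  expect_equal(drop(fit$means), colMeans(X), tolerance = 1e-8)
  ml_cov <- stats::cov(X) * (nrow(X) - 1) / nrow(X)
  expect_equal(fit$covariances[[1]], ml_cov, tolerance = 1e-6)
  expect_equal(fit$A, matrix(1, 1, 1))
  p <- viterbi_decode(fit, X)
  expect_true(all(p$path == 1L))
})

test_that("two well-separated states are recovered by EM", {
  set.seed(9)
  stay <- 0.95
  true_mu <- rbind(rep(5, 3), rep(-5, 3))
  path <- integer(20000); path[1] <- 1
  for (t in 2:20000)
    path[t] <- if (stats::runif(1) < stay) path[t - 1] else 3 - path[t - 1]
  X <- true_mu[path, ] + matrix(stats::rnorm(20000 * 3), 20000, 3)
  fit <- env_hmm(X, K = 2, n_restarts = 3, seed = 2)
  perm <- match_states(true_mu, fit$means, method = "euclidean")
  expect_lt(max(abs(fit$means[perm, ] - true_mu)), 0.1)
  expect_lt(abs(fit$A[perm[1], perm[1]] - stay), 0.02)
  expect_lt(abs(fit$A[perm[2], perm[2]] - stay), 0.02)
  # decoded path matches the truth after relabelling
  dec <- viterbi_decode(fit, X)$path
  relabel <- integer(2); relabel[perm] <- 1:2
  expect_gt(mean(relabel[dec] == path), 0.98)
})

test_that("more restarts never select a worse model", {
  set.seed(10)
  X <- rbind(matrix(stats::rnorm(300 * 2, 3), 300, 2),
             matrix(stats::rnorm(300 * 2, -3), 300, 2))
  f1 <- env_hmm(X, K = 2, n_restarts = 1, seed = 5, max_iter = 50)
  f10 <- env_hmm(X, K = 2, n_restarts = 10, seed = 5, max_iter = 50)
  expect_gte(f10$loglik, f1$loglik - 1e-9)
})

test_that("seed-fixed fits are bit-reproducible", {
  set.seed(11)
  X <- matrix(stats::rnorm(400 * 2), 400, 2)
  f1 <- env_hmm(X, K = 2, n_restarts = 2, seed = 7, max_iter = 30)
  f2 <- env_hmm(X, K = 2, n_restarts = 2, seed = 7, max_iter = 30)
  f1$call <- f2$call <- NULL
  expect_identical(f1, f2)
})

test_that("Viterbi equals exhaustive path maximization on random small models", {
  set.seed(12)
  for (rep in 1:100) {
    K <- sample(2:3, 1)
    Tn <- sample(4:10, 1)
    par <- random_hmm_pars(K, Tn)
    segs <- matrix(c(1L, Tn), 1)
    got <- mserd:::.viterbi_cpp(par$logB, log(par$pi), log(par$A), segs)
    want <- brute_force_viterbi(par$logB, log(par$pi), log(par$A))
    expect_equal(as.integer(got), as.integer(want))
  }
})

test_that("dominant emissions force the decoded pattern", {
  pattern <- rep(c(1L, 2L), 10)
  logB <- matrix(-1000, 20, 2)
  logB[cbind(1:20, pattern)] <- 0
  A <- matrix(0.5, 2, 2)
  mod <- manual_hmm(c(0.5, 0.5), A, matrix(0, 2, 1), list(diag(1), diag(1)))
  got <- mserd:::.viterbi_cpp(logB, log(c(0.5, 0.5)), log(A), matrix(c(1L, 20L), 1))
  expect_equal(as.integer(got), pattern)
})

test_that("decoding is exclusive and fractional occupancies sum to one", {
  cfg <- two_state_cfg(n_subjects = 2, n_sessions = 2, T_ = 800L)
  gen <- simulate_envelope_dataset(cfg)
  conc <- standardize_concatenate(gen$dataset)
  pca <- prewhiten_pca(conc$X, n_components = 4)
  fit <- env_hmm(pca$Z, K = 2, n_restarts = 2, seed = 3,
                 boundaries = conc$boundaries)
  dec <- viterbi_decode(fit, pca$Z)
  expect_equal(length(dec$path), nrow(pca$Z))
  expect_true(all(dec$path %in% 1:2))
  tp <- temporal_params_by_recording(dec, fs = conc$fs)
  fo_sums <- tapply(tp$FO, paste(tp$subject, tp$session), sum)
  expect_true(all(abs(fo_sums - 1) < 1e-12))
})

test_that("the selection score is deterministic, additive and label-invariant", {
  set.seed(13)
  X <- matrix(stats::rnorm(300 * 2), 300, 2)
  fit <- env_hmm(X, K = 2, n_restarts = 2, seed = 4, max_iter = 40)
  s1 <- model_score(fit, X)
  expect_identical(s1, model_score(fit, X))
  # additivity over independent segments: duplicated data doubles the score
  X2 <- rbind(X, X)
  b2 <- data.frame(subject = "s", session = c("a", "b"),
                   start = c(0, 300), end = c(300, 600))
  expect_equal(model_score(fit, X2, boundaries = b2), 2 * s1,
               tolerance = 1e-6 * abs(s1))
  # permuting state labels leaves the score unchanged
  swap <- fit
  swap$pi <- fit$pi[2:1]
  swap$A <- fit$A[2:1, 2:1]
  swap$means <- fit$means[2:1, , drop = FALSE]
  swap$covariances <- fit$covariances[2:1]
  expect_equal(model_score(swap, X), s1, tolerance = 1e-9)
})

test_that("the true generating model scores better than a perturbed copy", {
  true_mu <- rbind(c(4, 0), c(-4, 0))
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  mod <- manual_hmm(c(0.5, 0.5), A, true_mu, list(diag(2), diag(2)))
  sim <- simulate(mod, nsim = 20000, seed = 6)
  bad <- mod
  bad$means <- true_mu + 1
  bad$A <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)
  expect_lt(model_score(mod, sim$X), model_score(bad, sim$X))
})

test_that("state matching finds a planted permutation", {
  set.seed(14)
  A <- matrix(stats::rnorm(5 * 12), 5, 12)
  perm <- sample(5)
  B <- A[perm, ] * 2 + matrix(stats::rnorm(5 * 12, sd = 0.01), 5, 12)
  got <- match_states(A, B)
  expect_equal(perm[got], 1:5)
})

test_that("model methods expose coefficients, likelihood and predictions", {
  set.seed(15)
  X <- rbind(matrix(stats::rnorm(200 * 2, 3), 200, 2),
             matrix(stats::rnorm(200 * 2, -3), 200, 2))
  fit <- env_hmm(X, K = 2, n_restarts = 2, seed = 8, max_iter = 50)
  co <- coef(fit)
  expect_named(co, c("pi", "A", "means", "covariances"))
  expect_equal(sum(co$pi), 1, tolerance = 1e-10)
  expect_equal(rowSums(co$A), c(1, 1), tolerance = 1e-10)
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$loglik)
  gamma <- predict(fit, X, type = "posterior")
  expect_equal(rowSums(gamma), rep(1, 400), tolerance = 1e-9)
  expect_output(print(fit), "envelope HMM")
  expect_output(print(summary(fit)), "Per-state")
})
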