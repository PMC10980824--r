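test_that("absorbing chain stays in its start state", {
  cfg <- sim_config(n_subjects = 1, n_sessions = 1, n_nodes = 4, n_states = 3,
                    samples_per_session = 500,
                    transition_matrix = diag(3),
                    initial_probs = c(1, 0, 0), seed = 7)
  paths <- simulate_state_paths(cfg)
  expect_true(all(paths[[1]][[1]] == 1L))
})

test_that("uniform two-state chain has near-equal occupancy at large T", {
  cfg <- sim_config(n_subjects = 1, n_sessions = 1, n_nodes = 2, n_states = 2,
                    samples_per_session = 100000,
                    transition_matrix = matrix(0.5, 2, 2),
                    initial_probs = c(0.5, 0.5), seed = 11)
  p <- simulate_state_paths(cfg)[[1]][[1]]
  expect_lt(abs(mean(p == 1) - 0.5), 0.01)
  expect_lt(abs(mean(p == 2) - 0.5), 0.01)
})

test_that("geometric dwell times match 1/(1 - a_kk)", {
  cfg <- two_state_cfg(T_ = 100000L, stay = 0.9, seed = 13)
  p <- simulate_state_paths(cfg)[[1]][[1]]
  r <- rle(p)
  mlt_samples <- mean(r$lengths)
  expect_lt(abs(mlt_samples - 10) / 10, 0.05)  # 10 samples = 0.25 s at 40 Hz
})

test_that("generator is bit-reproducible and streams are seed-derived", {
  cfg <- two_state_cfg(n_subjects = 2, n_sessions = 2, T_ = 300L)
  a <- simulate_envelope_dataset(cfg)
  b <- simulate_envelope_dataset(cfg)
  expect_identical(a, b)
  cfg2 <- two_state_cfg(n_subjects = 2, n_sessions = 2, T_ = 300L, seed = 43L)
  c <- simulate_envelope_dataset(cfg2)
  expect_false(identical(a$dataset$data, c$dataset$data))
  # recordings within a run are distinct
  expect_false(identical(a$paths[[1]][[1]], a$paths[[2]][[1]]))
})

test_that("invalid stochastic matrices are rejected", {
  A_bad <- matrix(c(0.9, 0.2, 0.2, 0.8), 2, 2)  # rows do not sum to 1
  expect_error(
    sim_config(n_states = 2, n_nodes = 2, transition_matrix = A_bad,
               initial_probs = c(0.5, 0.5)),
    "sum to 1")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(samples_per_session = 1), "samples_per_session")
})

test_that("noiseless envelopes equal baseline plus the state pattern", {
  cfg <- sim_config(n_subjects = 1, n_sessions = 1, n_nodes = 3, n_states = 2,
                    samples_per_session = 200, baseline = 5,
                    state_patterns = rbind(c(1, 0, 0), c(0, 2, 0)),
                    noise_sd = 1e-12, seed = 3)
  paths <- simulate_state_paths(cfg)
  E <- simulate_envelopes(paths, cfg)$data[[1]][[1]]
  p <- paths[[1]][[1]]
  expected <- t(5 + cfg$state_patterns[p, ])
  expect_equal(E, expected, tolerance = 1e-9)
})

test_that("shared noise induces high envelope correlation between twin nodes", {
  Sigma <- diag(4) * 0.1
  Sigma[1, 2] <- Sigma[2, 1] <- 0.099  # nodes 1-2 nearly duplicate noise
  cfg <- sim_config(n_subjects = 1, n_sessions = 1, n_nodes = 4, n_states = 2,
                    samples_per_session = 10000,
                    state_patterns = matrix(0, 2, 4),
                    noise_cov = Sigma, seed = 5)
  E <- simulate_envelopes(simulate_state_paths(cfg), cfg)$data[[1]][[1]]
  expect_gt(stats::cor(E[1, ], E[2, ]), 0.9)
})

test_that("identity mixing preserves per-node marginal variance", {
  cfg <- two_state_cfg(T_ = 5000L, seed = 21)
  E1 <- simulate_envelopes(simulate_state_paths(cfg), cfg)$data[[1]][[1]]
  cfg2 <- cfg; cfg2$mixing <- diag(cfg$n_nodes)
  E2 <- simulate_envelopes(simulate_state_paths(cfg2), cfg2)$data[[1]][[1]]
  expect_equal(apply(E1, 1, var), apply(E2, 1, var), tolerance = 1e-10)
})

test_that("generator ground truth matches run-length temporal parameters", {
  cfg <- sim_config(n_subjects = 2, n_sessions = 2, n_nodes = 3, n_states = 3,
                    samples_per_session = 400, seed = 17)
  gen <- simulate_envelope_dataset(cfg)
  for (s in 1:2) for (j in 1:2) {
    tp <- temporal_params(gen$paths[[s]][[j]], K = 3, fs = cfg$fs)
    tr <- gen$truth[gen$truth$subject == gen$dataset$subjects[s] &
                      gen$truth$session == gen$dataset$sessions[j], ]
    expect_equal(tp$NO, tr$NO)
    expect_equal(tp$FO, tr$FO)
    expect_equal(tp$MLT_s, tr$MLT_s)
    expect_equal(tp$MIL_s, tr$MIL_s)
  }
})

test_that("planting a connectome effect adds delta, clips and preserves symmetry", {
  base <- list(diag(5), diag(5))
  base[[1]][1, 2] <- base[[1]][2, 1] <- 0.9
  edges <- rbind(c(1, 2), c(2, 3))
  out <- plant_connectome_effect(base, edges, delta = 0.3,
                                 mask = c(TRUE, FALSE))
  expect_equal(out[[1]][1, 2], 1.0)        # 0.9 + 0.3 clipped
  expect_equal(out[[1]][2, 3], 0.3)
  expect_identical(out[[2]], base[[2]])    # unflagged subject untouched
  expect_equal(out[[1]], t(out[[1]]))
  expect_identical(plant_connectome_effect(base, edges, delta = 0), base)
  expect_error(plant_connectome_effect(base, rbind(c(1, 9)), 0.1), "out of range")
})

test_that("keypress streams follow the 4-1-3-2-4 sequence and Poisson counts", {
  ev <- simulate_ftt_blocks(n_blocks = 1, mean_rate = 3, error_rate = 0,
                            seed = 9, learning_curve = FALSE)
  keys <- ev$key
  seq5 <- c(4, 1, 3, 2, 4)
  expect_equal(keys, seq5[(seq_along(keys) - 1) %% 5 + 1])
  # count within 3 SD of Poisson(90)
  counts <- vapply(1:30, function(s)
    nrow(simulate_ftt_blocks(n_blocks = 1, mean_rate = 3, error_rate = 0,
                             seed = s, learning_curve = FALSE)), 1L)
  expect_true(all(abs(counts - 90) <= 3 * sqrt(90)))
})

test_that("corruption rate matches the requested error rate", {
  ev <- simulate_ftt_blocks(n_blocks = 40, mean_rate = 10, error_rate = 0.5,
                            seed = 23, learning_curve = FALSE,
                            block_duration = 30)
  n_true <- attr(ev, "n_correct_true")
  frac_err <- 1 - sum(n_true) / nrow(ev)
  expect_gt(nrow(ev), 5000)
  expect_lt(abs(frac_err - 0.5), 0.02)
})
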