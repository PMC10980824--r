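test_that("paired t statistics match the closed form and its symmetries", {
  # one edge with differences (1, 2, 3): t = 2 / (1 / sqrt(3))
  mk <- function(v) { M <- diag(2); M[1, 2] <- M[2, 1] <- v; M }
  A <- lapply(c(1, 2, 3), mk)
  B <- lapply(c(0, 0, 0), mk)
  tmat <- edge_paired_t(A, B)
  expect_equal(tmat[1, 2], 2 / (1 / sqrt(3)), tolerance = 1e-12)
  # identical conditions: missing statistic (zero variance)
  expect_true(is.na(edge_paired_t(A, A)[1, 2]))
  # sign flip of all differences negates t
  expect_equal(edge_paired_t(B, A)[1, 2], -tmat[1, 2], tolerance = 1e-12)
})

test_that("edge correlations reproduce extremes and antisymmetry", {
  set.seed(26)
  vals <- stats::rnorm(10)
  mk <- function(v) { M <- diag(3); M[1, 2] <- M[2, 1] <- v
    M[1, 3] <- M[3, 1] <- stats::rnorm(1); M[2, 3] <- M[3, 2] <- stats::rnorm(1); M }
  mats <- lapply(vals, mk)
  r <- edge_correlation(mats, vals)
  expect_equal(r[1, 2], 1, tolerance = 1e-12)
  rneg <- edge_correlation(mats, -vals)
  expect_equal(rneg[lower.tri(rneg)], -r[lower.tri(r)], tolerance = 1e-12)
  expect_error(edge_correlation(mats, rep(1, 10)), "constant")
})

test_that("null edge correlations match the permutation null distribution", {
  set.seed(27)
  n_sub <- 30
  mats <- simulate_connectomes(n_sub, n_nodes = 6, n_time = 50, seed = 5)
  covariate <- stats::rnorm(n_sub)
  r_obs <- edge_correlation(mats, covariate)
  obs <- r_obs[lower.tri(r_obs)]
  perm <- replicate(1000, {
    rp <- edge_correlation(mats, sample(covariate))
    rp[lower.tri(rp)][1]
  })
  expect_lt(abs(mean(obs)), 0.15)
  ks <- suppressWarnings(stats::ks.test(obs, perm))
  expect_gt(ks$p.value, 0.01)
})

test_that("suprathreshold components follow graph connectivity", {
  n <- 8
  M <- matrix(0, n, n)
  set_edge <- function(M, i, j, v) { M[i, j] <- M[j, i] <- v; M }
  M <- set_edge(M, 1, 2, 4); M <- set_edge(M, 2, 3, 4); M <- set_edge(M, 7, 8, 4)
  comps <- suprathreshold_components(M, threshold = 3.5)
  expect_length(comps, 2)
  expect_equal(comps[[1]]$size, 2)
  expect_equal(comps[[1]]$nodes, 1:3)
  expect_equal(comps[[2]]$size, 1)
  expect_equal(comps[[2]]$nodes, c(7L, 8L))
  # threshold above the maximum: nothing
  expect_length(suprathreshold_components(M, threshold = 10), 0)
  # 4-cycle: one component with 4 edges and 4 nodes
  C <- matrix(0, 5, 5)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))) C <- set_edge(C, e[1], e[2], 5)
  cy <- suprathreshold_components(C, threshold = 3.5)
  expect_length(cy, 1)
  expect_equal(cy[[1]]$size, 4)
  expect_equal(cy[[1]]$nodes, 1:4)
  # negative tail is analysed separately
  expect_length(suprathreshold_components(-C, threshold = 3.5), 0)
  neg <- suprathreshold_components(-C, threshold = 3.5, direction = "negative")
  expect_equal(neg[[1]]$size, 4)
})

test_that("node weights count incident suprathreshold edges", {
  M <- matrix(0, 4, 4)
  M[1, 2] <- M[2, 1] <- 4; M[2, 3] <- M[3, 2] <- 4
  cp <- suprathreshold_components(M, 3.5)[[1]]
  w <- component_node_weights(cp)
  expect_equal(unname(w[c("1", "2", "3")]), c(1L, 2L, 1L))
})

test_that("a planted component is recovered with a small FWER p-value", {
  set.seed(28)
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1))
  base_a <- simulate_connectomes(20, n_nodes = 12, n_time = 60, seed = 100)
  base_b <- simulate_connectomes(20, n_nodes = 12, n_time = 60, seed = 200)
  planted <- plant_connectome_effect(base_a, edges, delta = 0.3)
  res <- nbs_fwer(planted, base_b, threshold = 3.5, n_perm = 500, seed = 1)
  expect_gt(length(res$components), 0)
  top <- res$components[[1]]
  planted_keys <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  found_keys <- paste(top$edges[, 1], top$edges[, 2])
  expect_gte(sum(planted_keys %in% found_keys), 4)
  expect_lt(top$p_fwer, 0.05)
})

test_that("permutation p-values are monotone in component size and never zero", {
  set.seed(29)
  base_a <- simulate_connectomes(15, n_nodes = 10, n_time = 40, seed = 300)
  base_b <- simulate_connectomes(15, n_nodes = 10, n_time = 40, seed = 400)
  planted <- plant_connectome_effect(
    base_a, rbind(c(1, 2), c(2, 3), c(5, 6)), delta = 0.5)
  res <- nbs_fwer(planted, base_b, threshold = 2.5, n_perm = 300, seed = 2)
  sizes <- vapply(res$components, `[[`, 1L, "size")
  ps <- vapply(res$components, `[[`, 1.0, "p_fwer")
  if (length(ps) > 1) expect_true(all(diff(ps[order(-sizes)]) >= 0))
  expect_true(all(ps > 0))
  # p computed from the stored null matches the +1 estimator
  for (i in seq_along(res$components))
    expect_equal(ps[i], (1 + sum(res$max_null >= sizes[i])) / (res$n_perm + 1))
})

test_that("raising the threshold never grows a component", {
  set.seed(30)
  M <- stats::cor(matrix(stats::rnorm(30 * 10), 30, 10)) * 10
  for (thr in c(2, 4, 6)) {
    lo <- suprathreshold_components(M, thr)
    hi <- suprathreshold_components(M, thr * 2)
    max_lo <- if (length(lo)) lo[[1]]$size else 0
    max_hi <- if (length(hi)) hi[[1]]$size else 0
    expect_lte(max_hi, max_lo)
  }
})

test_that("permutation streams are reproducible and storage order is irrelevant", {
  base_a <- simulate_connectomes(12, n_nodes = 8, n_time = 40, seed = 500)
  base_b <- simulate_connectomes(12, n_nodes = 8, n_time = 40, seed = 600)
  r1 <- nbs_fwer(base_a, base_b, threshold = 2.5, n_perm = 200, seed = 9)
  r2 <- nbs_fwer(base_a, base_b, threshold = 2.5, n_perm = 200, seed = 9)
  expect_identical(r1$max_null, r2$max_null)
  # permuting subject storage order leaves observed statistics identical
  ord <- c(5, 1, 12, 3, 9, 2, 11, 7, 4, 10, 6, 8)
  r3 <- suppressWarnings(
    nbs_fwer(base_a[ord], base_b[ord], threshold = 2.5, n_perm = 10, seed = 9))
  expect_equal(r3$stat_matrix, r1$stat_matrix, tolerance = 1e-12)
  # correlation design is reproducible too
  cov_ <- stats::rnorm(12)
  c1 <- nbs_fwer(base_a, covariate = cov_, threshold = 2.5, n_perm = 100, seed = 4)
  c2 <- nbs_fwer(base_a, covariate = cov_, threshold = 2.5, n_perm = 100, seed = 4)
  expect_identical(c1$max_null, c2$max_null)
})

test_that("design validation rejects ambiguous calls", {
  mats <- simulate_connectomes(6, 5, 30, seed = 7)
  expect_error(nbs_fwer(mats), "exactly one")
  expect_error(nbs_fwer(mats, matrices_b = mats, covariate = 1:6), "exactly one")
  expect_warning(nbs_fwer(mats, covariate = stats::rnorm(6), n_perm = 50, seed = 1),
                 "coarse")
})
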