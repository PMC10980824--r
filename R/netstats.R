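# Network-based statistics: edge-wise tests, suprathreshold connected
# components, permutation FWER over the maximum component size.

# lower-triangle edge index helpers (i < j, column-major order)
.edge_index <- function(n) {
  which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)[, c(2, 1), drop = FALSE]
}

.vec_lower <- function(M) M[lower.tri(M)]

# E x n_subjects matrix of lower-triangle edge values (robust to E = 1)
.lower_mat <- function(mats) {
  E <- nrow(mats[[1]]) * (nrow(mats[[1]]) - 1) / 2
  matrix(vapply(mats, .vec_lower, numeric(E)), nrow = E)
}

.mat_from_lower <- function(v, n) {
  M <- matrix(NA_real_, n, n)
  M[lower.tri(M)] <- v
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  M
}

#' Edge-wise paired t statistics between two conditions
#'
#' Per edge, the paired t statistic of the within-subject differences
#' `A - B` across subjects. Edges with zero difference variance get a
#' missing statistic (excluded from components downstream).
#'
#' @param matrices_a,matrices_b lists of symmetric matrices, one per subject,
#'   matched by position.
#' @return Symmetric matrix of t statistics (`NA` diagonal).
#' @export
edge_paired_t <- function(matrices_a, matrices_b) {
  stopifnot(length(matrices_a) == length(matrices_b), length(matrices_a) >= 3)
  n <- nrow(matrices_a[[1]])
  D <- t(.lower_mat(mapply(`-`, matrices_a, matrices_b, SIMPLIFY = FALSE)))
  m <- colMeans(D)
  s <- apply(D, 2, stats::sd)
  t_ <- ifelse(s > 0, m / (s / sqrt(nrow(D))), NA_real_)
  .mat_from_lower(t_, n)
}

#' Edge-wise Pearson correlation with a covariate
#'
#' Per edge, the Pearson correlation between the edge's values across
#' subjects and a behavioural or model-derived covariate.
#'
#' @param matrices list of symmetric matrices, one per subject.
#' @param covariate numeric vector, one value per subject.
#' @return Symmetric matrix of correlations (`NA` diagonal).
#' @export
edge_correlation <- function(matrices, covariate) {
  stopifnot(length(matrices) == length(covariate), all(is.finite(covariate)))
  if (stats::sd(covariate) == 0) stop("constant covariate", call. = FALSE)
  n <- nrow(matrices[[1]])
  V <- t(.lower_mat(matrices))
  r <- suppressWarnings(drop(stats::cor(covariate, V)))
  .mat_from_lower(r, n)
}

#' Suprathreshold connected components of a statistic matrix
#'
#' Keeps the edges whose statistic exceeds the threshold in the requested
#' direction (`statistic > threshold`, or `statistic < -threshold` for the
#' negative tail; the two tails are analysed separately) and returns the
#' maximal connected components of the resulting graph.
#'
#' @param stat_matrix symmetric edge-statistic matrix (`NA` allowed).
#' @param threshold positive statistic cutoff (e.g. `t = 3.5`).
#' @param direction `"positive"` (default) or `"negative"`.
#' @return List of components, each a list with `edges` (2-column matrix),
#'   `nodes` (integer vector), `size` (edge count); ordered by decreasing
#'   size. Empty list when no edge survives.
#' @export
suprathreshold_components <- function(stat_matrix, threshold,
                                      direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  n <- nrow(stat_matrix)
  v <- .vec_lower(stat_matrix)
  keep <- if (direction == "positive") !is.na(v) & v > threshold
          else !is.na(v) & v < -threshold
  if (!any(keep)) return(list())
  ed <- .edge_index(n)[keep, , drop = FALSE]
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[ed[, 1]]
  comps <- lapply(unique(comp_of_edge), function(cid) {
    e <- ed[comp_of_edge == cid, , drop = FALSE]
    list(edges = e, nodes = sort(unique(as.vector(e))), size = nrow(e))
  })
  comps[order(vapply(comps, `[[`, 1L, "size"), decreasing = TRUE)]
}

#' Node weights of a suprathreshold network
#'
#' For reporting hubs: each node's weight is the number of suprathreshold
#' edges incident to it.
#'
#' @param component one component from [suprathreshold_components()].
#' @return Named integer vector (node index -> weight).
#' @export
component_node_weights <- function(component) {
  tab <- table(as.vector(component$edges))
  stats::setNames(as.integer(tab), names(tab))
}

#' Network-based statistic with permutation FWER control
#'
#' Computes the observed edge-wise statistics and suprathreshold components,
#' then builds the null distribution of the maximum component size (edge
#' count) by permutation: random sign-flips of the within-subject difference
#' matrices for the paired design, random reshuffling of the covariate
#' across subjects for the correlation design. The FWER-corrected p-value of
#' each component is `(1 + #{permutation max size >= observed size}) /
#' (n_perm + 1)`.
#'
#' For the correlation design the correlations are thresholded through their
#' t-transform `t = r * sqrt((n-2) / (1-r^2))`, so a single t cutoff applies
#' to both designs.
#'
#' @param matrices_a lists of symmetric matrices per subject (condition A, or
#'   the only condition for the correlation design).
#' @param matrices_b condition B matrices (paired design only).
#' @param covariate per-subject covariate (correlation design only).
#' @param threshold statistic cutoff on the t scale (default 3.5).
#' @param n_perm number of permutations (default 5000; < 100 warns).
#' @param direction `"positive"` or `"negative"` tail.
#' @param seed integer seed for the permutation stream.
#' @return Object of class `"nbs_result"`: list with `stat_matrix`,
#'   `components` (each with `p_fwer` attached), `max_null` (permutation
#'   null of the maximum size), `threshold`, `n_perm`, `seed`, `design`.
#' @export
nbs_fwer <- function(matrices_a, matrices_b = NULL, covariate = NULL,
                     threshold = 3.5, n_perm = 5000L,
                     direction = c("positive", "negative"), seed = 1L) {
  direction <- match.arg(direction)
  if (n_perm < 100) warning("n_perm < 100 gives a coarse FWER estimate")
  paired <- !is.null(matrices_b)
  if (paired == !is.null(covariate))
    stop("supply exactly one of matrices_b (paired) or covariate (correlation)",
         call. = FALSE)
  n <- nrow(matrices_a[[1]])
  ns <- length(matrices_a)
  edges <- .edge_index(n)
  E <- n * (n - 1) / 2

  dir_sign <- if (direction == "positive") 1L else -1L
  if (paired) {
    # E x ns difference matrix; the per-edge sum of squares is invariant
    # under sign flips, so each permutation needs only one matrix product
    D <- .lower_mat(mapply(`-`, matrices_a, matrices_b, SIMPLIFY = FALSE))
    SS <- rowSums(D^2)
    t_from_sum <- function(sm) {  # sm: E-vector or E x P matrix of flip-sums
      mu <- sm / ns
      v <- (SS - ns * mu^2) / (ns - 1)  # SS recycles down columns
      out <- mu / sqrt(v / ns)
      out[!(v > 1e-300)] <- NA_real_
      out
    }
    t_obs <- t_from_sum(rowSums(D))
    set.seed(stream_seed(seed, 0L))
    S <- matrix(sample(c(-1, 1), n_perm * ns, replace = TRUE), ns, n_perm)
    max_null <- integer(n_perm)
    chunk <- max(1L, floor(4e7 / E))  # bound the E x chunk working matrices
    for (c0 in seq(1L, n_perm, by = chunk)) {
      idx <- c0:min(c0 + chunk - 1L, n_perm)
      Tp <- t_from_sum(D %*% S[, idx, drop = FALSE])
      max_null[idx] <- .nbs_maxcomp_cpp(Tp, edges, n, threshold, dir_sign)
    }
  } else {
    V <- t(.lower_mat(matrices_a))  # ns x E
    if (stats::sd(covariate) == 0) stop("constant covariate", call. = FALSE)
    r_to_t <- function(r) {
      r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
      r * sqrt((ns - 2) / (1 - r^2))
    }
    t_obs <- r_to_t(suppressWarnings(drop(stats::cor(covariate, V))))
    set.seed(stream_seed(seed, 0L))
    max_null <- integer(n_perm)
    chunk <- max(1L, floor(4e7 / E))
    for (c0 in seq(1L, n_perm, by = chunk)) {
      idx <- c0:min(c0 + chunk - 1L, n_perm)
      C <- vapply(idx, function(p) sample(covariate), numeric(ns))
      Rp <- t(suppressWarnings(stats::cor(C, V)))  # E x chunk
      max_null[idx] <- .nbs_maxcomp_cpp(r_to_t(Rp), edges, n, threshold, dir_sign)
    }
  }

  stat_matrix <- .mat_from_lower(t_obs, n)
  comps <- suprathreshold_components(stat_matrix, threshold, direction)
  comps <- lapply(comps, function(cp) {
    cp$p_fwer <- (1 + sum(max_null >= cp$size)) / (n_perm + 1)
    cp
  })
  structure(list(stat_matrix = stat_matrix, components = comps,
                 max_null = max_null, threshold = threshold,
                 n_perm = as.integer(n_perm), seed = seed,
                 direction = direction,
                 design = if (paired) "paired" else "correlation"),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("NBS (%s design, %s tail): threshold %.2f, %d permutations\n",
              x$design, x$direction, x$threshold, x$n_perm))
  if (length(x$components) == 0) {
    cat("  no suprathreshold components\n")
  } else {
    for (i in seq_along(x$components)) {
      cp <- x$components[[i]]
      cat(sprintf("  component %d: %d edges, %d nodes, p_fwer = %.4f\n",
                  i, cp$size, length(cp$nodes), cp$p_fwer))
    }
  }
  invisible(x)
}
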