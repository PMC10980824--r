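#' Build the connectome node registry
#'
#' Concatenates an atlas table (e.g. the 116-region AAL parcellation,
#' cerebellum included) with extra literature-derived nodes, atlas first.
#' Coordinates are carried as metadata only; no geometry is computed on them.
#'
#' @param aal_table data.frame with columns `id`, `name`, `mni_x`, `mni_y`,
#'   `mni_z`, `source`.
#' @param extra_nodes optional data.frame with the same columns (may have
#'   zero rows).
#' @return The combined registry data.frame, with attribute `n_nodes`.
#' @export
build_node_registry <- function(aal_table, extra_nodes = NULL) {
  cols <- c("id", "name", "mni_x", "mni_y", "mni_z", "source")
  stopifnot(all(cols %in% names(aal_table)))
  reg <- aal_table[, cols]
  if (!is.null(extra_nodes) && nrow(extra_nodes) > 0) {
    stopifnot(all(cols %in% names(extra_nodes)))
    reg <- rbind(reg, extra_nodes[, cols])
  }
  if (anyDuplicated(reg$id)) stop("duplicate node ids in registry", call. = FALSE)
  if (anyDuplicated(reg$name)) stop("duplicate node names in registry", call. = FALSE)
  rownames(reg) <- NULL
  attr(reg, "n_nodes") <- nrow(reg)
  reg
}

#' Read the bundled node registry
#'
#' Loads the registry TSV shipped with the package: the 116 standard AAL
#' region labels plus 10 synthetic motor-literature placeholder nodes
#' (126 nodes total). MNI coordinates are left `NA`; users analysing real
#' data should supply their own registry with coordinates.
#'
#' @param path registry TSV (columns `id`, `name`, `mni_x`, `mni_y`,
#'   `mni_z`, `source`); defaults to the bundled file.
#' @return Registry data.frame as from [build_node_registry()].
#' @export
read_node_registry <- function(path = system.file("extdata",
                                                  "node_registry_synthetic.tsv",
                                                  package = "mserd")) {
  reg <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  build_node_registry(reg[reg$source == "AAL", ], reg[reg$source != "AAL", ])
}

#' Regression orthogonalization of node signals
#'
#' Residualizes each column of `x` on the seed signal (ordinary least
#' squares with intercept), removing the instantaneous linear component
#' shared with the seed -- a generic stand-in for source-leakage correction.
#' Identity mode returns the input untouched.
#'
#' @param x numeric vector or samples-by-nodes matrix of target signals.
#' @param seed numeric seed signal (same length), or `NULL` for identity
#'   mode.
#' @return Residualized signals, same shape as `x`.
#' @export
orthogonalize <- function(x, seed = NULL) {
  if (is.null(seed)) return(x)
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  if (stats::sd(seed) == 0) stop("constant seed signal", call. = FALSE)
  qz <- qr(cbind(1, seed))
  out <- qr.resid(qz, X)
  if (vec) drop(out) else out
}

#' Slow amplitude-envelope correlation connectome
#'
#' Pearson correlation between moving-average-smoothed node envelopes
#' (window `smooth_s` seconds, default 1.0 s: the slow timescale), returning
#' a symmetric matrix with unit diagonal. With
#' `leakage_correction = "pairwise"`, each ordered pair is residualized
#' (target on seed) before smoothing and correlating, and the matrix is
#' symmetrized by averaging the two directions.
#'
#' @param node_signals samples-by-nodes matrix of envelope signals.
#' @param fs sampling rate in Hz.
#' @param smooth_s smoothing window in seconds (0 disables smoothing).
#' @param leakage_correction `"none"` (default) or `"pairwise"`.
#' @return n-by-n correlation matrix; zero-variance channels give `NA`
#'   rows/columns (diagonal kept at 1 for valid nodes).
#' @export
envelope_correlation <- function(node_signals, fs, smooth_s = 1.0,
                                 leakage_correction = c("none", "pairwise")) {
  leakage_correction <- match.arg(leakage_correction)
  X <- as.matrix(node_signals)
  n <- ncol(X)
  if (n < 2) stop("need >= 2 nodes", call. = FALSE)
  smooth <- function(M) {
    if (smooth_s <= 0) return(M)
    win <- max(1L, round(smooth_s * fs))
    if (win >= nrow(M)) stop("smoothing window longer than signal", call. = FALSE)
    cs <- rbind(0, apply(as.matrix(M), 2, cumsum))
    st <- seq_len(nrow(M) - win + 1L)
    (cs[st + win, , drop = FALSE] - cs[st, , drop = FALSE]) / win
  }
  bad <- apply(X, 2, stats::sd) == 0
  R <- matrix(NA_real_, n, n)
  if (leakage_correction == "none") {
    S <- smooth(X[, !bad, drop = FALSE])
    R[!bad, !bad] <- stats::cor(S)
  } else {
    for (i in seq_len(n)) {
      if (bad[i]) next
      res <- orthogonalize(X[, -i, drop = FALSE], seed = X[, i])
      keep <- apply(res, 2, stats::sd) > 1e-12
      S <- smooth(cbind(X[, i], res))
      r <- suppressWarnings(drop(stats::cor(S[, 1], S[, -1, drop = FALSE])))
      r[!keep] <- NA
      R[i, seq_len(n)[-i]] <- r
    }
    R <- (R + t(R)) / 2
  }
  diag(R)[!bad] <- 1
  R
}

#' Per-node signal power
#'
#' Sample variance of each node signal, the standard control vector for
#' power-induced connectivity effects.
#'
#' @param node_signals samples-by-nodes matrix (or vector).
#' @return Numeric vector of per-node variances.
#' @export
node_power <- function(node_signals) {
  X <- if (is.null(dim(node_signals))) matrix(node_signals, ncol = 1) else as.matrix(node_signals)
  if (nrow(X) < 2) stop("need >= 2 samples", call. = FALSE)
  unname(apply(X, 2, stats::var))
}

#' Mean connectivity strength within a state network
#'
#' Restricts the connectome to the network's nodes, averages each node's
#' off-diagonal correlations within the network, then averages these node
#' means -- one scalar per subject and session. For a symmetric matrix this
#' equals the grand mean of the off-diagonal entries of the restricted
#' matrix.
#'
#' @param connectome symmetric correlation matrix.
#' @param state_network a `"state_network"` (or integer node vector).
#' @return Scalar mean connectivity strength.
#' @export
mean_connectivity_strength <- function(connectome, state_network) {
  nodes <- if (inherits(state_network, "state_network")) state_network$nodes else as.integer(state_network)
  if (length(nodes) < 2) stop("state network must have >= 2 nodes", call. = FALSE)
  if (max(nodes) > nrow(connectome)) stop("network node outside connectome", call. = FALSE)
  M <- connectome[nodes, nodes, drop = FALSE]
  node_means <- (rowSums(M) - diag(M)) / (length(nodes) - 1)
  mean(node_means)
}
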