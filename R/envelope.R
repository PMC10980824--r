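#' Amplitude envelope via the Hilbert transform
#'
#' Modulus of the analytic signal, computed by the standard FFT construction
#' (negative-frequency half zeroed, positive half doubled).
#'
#' @param x real numeric vector, length >= 4.
#' @return Non-negative envelope, same length as `x`.
#' @export
hilbert_envelope <- function(x) {
  if (!is.numeric(x) || length(x) < 4) stop("need a numeric signal of length >= 4", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite values in signal", call. = FALSE)
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Moving-average downsampling of an envelope
#'
#' Averages the signal over sliding windows of `win_s` seconds stepped every
#' `step_s` seconds (75% overlap at the defaults), so the output rate is
#' `1 / step_s` -- 40 Hz for 100-ms windows sliding every 25 ms. Windows are
#' left-aligned and half-open; a partial trailing window is dropped, giving
#' `floor((T/fs - win_s) / step_s) + 1` output samples.
#'
#' @param x numeric vector or time-by-channel matrix.
#' @param fs input sampling rate in Hz.
#' @param win_s window width in seconds (default 0.100).
#' @param step_s window step in seconds (default 0.025).
#' @return A list with `x` (downsampled vector/matrix) and `fs` (output rate,
#'   `1 / step_s`).
#' @export
moving_average_downsample <- function(x, fs, win_s = 0.100, step_s = 0.025) {
  stopifnot(win_s >= step_s, step_s > 0, fs > 0)
  win <- round(win_s * fs)
  step <- step_s * fs
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  n <- nrow(X)
  if (n < win) stop("signal shorter than one window", call. = FALSE)
  n_out <- floor((n / fs - win_s) / step_s) + 1
  starts <- pmin(round((seq_len(n_out) - 1) * step) + 1, n - win + 1)
  cs <- rbind(0, apply(X, 2, cumsum))
  out <- (cs[starts + win, , drop = FALSE] - cs[starts, , drop = FALSE]) / win
  list(x = if (vec) drop(out) else out, fs = 1 / step_s)
}

#' Standardize and concatenate an envelope dataset
#'
#' Each node channel is demeaned per recording; all channels are then divided
#' by one global standard deviation computed over the whole concatenated
#' matrix; recordings are stacked subject-major, session-minor with boundary
#' bookkeeping for later de-concatenation.
#'
#' @param dataset an `"envelope_dataset"` (see [simulate_envelopes()]), whose
#'   per-recording matrices are nodes-by-time.
#' @return A `"concatenated_envelope"`: list with `X` (samples-by-nodes),
#'   `boundaries` (data.frame `subject`, `session`, `start`, `end`, half-open
#'   `[start, end)` in 0-based rows), `fs`, `global_sd`.
#' @export
standardize_concatenate <- function(dataset) {
  stopifnot(inherits(dataset, "envelope_dataset") || is.list(dataset))
  blocks <- list(); rows <- list(); off <- 0L
  for (s in seq_along(dataset$data)) for (j in seq_along(dataset$data[[s]])) {
    E <- t(dataset$data[[s]][[j]])          # time x nodes
    E <- sweep(E, 2, colMeans(E))           # demean per recording & channel
    blocks[[length(blocks) + 1L]] <- E
    rows[[length(rows) + 1L]] <- data.frame(
      subject = dataset$subjects[s], session = dataset$sessions[j],
      start = off, end = off + nrow(E))
    off <- off + nrow(E)
  }
  if (length(blocks) == 0) stop("empty dataset", call. = FALSE)
  X <- do.call(rbind, blocks)
  g <- stats::sd(as.vector(X))
  if (!is.finite(g) || g == 0) stop("zero global variance", call. = FALSE)
  structure(list(X = X / g, boundaries = do.call(rbind, rows),
                 fs = dataset$fs, global_sd = g),
            class = "concatenated_envelope")
}

#' De-concatenate a sample-wise vector or matrix by recording
#'
#' @param x vector or matrix whose rows follow the concatenated sample axis.
#' @param boundaries boundary table from [standardize_concatenate()].
#' @return Named list of per-recording pieces (`subject.session`).
#' @export
deconcatenate <- function(x, boundaries) {
  out <- lapply(seq_len(nrow(boundaries)), function(i) {
    idx <- (boundaries$start[i] + 1L):boundaries$end[i]
    if (is.null(dim(x))) x[idx] else x[idx, , drop = FALSE]
  })
  names(out) <- paste(boundaries$subject, boundaries$session, sep = ".")
  out
}

#' Pre-whitened principal-component reduction
#'
#' Projects the concatenated envelope matrix onto its top principal
#' components, scaled to unit variance (whitening on the retained subspace).
#' The basis is kept so state-level results can be mapped back to node space.
#'
#' @param X samples-by-nodes matrix (already standardized).
#' @param n_components number of components to retain (default 40, reduced
#'   with a warning when the rank is lower).
#' @return List with `Z` (samples-by-`n_components`, unit-variance columns),
#'   `basis` (nodes-by-`n_components` loadings), `sdev` (component SDs),
#'   `center` (column means removed before the SVD).
#' @export
prewhiten_pca <- function(X, n_components = 40L) {
  X <- as.matrix(X)
  n_components <- min(n_components, ncol(X), nrow(X) - 1L)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0, nv = min(ncol(X), n_components + 5L))
  sdev <- sv$d / sqrt(nrow(X) - 1)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (rank < n_components) {
    warning("rank ", rank, " < requested ", n_components, " components; reducing")
    n_components <- rank
  }
  V <- sv$v[, seq_len(n_components), drop = FALSE]
  s <- sdev[seq_len(n_components)]
  Z <- sweep(Xc %*% V, 2, s, "/")
  list(Z = Z, basis = V, sdev = s, center = ctr)
}
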