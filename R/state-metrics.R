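#' Temporal parameters of a decoded state path
#'
#' Per-state summary of one recording's state sequence, by run-length
#' encoding: `NO` (number of activation runs), `FO` (fraction of samples in
#' the state), `MLT` (mean activation-run length, seconds), `MIL` (mean
#' length of inactive gaps lying strictly between two activation runs,
#' seconds; leading/trailing inactivity is excluded). Unvisited states get
#' `NO = 0`, `FO = 0` and missing `MLT`/`MIL`; a state visited once has a
#' defined `MLT` but missing `MIL`.
#'
#' @param path integer state sequence of one recording (values `1..K`).
#' @param K number of states (default `max(path)`).
#' @param fs sampling rate in Hz.
#' @return data.frame with columns `state`, `NO`, `FO`, `MLT_s`, `MIL_s`.
#' @export
temporal_params <- function(path, K = max(path), fs) {
  stopifnot(length(path) > 0, fs > 0)
  r <- rle(as.integer(path))
  Tn <- length(path)
  out <- data.frame(state = seq_len(K), NO = 0L, FO = 0,
                    MLT_s = NA_real_, MIL_s = NA_real_)
  for (k in seq_len(K)) {
    on <- r$values == k
    runs <- r$lengths[on]
    out$NO[k] <- length(runs)
    out$FO[k] <- sum(runs) / Tn
    if (length(runs) > 0) out$MLT_s[k] <- mean(runs) / fs
    if (length(runs) >= 2) {
      # inactive gaps between consecutive visits: total samples between the
      # end of one activation run and the start of the next
      pos <- which(on)
      gaps <- vapply(seq_len(length(pos) - 1), function(i) {
        sum(r$lengths[(pos[i] + 1):(pos[i + 1] - 1)])
      }, 1.0)
      out$MIL_s[k] <- mean(gaps) / fs
    }
  }
  out
}

#' Temporal parameters per subject and session
#'
#' De-concatenates a decoded state sequence at the recording boundaries and
#' computes [temporal_params()] separately for each subject and session.
#'
#' @param state_seq a `"state_sequence"` from [viterbi_decode()] (with a
#'   boundary table).
#' @param fs sampling rate in Hz.
#' @return Long data.frame: `subject`, `session`, `state`, `NO`, `FO`,
#'   `MLT_s`, `MIL_s`.
#' @export
temporal_params_by_recording <- function(state_seq, fs) {
  stopifnot(inherits(state_seq, "state_sequence"))
  b <- state_seq$boundaries
  if (is.null(b)) stop("state sequence has no boundary table", call. = FALSE)
  pieces <- deconcatenate(state_seq$path, b)
  out <- lapply(seq_len(nrow(b)), function(i) {
    tp <- temporal_params(pieces[[i]], K = state_seq$K, fs = fs)
    tp$subject <- b$subject[i]
    tp$session <- b$session[i]
    tp
  })
  do.call(rbind, out)[, c("subject", "session", "state", "NO", "FO", "MLT_s", "MIL_s")]
}

#' State power maps by partial correlation
#'
#' Node-wise partial correlation between each state's activation indicator
#' and the concatenated node envelopes, controlling for the indicators of
#' the other states. Because the K indicators sum to one, one state is
#' dropped as reference from the control set (the last state, or `K - 1`
#' when mapping the last state itself), avoiding exact collinearity.
#'
#' @param state_seq a `"state_sequence"` (or integer path).
#' @param envelopes samples-by-nodes matrix of standardized node envelopes
#'   aligned with the path.
#' @param K number of states.
#' @return K-by-nodes matrix of partial correlations in `[-1, 1]`; constant
#'   envelope channels yield `NA` columns.
#' @export
state_power_maps <- function(state_seq, envelopes, K = NULL) {
  path <- if (inherits(state_seq, "state_sequence")) state_seq$path else as.integer(state_seq)
  if (is.null(K)) K <- if (inherits(state_seq, "state_sequence")) state_seq$K else max(path)
  E <- as.matrix(envelopes)
  if (nrow(E) != length(path)) stop("sample axes differ", call. = FALSE)
  ind <- matrix(0, length(path), K)
  ind[cbind(seq_along(path), path)] <- 1
  const <- apply(E, 2, stats::sd) == 0
  maps <- matrix(NA_real_, K, ncol(E))
  for (k in seq_len(K)) {
    ref <- if (k == K) K - 1L else K
    ctrl <- setdiff(seq_len(K), c(k, ref))
    Z <- cbind(1, ind[, ctrl, drop = FALSE])
    qz <- qr(Z)
    rx <- qr.resid(qz, ind[, k])
    RE <- qr.resid(qz, E[, !const, drop = FALSE])
    if (stats::sd(rx) == 0) next
    maps[k, !const] <- drop(stats::cor(rx, RE))
  }
  maps
}

#' Extract a state network from a power map
#'
#' The state network of an HMM state is the node subset where the absolute
#' power-map value reaches `fraction` of its maximum absolute value
#' (default 60%). Scale-invariant: the map and any nonzero multiple give the
#' same node set.
#'
#' @param map numeric vector of node-wise power-map values (NAs allowed).
#' @param fraction threshold fraction of the maximum absolute value.
#' @return Object of class `"state_network"`: list with `nodes` (integer
#'   indices), `fraction`, `map_max`.
#' @export
extract_state_network <- function(map, fraction = 0.60) {
  if (all(is.na(map))) stop("all map values missing", call. = FALSE)
  m <- max(abs(map), na.rm = TRUE)
  nodes <- which(!is.na(map) & abs(map) >= fraction * m)
  structure(list(nodes = nodes, fraction = fraction, map_max = m),
            class = "state_network")
}
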