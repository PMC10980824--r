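#' Score the presses of one finger-tapping block
#'
#' Marks each press correct or incorrect against the cyclic 5-element target
#' sequence 4-1-3-2-4. The expected position advances with every press; after
#' a mismatch the expectation resynchronizes to the best local alignment
#' within one cycle, chosen by a one-press lookahead: a plain substitution
#' (advance by one) is preferred unless treating the wrong key as a skip to
#' its next occurrence in the cycle makes the following press match.
#'
#' @param keys integer vector of pressed keys (1..4), in press order.
#' @return Logical vector, `TRUE` where the press is correct.
#' @export
score_presses <- function(keys) {
  seq5 <- c(4L, 1L, 3L, 2L, 4L)
  n <- length(keys)
  ok <- logical(n)
  pos <- 1L  # index into seq5 of the next expected element
  for (i in seq_len(n)) {
    if (keys[i] == seq5[pos]) {
      ok[i] <- TRUE
      pos <- pos %% 5L + 1L
    } else {
      # candidate resync: earliest occurrence of the pressed key ahead in the
      # cycle (skip hypothesis) vs plain substitution (advance by one)
      sub_pos <- pos %% 5L + 1L
      skip_pos <- sub_pos
      for (off in 1:4) {
        p <- (pos - 1L + off) %% 5L + 1L
        if (seq5[p] == keys[i]) { skip_pos <- p %% 5L + 1L; break }
      }
      pos <- sub_pos
      if (skip_pos != sub_pos && i < n &&
          keys[i + 1L] == seq5[skip_pos] && keys[i + 1L] != seq5[sub_pos])
        pos <- skip_pos
    }
  }
  ok
}

#' Global Performance Index of one block
#'
#' Block-level motor performance combining speed and accuracy:
#' `GPI = (correct presses per second) * (n_correct / n_presses)`, and 0 for
#' an empty block. Strictly increasing in the number of correct presses at
#' fixed press count and duration, strictly decreasing in duration at fixed
#' counts. The scoring rule is deliberately isolated here so an alternative
#' speed-accuracy formula can be dropped in.
#'
#' @param events data.frame with columns `t_ms` and `key` (one block), or
#'   `NULL` when counts are given directly.
#' @param duration block duration in seconds.
#' @param n_presses,n_correct optional explicit counts, bypassing `events`.
#' @return The GPI score (1/s units), with attributes `n_presses` and
#'   `n_correct`.
#' @export
gpi <- function(events = NULL, duration = 30, n_presses = NULL, n_correct = NULL) {
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (is.null(n_presses)) {
    stopifnot(is.data.frame(events))
    if (nrow(events) > 0 && any(events$t_ms < 0))
      stop("negative timestamps", call. = FALSE)
    n_presses <- nrow(events)
    n_correct <- if (n_presses > 0) sum(score_presses(events$key)) else 0L
  }
  stopifnot(n_correct >= 0, n_correct <= n_presses)
  g <- if (n_presses == 0) 0 else (n_correct / duration) * (n_correct / n_presses)
  structure(g, n_presses = n_presses, n_correct = n_correct)
}

#' Best Motor Performance
#'
#' Mean of the two highest GPI scores among the learning blocks.
#'
#' @param learning_gpis numeric vector of learning-block GPI scores (>= 2).
#' @return Scalar BMP.
#' @export
best_motor_performance <- function(learning_gpis) {
  if (length(learning_gpis) < 2) stop("need >= 2 learning blocks", call. = FALSE)
  mean(sort(learning_gpis, decreasing = TRUE)[1:2])
}

#' Learning Index
#'
#' Percent change in performance from baseline to Best Motor Performance,
#' `100 * (BMP - baseline) / baseline`, with baseline the mean GPI of
#' learning blocks 2 and 3 (block 1 is excluded as task discovery).
#'
#' @param learning_gpis GPI scores of the learning blocks, in block order.
#' @return Percent LI, or `NA` with a warning when the baseline is not
#'   positive.
#' @export
learning_index <- function(learning_gpis) {
  if (length(learning_gpis) < 3) stop("need >= 3 learning blocks", call. = FALSE)
  baseline <- mean(learning_gpis[2:3])
  if (!is.finite(baseline) || baseline <= 0) {
    warning("baseline GPI <= 0; learning index undefined")
    return(NA_real_)
  }
  bmp <- best_motor_performance(learning_gpis)
  100 * (bmp - baseline) / baseline
}

#' Offline change in performance
#'
#' Change from the Best Motor Performance to the best GPI score of one
#' post-learning test window (two blocks): `max(test GPIs) - BMP`.
#'
#' @param bmp the Best Motor Performance score.
#' @param test_gpis GPI scores of the test window.
#' @return Signed score difference; `NA` when the window is missing/empty.
#' @export
offline_change <- function(bmp, test_gpis) {
  if (length(test_gpis) == 0 || all(is.na(test_gpis))) return(NA_real_)
  max(test_gpis, na.rm = TRUE) - bmp
}

#' Within-subject Z-normalisation of block scores
#'
#' Standardizes every block score of a subject by the mean and SD of that
#' subject's learning blocks, removing additive and multiplicative
#' between-group baseline offsets before group statistics.
#'
#' @param blocks data.frame with columns `subject`, `block`, `gpi`.
#' @param learning_blocks integer vector of block indices defining the
#'   normalisation population (default `1:20`).
#' @return The input with a `z` column appended; a zero learning-block SD
#'   yields `NA` z-scores for that subject, with a warning.
#' @export
z_normalise <- function(blocks, learning_blocks = 1:20) {
  stopifnot(all(c("subject", "block", "gpi") %in% names(blocks)))
  blocks$z <- NA_real_
  for (s in unique(blocks$subject)) {
    i <- blocks$subject == s
    learn <- blocks$gpi[i & blocks$block %in% learning_blocks]
    if (length(learn) < 2) stop("need >= 2 learning blocks per subject", call. = FALSE)
    mu <- mean(learn); sd_ <- stats::sd(learn)
    if (!is.finite(sd_) || sd_ == 0) {
      warning("zero learning-block SD for subject ", s, "; z undefined")
      next
    }
    blocks$z[i] <- (blocks$gpi[i] - mu) / sd_
  }
  blocks
}

#' Behavioural indices of one subject
#'
#' Scores a keypress stream (26 blocks: 20 learning, then 3 test windows of
#' 2 blocks each) into per-block GPI and the derived indices: BMP, LI and the
#' offline change per window.
#'
#' @param events data.frame with columns `block`, `t_ms`, `key`.
#' @param duration block duration in seconds.
#' @param n_learning number of learning blocks (default 20).
#' @return List with `blocks` (data.frame `block`, `n_presses`, `n_correct`,
#'   `gpi`) and `indices` (one-row data.frame `bmp`, `li`, `offline_T1..T3`).
#' @export
behaviour_indices <- function(events, duration = 30, n_learning = 20L) {
  stopifnot(all(c("block", "t_ms", "key") %in% names(events)))
  ids <- sort(unique(events$block))
  per <- lapply(ids, function(b) {
    g <- gpi(events[events$block == b, , drop = FALSE], duration = duration)
    data.frame(block = b, n_presses = attr(g, "n_presses"),
               n_correct = attr(g, "n_correct"), gpi = as.numeric(g))
  })
  tab <- do.call(rbind, per)
  learn <- tab$gpi[tab$block <= n_learning]
  bmp <- best_motor_performance(learn)
  li <- learning_index(learn)
  off <- vapply(1:3, function(w) {
    win <- tab$gpi[tab$block %in% (n_learning + 2 * w - 1:0)]
    offline_change(bmp, win)
  }, 1.0)
  list(blocks = tab,
       indices = data.frame(bmp = bmp, li = li, offline_T1 = off[1],
                            offline_T2 = off[2], offline_T3 = off[3]))
}
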