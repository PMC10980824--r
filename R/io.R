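# Plain-text readers/writers for the pipeline's interchange formats:
# envelope datasets as wide TSV, keypress streams and tables as CSV,
# models and results as JSON.

#' Write / read an envelope dataset as wide TSV
#'
#' One file per dataset: columns `subject`, `session`, `sample`, then one
#' column per node. Sampling rate and band are carried in a `# fs=... band=...`
#' header comment.
#'
#' @param dataset an `"envelope_dataset"`.
#' @param path output TSV path.
#' @export
write_envelope_tsv <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g band=%g-%g", dataset$fs,
                     dataset$band[1], dataset$band[2]), con)
  n_nodes <- nrow(dataset$data[[1]][[1]])
  header <- c("subject", "session", "sample", sprintf("node%03d", seq_len(n_nodes)))
  writeLines(paste(header, collapse = "\t"), con)
  for (s in seq_along(dataset$data)) for (j in seq_along(dataset$data[[s]])) {
    E <- t(dataset$data[[s]][[j]])
    block <- cbind(dataset$subjects[s], dataset$sessions[j],
                   seq_len(nrow(E)), format(E, digits = 8, trim = TRUE))
    utils::write.table(block, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_envelope_tsv
#' @param path TSV path written by [write_envelope_tsv()].
#' @return An `"envelope_dataset"`.
#' @export
read_envelope_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("fs=([0-9.]+) band=([0-9.]+)-([0-9.]+)", hdr))[[1]]
  tab <- utils::read.delim(path, skip = 1, sep = "\t", stringsAsFactors = FALSE)
  subjects <- unique(tab$subject)
  sessions <- unique(tab$session)
  node_cols <- grep("^node", names(tab))
  data <- lapply(subjects, function(s) {
    lapply(sessions, function(j) {
      sub <- tab[tab$subject == s & tab$session == j, , drop = FALSE]
      t(as.matrix(sub[order(sub$sample), node_cols, drop = FALSE]))
    })
  })
  structure(list(subjects = subjects, sessions = sessions,
                 fs = as.numeric(m[2]),
                 band = c(as.numeric(m[3]), as.numeric(m[4])), data = data),
            class = "envelope_dataset")
}

#' Serialize a fitted envelope HMM to JSON
#'
#' @param model an [env_hmm()] fit.
#' @param path output JSON path.
#' @export
write_hmm_json <- function(model, path) {
  obj <- list(K = model$K, d = model$d, pi = model$pi, A = model$A,
              means = model$means, covariances = model$covariances,
              loglik = model$loglik, score = model$score,
              restart_index = model$restart_index, cov_type = model$cov_type,
              seed = model$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_hmm_json
#' @return An `"env_hmm"` object (without the fitting call/boundaries).
#' @export
read_hmm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$A <- matrix(unlist(obj$A), obj$K, obj$K)
  obj$means <- matrix(unlist(obj$means), obj$K, obj$d)
  cov_in <- obj$covariances
  obj$covariances <- if (is.array(cov_in) && length(dim(cov_in)) == 3) {
    lapply(seq_len(obj$K), function(k) matrix(cov_in[k, , ], obj$d, obj$d))
  } else {
    lapply(cov_in, function(m) matrix(unlist(m), obj$d, obj$d))
  }
  obj$n_samples <- NA_integer_
  obj$boundaries <- NULL
  obj$n_restarts <- NA_integer_
  obj$converged <- NA
  obj$n_iter <- NA_integer_
  class(obj) <- "env_hmm"
  obj
}

#' Write a connectome set as a flat CSV edge list
#'
#' Columns: `subject`, `session`, `node_i`, `node_j`, `r` (lower triangle).
#'
#' @param matrices named list (subject.session) of symmetric matrices.
#' @param path output CSV path.
#' @export
write_connectome_csv <- function(matrices, path) {
  n <- nrow(matrices[[1]])
  idx <- .edge_index(n)
  rows <- lapply(names(matrices), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    data.frame(subject = parts[1], session = parts[2],
               node_i = idx[, 1], node_j = idx[, 2],
               r = .vec_lower(matrices[[nm]]))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
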