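#' Configuration of a full pipeline run
#'
#' Collects every stage's settings with defaults at the analysis' canonical
#' values: 8 HMM states with 10 restarts, envelope downsampling to 40 Hz
#' (100-ms windows every 25 ms), 40 principal components, NBS threshold
#' t = 3.5 with 5000 permutations, state-network fraction 0.60, and a
#' Bonferroni family of 21 for the state temporal parameters. The seed is
#' mandatory: every stochastic stage derives its stream from it.
#'
#' @param sim a [sim_config()] describing the synthetic dataset.
#' @param seed master seed (required, integer).
#' @param n_states,n_restarts,hmm_tol,hmm_max_iter HMM settings.
#' @param n_components PCA dimension (capped at the node count).
#' @param nbs_threshold,nbs_n_perm NBS settings.
#' @param network_fraction state-network extraction threshold.
#' @param smooth_s slow-envelope smoothing window, seconds.
#' @param ftt_mean_rate,ftt_error_rate finger-tapping generator settings.
#' @return A `"run_config"` list with a reproducible `hash`.
#' @export
run_config <- function(sim = sim_config(), seed = sim$seed,
                       n_states = 8L, n_restarts = 10L,
                       hmm_tol = 1e-6, hmm_max_iter = 500L,
                       n_components = 40L,
                       nbs_threshold = 3.5, nbs_n_perm = 5000L,
                       network_fraction = 0.60,
                       smooth_s = 1.0,
                       ftt_mean_rate = 3, ftt_error_rate = 0.05) {
  if (is.null(seed) || is.na(seed))
    stop("a seed is required for a pipeline run", call. = FALSE)
  cfg <- list(sim = sim, seed = as.integer(seed), n_states = as.integer(n_states),
              n_restarts = as.integer(n_restarts), hmm_tol = hmm_tol,
              hmm_max_iter = as.integer(hmm_max_iter),
              n_components = as.integer(n_components),
              nbs_threshold = nbs_threshold, nbs_n_perm = as.integer(nbs_n_perm),
              network_fraction = network_fraction, smooth_s = smooth_s,
              ftt_mean_rate = ftt_mean_rate, ftt_error_rate = ftt_error_rate)
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param cfg a configuration list (hash field ignored).
#' @return Hex md5 of the canonical JSON serialization.
#' @export
config_hash <- function(cfg) {
  cfg$hash <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, digits = NA, auto_unbox = TRUE, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full multiscale analysis on a synthetic dataset
#'
#' Executes the stages in dependency order: simulate envelopes and keypress
#' streams; behavioural indices; standardize/concatenate and PCA-reduce;
#' fit the envelope HMM and Viterbi-decode; temporal parameters, power maps
#' and state networks; envelope-correlation connectomes and node power;
#' NBS contrast (first vs second session) across subjects; state-network
#' mean connectivity strength and its Spearman correlation with behaviour.
#' Every output table is written under `out_dir` with the config hash and
#' seed in a sidecar `run_info.json`; a rerun with an identical config is
#' bit-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing and returns results only.
#' @param verbose log stage progress with timestamps.
#' @return Invisible list with the per-stage results: `behaviour`, `conc`,
#'   `pca`, `model`, `states`, `temporal`, `power_maps`, `networks`,
#'   `connectomes`, `strength`, `nbs`, `stats`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_ <- function(...) if (verbose)
    message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "), sprintf(...))
  sim <- config$sim

  log_("stage simulate: %d subjects x %d sessions x %d nodes",
       sim$n_subjects, sim$n_sessions, sim$n_nodes)
  gen <- simulate_envelope_dataset(sim)

  log_("stage behaviour")
  beh <- lapply(seq_len(sim$n_subjects), function(s) {
    ev <- simulate_ftt_blocks(mean_rate = config$ftt_mean_rate,
                              error_rate = config$ftt_error_rate,
                              seed = stream_seed(config$seed, 900000L + s))
    behaviour_indices(ev)
  })
  blocks <- do.call(rbind, lapply(seq_along(beh), function(s)
    cbind(subject = gen$dataset$subjects[s], beh[[s]]$blocks)))
  blocks <- z_normalise(blocks)
  indices <- do.call(rbind, lapply(seq_along(beh), function(s)
    cbind(subject = gen$dataset$subjects[s], beh[[s]]$indices)))

  log_("stage envelope: standardize + concatenate + PCA")
  conc <- standardize_concatenate(gen$dataset)
  pca <- prewhiten_pca(conc$X, n_components = min(config$n_components, sim$n_nodes))

  log_("stage hmm: K=%d, %d restarts", config$n_states, config$n_restarts)
  model <- env_hmm(pca$Z, K = config$n_states, n_restarts = config$n_restarts,
                   seed = stream_seed(config$seed, 100000L),
                   boundaries = conc$boundaries, tol = config$hmm_tol,
                   max_iter = config$hmm_max_iter)
  states <- viterbi_decode(model, pca$Z)

  log_("stage states: temporal parameters, power maps, networks")
  temporal <- temporal_params_by_recording(states, fs = conc$fs)
  maps <- state_power_maps(states, conc$X)
  networks <- lapply(seq_len(config$n_states), function(k)
    extract_state_network(maps[k, ], fraction = config$network_fraction))

  log_("stage connectivity: envelope correlation per recording")
  env_rec <- deconcatenate(conc$X, conc$boundaries)
  connectomes <- lapply(env_rec, envelope_correlation, fs = conc$fs,
                        smooth_s = config$smooth_s)
  power <- lapply(env_rec, node_power)

  log_("stage nbs: session 1 vs 2 paired contrast")
  b <- conc$boundaries
  subj <- unique(b$subject)
  ses <- unique(b$session)
  nbs <- NULL
  if (length(ses) >= 2 && length(subj) >= 3) {
    m1 <- connectomes[paste(subj, ses[1], sep = ".")]
    m2 <- connectomes[paste(subj, ses[2], sep = ".")]
    nbs <- nbs_fwer(m1, m2, threshold = config$nbs_threshold,
                    n_perm = config$nbs_n_perm,
                    seed = stream_seed(config$seed, 200000L))
  }

  log_("stage stats: state-network strength vs behaviour")
  strength <- do.call(rbind, lapply(seq_len(config$n_states), function(k) {
    if (length(networks[[k]]$nodes) < 2) return(NULL)
    data.frame(state = k, recording = names(connectomes),
               strength = vapply(connectomes, mean_connectivity_strength,
                                 1.0, state_network = networks[[k]]))
  }))
  stats_tab <- NULL
  if (!is.null(strength) && length(subj) >= 5) {
    rows <- lapply(unique(strength$state), function(k) {
      s1 <- strength[strength$state == k &
                       strength$recording %in% paste(subj, ses[1], sep = "."), ]
      v <- s1$strength[match(paste(indices$subject, ses[1], sep = "."), s1$recording)]
      cbind(state = k, spearman_ci(v, indices$bmp))
    })
    stats_tab <- do.call(rbind, rows)
    stats_tab$p_bonferroni <- bonferroni(
      stats_tab$p, bonferroni_factor(config$n_states, 4L))
  }

  res <- list(behaviour = list(blocks = blocks, indices = indices),
              conc = conc, pca = pca, model = model, states = states,
              temporal = temporal, power_maps = maps, networks = networks,
              connectomes = connectomes, node_power = power,
              strength = strength, nbs = nbs, stats = stats_tab,
              config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    info <- list(config_hash = config$hash, seed = config$seed,
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 schema_version = "1.0")
    jsonlite::write_json(info, file.path(out_dir, "run_info.json"),
                         auto_unbox = TRUE)
    utils::write.csv(blocks, file.path(out_dir, "behaviour_blocks.csv"),
                     row.names = FALSE)
    utils::write.csv(indices, file.path(out_dir, "behaviour_indices.csv"),
                     row.names = FALSE)
    utils::write.csv(temporal, file.path(out_dir, "temporal_params.csv"),
                     row.names = FALSE)
    utils::write.table(t(maps), file.path(out_dir, "state_power_maps.tsv"),
                       sep = "\t", row.names = FALSE,
                       col.names = sprintf("state%d", seq_len(config$n_states)))
    jsonlite::write_json(lapply(networks, `[[`, "nodes"),
                         file.path(out_dir, "state_networks.json"))
    write_hmm_json(model, file.path(out_dir, "hmm_model.json"))
    write_connectome_csv(res$connectomes, file.path(out_dir, "connectomes.csv"))
    if (!is.null(strength))
      utils::write.csv(strength, file.path(out_dir, "network_strength.csv"),
                       row.names = FALSE)
    if (!is.null(stats_tab))
      utils::write.csv(stats_tab, file.path(out_dir, "strength_behaviour_stats.csv"),
                       row.names = FALSE)
    if (!is.null(nbs))
      jsonlite::write_json(
        list(threshold = nbs$threshold, n_perm = nbs$n_perm, seed = nbs$seed,
             components = lapply(nbs$components, function(cp)
               list(size = cp$size, nodes = cp$nodes, p_fwer = cp$p_fwer,
                    edges = cp$edges))),
        file.path(out_dir, "nbs_result.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(res)
}
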