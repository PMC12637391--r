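# Campaign orchestration: trials, decoupled-run scheduling, averaging,
# feature extraction and report export.
#
# One campaign mirrors the study protocol: n_trials trials, each with its
# own seed for the background noise and the thalamic fiber selection; two
# stimuli per trial with the response to the second extracted; per trial,
# one connected run plus one decoupled run per decoupling target (the
# thalamus-silenced run is the THAL target).  All traces are band-passed,
# averaged across trials, and decomposed into presynaptic, pathway and
# postsynaptic contributions.

#' Campaign specification
#'
#' @param config circuit configuration (see [default_circuit_config()])
#' @param n_trials number of trials (study protocol: 10)
#' @param base_seed integer; trial t uses seed `base_seed + t - 1`
#' @param targets populations whose presynaptic contribution is isolated
#'   (include `"THAL"` for the thalamic contribution)
#' @param post_populations postsynaptic populations for pathway restriction
#'   and postsynaptic contributions
#' @param stimulus stimulus_spec, or NULL to build the default spec with
#'   `n_fibers` matching the circuit's thalamic population
#' @param electrode electrode_spec for the EEG
#' @param window stimulus-relative analysis window, ms
#' @param filter `c(order, low_hz, high_hz)`
#' @param dt integration step, ms
#' @param record_every report interval in steps
#' @return list of class `campaign_spec`
#' @export
campaign_spec <- function(config, n_trials = 10L, base_seed = 1L,
                          targets = c("THAL", "L5I", "L5PeriTC", "L5E", "L6E"),
                          post_populations = c("L23E", "L4E", "L5E", "L6E"),
                          stimulus = NULL,
                          electrode = electrode_spec(c(0, 0, -1500)),
                          window = c(-10, 100), filter = c(2, 1, 500),
                          dt = 0.025, record_every = 4L) {
  stopifnot(n_trials >= 1L)
  structure(list(config = config, n_trials = as.integer(n_trials),
                 base_seed = as.integer(base_seed), targets = targets,
                 post_populations = post_populations, stimulus = stimulus,
                 electrode = electrode, window = window, filter = filter,
                 dt = dt, record_every = as.integer(record_every)),
            class = "campaign_spec")
}

#' Run a simulation campaign
#'
#' @param spec campaign_spec
#' @param circuit optional prebuilt circuit_model (else built from
#'   `spec$config` with `spec$base_seed`)
#' @param verbose print per-stage progress
#' @return list of class `campaign_result`: averaged SEP, contribution_set,
#'   sep_features, linear-sum validation, per-trial seeds and manifest data
#' @export
run_campaign <- function(spec, circuit = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "campaign_spec"))
  if (is.null(circuit)) circuit <- build_circuit(spec$config, spec$base_seed)
  for (tg in spec$targets) {
    if (!tg %in% population_names(circuit)) {
      stop("decoupling target does not exist in the circuit: ", tg)
    }
  }
  compiled <- compile_circuit(circuit)
  weights <- point_electrode_weights(compartment_centers(compiled),
                                     spec$electrode)
  weights$comp_neuron <- compiled$comps$neuron
  fiber_ids <- population_ids(circuit, "THAL")
  if (is.null(spec$stimulus)) {
    spec$stimulus <- stimulus_spec(n_fibers = length(fiber_ids))
  }
  onsets <- stimulus_onsets(spec$stimulus)
  t_sim <- max(onsets) + spec$window[2] + 10
  seeds <- spec$base_seed + seq_len(spec$n_trials) - 1L

  trial_net <- list()
  trial_pre <- list()
  trial_path <- list()
  n_sims <- 0L
  for (ti in seq_len(spec$n_trials)) {
    ts <- seeds[ti]
    if (verbose) message("trial ", ti, " (seed ", ts, ")")
    thal <- generate_thalamic_spikes(spec$stimulus, fiber_ids, seed = ts)
    con <- simulate_connected(compiled, thal, trial_seed = ts, t_sim = t_sim,
                              dt = spec$dt, record_every = spec$record_every)
    n_sims <- n_sims + 1L
    net_raw <- compute_signal(con$currents, weights)
    net <- postprocess_sep(net_raw, onsets, window = spec$window,
                           filter = spec$filter)
    trial_net[[ti]] <- net
    pre_t <- list(); path_t <- list()
    for (tg in spec$targets) {
      plan <- replay_plan(circuit, con$spikes, thal, exclude = tg)
      dec <- simulate_decoupled(compiled, plan, trial_seed = ts,
                                t_sim = t_sim, dt = spec$dt,
                                record_every = spec$record_every)
      n_sims <- n_sims + 1L
      dec_tr <- postprocess_sep(compute_signal(dec$currents, weights),
                                onsets, window = spec$window,
                                filter = spec$filter)
      pre_t[[tg]] <- presynaptic_contribution(net, dec_tr)
      for (pp in spec$post_populations) {
        path_t[[paste0(tg, "__", pp)]] <-
          pathway_contribution(net, dec_tr, pp, circuit)
      }
    }
    trial_pre[[ti]] <- pre_t
    trial_path[[ti]] <- path_t
  }

  total <- average_trials(trial_net)
  pre_avg <- lapply(stats::setNames(spec$targets, spec$targets), function(tg) {
    average_trials(lapply(trial_pre, `[[`, tg))
  })
  path_names <- names(trial_path[[1]])
  path_avg <- lapply(stats::setNames(path_names, path_names), function(nm) {
    average_trials(lapply(trial_path, `[[`, nm))
  })
  post_avg <- lapply(stats::setNames(spec$post_populations,
                                     spec$post_populations), function(pp) {
    postsynaptic_contribution(total, pp, circuit)
  })
  cs <- contribution_set(total, presynaptic = pre_avg, pathways = path_avg,
                         postsynaptic = post_avg)
  features <- sep_features(total, baseline_window = c(spec$window[1], 0))
  validation <- if (length(pre_avg)) validate_linear_sum(cs) else NULL

  structure(list(circuit = circuit, spec = spec, total = total,
                 contributions = cs, features = features,
                 validation = validation, trial_seeds = seeds,
                 n_simulations = n_sims), class = "campaign_result")
}

#' @export
print.campaign_result <- function(x, ...) {
  cat(sprintf("<campaign_result: %d trials, %d simulations, %d targets>\n",
              length(x$trial_seeds), x$n_simulations,
              length(x$contributions$presynaptic)))
  print(x$features)
  invisible(x)
}

trace_df <- function(trace) {
  if (is.matrix(trace$values)) {
    data.frame(time = trace$time, trace$values)
  } else {
    data.frame(time = trace$time, value = trace$values)
  }
}

write_csv_plain <- function(df, path) {
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = NA),
                     path, sep = ",", quote = FALSE, row.names = FALSE)
}

#' Export campaign reports
#'
#' Writes the averaged SEP, all contribution traces, a peak summary table,
#' the feature table and a JSON run manifest (configuration digest, trial
#' seeds, package version) to `dir`.  Re-export of the same results is
#' byte-identical.
#'
#' @param results campaign_result
#' @param dir output directory (created if needed)
#' @return invisible character vector of file paths
#' @export
export_reports <- function(results, dir) {
  stopifnot(inherits(results, "campaign_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "sep_total.csv")
  write_csv_plain(trace_df(results$total), p); paths <- c(paths, p)

  cs <- results$contributions
  for (kind in c("presynaptic", "pathways", "postsynaptic")) {
    lst <- cs[[kind]]
    if (!length(lst)) next
    df <- data.frame(time = results$total$time)
    for (nm in names(lst)) df[[nm]] <- lst[[nm]]$values
    p <- file.path(dir, paste0("contributions_", kind, ".csv"))
    write_csv_plain(df, p); paths <- c(paths, p)
  }

  summ <- do.call(rbind, lapply(names(cs$presynaptic), function(nm) {
    v <- cs$presynaptic[[nm]]$values
    data.frame(population = nm, peak = max(v), trough = min(v),
               peak_to_peak = max(v) - min(v))
  }))
  p <- file.path(dir, "summary.csv")
  write_csv_plain(summ, p); paths <- c(paths, p)

  feat <- results$features
  p <- file.path(dir, "features.csv")
  write_csv_plain(data.frame(feature = names(unclass(feat)),
                             value = unlist(unclass(feat))), p)
  paths <- c(paths, p)

  manifest <- list(
    package = "sepdecomp",
    version = as.character(utils::packageVersion("sepdecomp")),
    base_seed = results$spec$base_seed,
    trial_seeds = results$trial_seeds,
    n_trials = results$spec$n_trials,
    targets = results$spec$targets,
    config_digest = config_digest(results$spec$config),
    n_simulations = results$n_simulations,
    filter = results$spec$filter,
    window = results$spec$window)
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

# Cheap deterministic digest of a configuration (order-sensitive fold over
# the deparsed structure); identifies a config in the run manifest.
config_digest <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  h <- 0
  for (x in utf8ToInt(txt)) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}
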