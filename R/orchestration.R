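#' Default pipeline configuration
#'
#' All tunable parameters of an end-to-end run in one nested list; every
#' stochastic stage derives its own seed from the master `seed`. Can be
#' written to / read from YAML with [write_run_config()] /
#' [read_run_config()].
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @return a nested configuration list.
#' @export
default_run_config <- function(seed = 1, out_dir = "scloom_run") {
  list(
    seed = seed,
    out_dir = out_dir,
    population = list(n_sSC = 50, n_dSC = 50),
    protocol = list(n_trials = 100, isi = 3, grid_nrow = 5, grid_ncol = 5,
                    spacing = 15),
    circuit = list(tau_rec = 180, a = 1, w_min = 0, loom_dose = 8,
                   grid_nrow = 7, grid_ncol = 7, spacing = 15),
    analysis = list(alpha = 0.005, window = 5, habituation_i = 10,
                    repeat_trials = 10, repeat_isi = 2),
    decoding = list(sizes = c(5, 10, 30, 70, 150, 300), reps = 100,
                    folds = 4))
}

validate_run_config <- function(config) {
  needed <- c("seed", "out_dir", "population", "protocol", "circuit",
              "analysis", "decoding")
  missing <- setdiff(needed, names(config))
  if (length(missing)) {
    stop("run config is missing fields: ", paste(missing, collapse = ", "))
  }
  invisible(config)
}

#' @rdname default_run_config
#' @param config a configuration list.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

circuit_from_config <- function(cc) {
  circuit_config(grid = loom_grid(cc$grid_nrow, cc$grid_ncol, cc$spacing),
                 tau_rec = cc$tau_rec, a = cc$a, w_min = cc$w_min,
                 loom_dose = cc$loom_dose)
}

#' Run the full pipeline
#'
#' Protocols -> circuit-driven synthetic spikes -> trial tables -> single
#' neuron metrics -> population decoding, with every output written under
#' `config$out_dir` together with a manifest (config, stage seeds, content
#' hashes). Identical configurations produce byte-identical outputs.
#'
#' Stages: (1) a repeated-loom protocol scores per-neuron habituation;
#' (2) a random-loom protocol yields receptive-field sizes, latency
#' variability and the location/novelty decoding curves (with virtual
#' neuron augmentation).
#'
#' @param config a configuration list (see [default_run_config()]) or a
#'   YAML path.
#' @return (invisibly) list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name) message(sprintf("[scloom] %s (%.1f s elapsed)",
                                          name, proc.time()[["elapsed"]]))
  circuit <- circuit_from_config(config$circuit)
  pop <- make_population(config$population$n_sSC, config$population$n_dSC,
                         seed = derive_seed(config$seed, "population"),
                         circuit = circuit)
  paths <- list()

  stage("habituation run (repeated loom)")
  p_rep <- repeat_loom_protocol(n_trials = config$analysis$repeat_trials,
                                isi = config$analysis$repeat_isi)
  rec_rep <- generate_spikes(pop, p_rep,
                             seed = derive_seed(config$seed, "rep_spikes"))
  tt_rep <- build_trial_table(rec_rep, window = config$analysis$window)
  hab <- do.call(rbind, lapply(unique(tt_rep$neuron), function(id) {
    rows <- tt_rep[tt_rep$neuron == id, ]
    h <- habituation_index(rows$count, rows$mu[1],
                           i = config$analysis$habituation_i,
                           alpha = config$analysis$alpha)
    data.frame(neuron = id, layer = rows$layer[1],
               depth_um = rows$depth_um[1], index = h$index,
               included = h$included)
  }))
  paths$habituation <- file.path(config$out_dir, "habituation.csv")
  utils::write.csv(hab, paths$habituation, row.names = FALSE)

  stage("random-loom run")
  grid <- loom_grid(config$protocol$grid_nrow, config$protocol$grid_ncol,
                    config$protocol$spacing)
  p_rnd <- random_loom_protocol(config$protocol$n_trials,
                                config$protocol$isi, grid,
                                seed = derive_seed(config$seed, "protocol"))
  paths$protocol <- file.path(config$out_dir, "random_loom_protocol.json")
  write_protocol(p_rnd, paths$protocol)
  rec <- generate_spikes(pop, p_rnd,
                         seed = derive_seed(config$seed, "rnd_spikes"))
  paths$recording <- write_recording(rec, config$out_dir)
  tt <- build_trial_table(rec, window = config$analysis$window)
  paths$trial_table <- file.path(config$out_dir, "trial_table.csv")
  utils::write.csv(tt, paths$trial_table, row.names = FALSE)

  stage("single-neuron metrics")
  rf <- do.call(rbind, lapply(unique(tt$neuron), function(id) {
    rows <- tt[tt$neuron == id, ]
    est <- rf_size(rows$count, rows$mu, rows$x, rows$y,
                   spacing = config$protocol$spacing,
                   alpha = config$analysis$alpha)
    data.frame(neuron = id, layer = rows$layer[1],
               depth_um = rows$depth_um[1], size = est$size,
               delta = est$delta, included = est$included)
  }))
  paths$rf <- file.path(config$out_dir, "rf_size.csv")
  utils::write.csv(rf, paths$rf, row.names = FALSE)
  lat <- do.call(rbind, lapply(seq_len(nrow(pop)), function(j) {
    rows <- tt[tt$neuron == pop$id[j], ]
    ls <- latency_stats(rec$spikes[[j]], rows$onset, rows$duration,
                        rows$mu, alpha = config$analysis$alpha)
    data.frame(neuron = pop$id[j], layer = pop$layer[j],
               depth_um = pop$depth_um[j], latency_sd = ls$sd,
               n_trials_used = ls$n_trials_used, included = ls$included,
               reason = ls$reason)
  }))
  paths$latency <- file.path(config$out_dir, "latency.csv")
  utils::write.csv(lat, paths$latency, row.names = FALSE)

  stage("population decoding")
  curve <- NULL
  groups_present <- unique(pop$layer)
  if (length(setdiff(c("sSC", "dSC"), groups_present))) {
    warning("decoding skips absent group(s): ",
            paste(setdiff(c("sSC", "dSC"), groups_present), collapse = ", "))
  }
  ds <- decoding_dataset(tt, pop, grid)
  aug <- augment_population(ds)
  curve <- subsample_curve(aug, sizes = config$decoding$sizes,
                           reps = config$decoding$reps,
                           seed = derive_seed(config$seed, "decode"),
                           folds = config$decoding$folds)
  paths$decoding <- file.path(config$out_dir, "decoding_curve.csv")
  utils::write.csv(curve, paths$decoding, row.names = FALSE)
  summ <- list(
    n_neurons = nrow(pop), n_augmented = ncol(aug$X),
    chance_location = chance_level("location", ds$y_location),
    chance_novelty = chance_level("novelty", ds$y_novelty))
  paths$summary <- file.path(config$out_dir, "decoding_summary.json")
  jsonlite::write_json(summ, paths$summary, auto_unbox = TRUE, digits = NA)

  stage("manifest")
  files <- sort(unname(unlist(paths)))
  manifest <- list(
    config = config,
    seeds = list(population = derive_seed(config$seed, "population"),
                 rep_spikes = derive_seed(config$seed, "rep_spikes"),
                 protocol = derive_seed(config$seed, "protocol"),
                 rnd_spikes = derive_seed(config$seed, "rnd_spikes"),
                 decode = derive_seed(config$seed, "decode")),
    r_version = as.character(getRversion()),
    files = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }))
  man_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(population = pop, habituation = hab, rf = rf,
                 latency = lat, decoding = curve, summary = summ,
                 paths = c(paths, manifest = man_path)))
}

#' Write / read a population recording as plain text
#'
#' Two CSVs (`spikes.csv`: neuron_id, time_s; `neurons.csv`: the metadata
#' table) plus the protocol JSON. Spike times round-trip at 1 microsecond
#' resolution.
#'
#' @param recording a [generate_spikes()] recording.
#' @param dir output directory.
#' @return `write_recording` returns the vector of paths;
#'   `read_recording` returns a `population_recording`.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- data.frame(
    neuron_id = rep(recording$neurons$id, lengths(recording$spikes)),
    time_s = round(unlist(recording$spikes), 6))
  p_spikes <- file.path(dir, "spikes.csv")
  p_neurons <- file.path(dir, "neurons.csv")
  p_proto <- file.path(dir, "protocol.json")
  utils::write.csv(sp, p_spikes, row.names = FALSE)
  utils::write.csv(as.data.frame(recording$neurons), p_neurons,
                   row.names = FALSE)
  write_protocol(recording$protocol, p_proto)
  c(spikes = p_spikes, neurons = p_neurons, protocol = p_proto)
}

#' @rdname write_recording
#' @param spikes_csv,neurons_csv,protocol_json input paths.
#' @export
read_recording <- function(spikes_csv, neurons_csv, protocol_json) {
  sp <- utils::read.csv(spikes_csv, colClasses = c("character", "numeric"))
  if (nrow(sp) > 0 && (any(is.na(sp$time_s)) || any(sp$time_s < 0))) {
    bad <- which(is.na(sp$time_s) | sp$time_s < 0)
    stop("malformed spike rows at lines: ",
         paste(utils::head(bad + 1, 5), collapse = ", "))
  }
  neurons <- utils::read.csv(neurons_csv)
  protocol <- read_protocol(protocol_json)
  spikes <- lapply(neurons$id, function(id) {
    v <- sp$time_s[sp$neuron_id == id]
    if (is.unsorted(v)) {
      warning("unsorted spike times for ", id, "; sorted")
      v <- sort(v)
    }
    round(v, 6)
  })
  structure(list(spikes = spikes, neurons = neurons, protocol = protocol,
                 seed = NA_integer_,
                 duration = protocol_duration(protocol) + 1),
            class = "population_recording")
}
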