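.write_mtx <- function(w, path) {
  Matrix::writeMM(methods::as(Matrix::Matrix(w, sparse = TRUE),
                              "generalMatrix"), path)
  invisible(path)
}

.read_mtx <- function(path) as.matrix(Matrix::readMM(path))

#' Serialize a network to disk
#'
#' Weight blocks as Matrix Market files, cell parameter tables as CSV,
#' and a JSON manifest naming the blocks, the seeds actually used and
#' the resolved configuration with per-file checksums.
#'
#' @param network an `assoc_network`
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest list
#' @export
write_network <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (blk in names(network$weights)) {
    f <- file.path(dir, paste0("weights_", blk, ".mtx"))
    .write_mtx(network$weights[[blk]], f)
    files <- c(files, f)
  }
  for (blk in names(network$masks)) {
    f <- file.path(dir, paste0("mask_", blk, ".mtx"))
    .write_mtx(network$masks[[blk]] * 1, f)
    files <- c(files, f)
  }
  f <- file.path(dir, "mask_input.mtx")
  .write_mtx(network$ensemble$mask * 1, f)
  files <- c(files, f)
  f <- file.path(dir, "cells.csv")
  write.csv(network$cells, f, row.names = FALSE)
  files <- c(files, f)
  cfg <- network$config
  manifest <- list(
    format = "pairnet-network-v1",
    config = list(
      n_associative = cfg$n_associative,
      groups_per_stimulus = cfg$groups_per_stimulus,
      input_probability = cfg$input_probability,
      regime = cfg$regime, master_seed = cfg$master_seed,
      w0 = cfg$w0),
    seeds = as.list(network$seeds),
    goal_rates = network$goal_rates,
    blocks = basename(files),
    checksums = as.list(tools::md5sum(files)))
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a serialized network
#'
#' Rebuilds the network from a directory written by [write_network()]:
#' the configuration is re-resolved and the stored weights, masks and
#' cell tables replace the freshly sampled ones.
#'
#' @param dir directory containing `manifest.json`
#' @return an `assoc_network`
#' @export
read_network <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- manifest$config
  config <- network_config(
    n_associative = cfg$n_associative,
    groups_per_stimulus = cfg$groups_per_stimulus,
    input_probability = cfg$input_probability,
    regime = cfg$regime, master_seed = cfg$master_seed, w0 = cfg$w0)
  net <- build_associative_network(config)
  for (blk in names(net$weights)) {
    f <- file.path(dir, paste0("weights_", blk, ".mtx"))
    if (file.exists(f)) net$weights[[blk]] <- .read_mtx(f)
  }
  for (blk in names(net$masks)) {
    f <- file.path(dir, paste0("mask_", blk, ".mtx"))
    if (file.exists(f)) net$masks[[blk]] <- .read_mtx(f) > 0
  }
  net$ensemble$mask <- .read_mtx(file.path(dir, "mask_input.mtx")) > 0
  net$ensemble$weights <- net$weights$input
  net$cells <- read.csv(file.path(dir, "cells.csv"))
  net$goal_rates <- lapply(manifest$goal_rates, as.numeric)
  net
}

#' Write spike records to CSV
#'
#' @param spikes data.frame with `neuron` and `time_ms`
#' @param path output CSV path
#' @param trial,population optional constant columns
#' @return invisibly, the path
#' @export
write_spikes <- function(spikes, path, trial = 1L,
                         population = "associative") {
  out <- data.frame(trial = trial, population = population,
                    neuron_id = spikes$neuron,
                    time_ms = spikes$time_ms)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read spike records from CSV
#'
#' @param path CSV written by [write_spikes()]
#' @return data.frame with `trial`, `population`, `neuron_id`, `time_ms`
#' @export
read_spikes <- function(path) read.csv(path)

.config_schema <- c("n_associative", "groups_per_stimulus",
                    "input_probability", "regime", "master_seed", "w0",
                    "allow_nonstandard", "dt", "cue_ms", "relax_ms",
                    "sigma_v", "g_noise_assoc", "g_noise_decision",
                    "g_unit", "gref_gain")

#' Load a run configuration from YAML or JSON
#'
#' An empty file resolves to the all-defaults standard-regime
#' configuration. Unknown keys are rejected with a message naming the
#' offending key; grid values outside the stated sets are rejected
#' unless `allow_nonstandard: true` is set in the file.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file
#' @return a resolved [network_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .config_schema)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "),
         "; allowed keys: ", paste(.config_schema, collapse = ", "),
         call. = FALSE)
  kin_args <- raw[intersect(names(raw), c("g_unit", "gref_gain"))]
  int_args <- raw[intersect(names(raw), c("dt", "cue_ms", "relax_ms"))]
  names(int_args)[names(int_args) == "cue_ms"] <- "cue_ms"
  noise_args <- raw[intersect(names(raw),
                              c("sigma_v", "g_noise_assoc",
                                "g_noise_decision"))]
  net_args <- raw[intersect(names(raw),
                            c("n_associative", "groups_per_stimulus",
                              "input_probability", "regime",
                              "master_seed", "w0",
                              "allow_nonstandard"))]
  net_args$kinetics <- do.call(kinetics_config, kin_args)
  net_args$integration <- do.call(integration_config, int_args)
  net_args$noise <- do.call(noise_config, noise_args)
  do.call(network_config, net_args)
}

#' Write a resolved configuration
#'
#' @param config a [network_config()]
#' @param path output `.yaml` or `.json` path
#' @return invisibly, the path
#' @export
write_config <- function(config, path) {
  out <- list(
    n_associative = config$n_associative,
    groups_per_stimulus = config$groups_per_stimulus,
    input_probability = config$input_probability,
    regime = config$regime, master_seed = config$master_seed,
    w0 = config$w0,
    dt = config$integration$dt, cue_ms = config$integration$cue_ms,
    relax_ms = config$integration$relax_ms,
    sigma_v = config$noise$sigma_v,
    g_noise_assoc = config$noise$g_noise_assoc,
    g_noise_decision = config$noise$g_noise_decision,
    g_unit = config$kinetics$g_unit,
    gref_gain = config$kinetics$gref_gain)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' Write training outputs with a checksum manifest
#'
#' Writes the per-trial outcome log (CSV), the per-cell selectivity of
#' the final probe (CSV), network summary metrics (JSON) and a run
#' manifest with md5 checksums of every file.
#'
#' @param training a `pairnet_training` object
#' @param dir output directory
#' @return invisibly, the manifest list
#' @export
write_outputs <- function(training, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  f <- file.path(dir, "outcome_log.csv")
  write.csv(training$log, f, row.names = FALSE)
  files <- c(files, f)
  final <- training$probes[[length(training$probes)]]
  f <- file.path(dir, "selectivity.csv")
  write.csv(data.frame(cell = seq_along(final$selectivity$per_cell),
                       selectivity = final$selectivity$per_cell,
                       final$rates),
            f, row.names = FALSE)
  files <- c(files, f)
  sel_trace <- vapply(training$probes,
                      function(p) p$selectivity$mean, 0)
  ok <- training$log$correct[!is.na(training$log$correct)]
  metrics <- list(
    condition = training$condition, n_trials = training$n_trials,
    initial_selectivity = training$initial_selectivity,
    final_selectivity = training$final_selectivity,
    selectivity_by_probe = data.frame(trial = training$probe_trials,
                                      mean_selectivity = sel_trace),
    change = classify_change(training$initial_selectivity,
                             training$final_selectivity),
    fraction_correct = if (length(ok) > 0) mean(ok))
  f <- file.path(dir, "metrics.json")
  jsonlite::write_json(metrics, f, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  files <- c(files, f)
  manifest <- list(
    format = "pairnet-run-v1",
    condition = training$condition, n_trials = training$n_trials,
    seed = training$seed,
    files = basename(files),
    checksums = as.list(tools::md5sum(files)))
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Verify an output directory against its manifest
#'
#' @param dir directory containing `run_manifest.json` or
#'   `manifest.json`
#' @return TRUE if all checksums match; otherwise an error naming the
#'   mismatching file
#' @export
verify_outputs <- function(dir) {
  mf <- file.path(dir, "run_manifest.json")
  if (!file.exists(mf)) mf <- file.path(dir, "manifest.json")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  for (f in names(manifest$checksums)) {
    actual <- unname(tools::md5sum(file.path(dir, f)))
    if (is.na(actual) || actual != manifest$checksums[[f]])
      stop("checksum mismatch for ", f, call. = FALSE)
  }
  TRUE
}
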