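.pairs <- c("AB", "AD", "CB", "CD")

#' Correct response for a stimulus pair
#'
#' The biconditional (XOR) mapping: if both A and B are present, or
#' neither is, the correct response is Release; if exactly one of A and
#' B is present, it is Hold.
#'
#' @param pair one of `"AB"`, `"AD"`, `"CB"`, `"CD"` (vectorized)
#' @return `"Release"` or `"Hold"`
#' @export
correct_response <- function(pair) {
  if (length(pair) > 1) return(vapply(pair, correct_response, ""))
  pair <- paste(.normalize_pair(pair), collapse = "")
  if (!pair %in% .pairs)
    stop("unknown stimulus pair: ", pair, call. = FALSE)
  if (pair %in% c("AB", "CD")) "Release" else "Hold"
}

#' Balanced pseudorandom trial sequence
#'
#' Blocks of four trials, one per stimulus pair, shuffled within each
#' block, so every pair appears `n/4` times up to rounding and no long
#' runs of a single pair bias homeostasis.
#'
#' @param n_trials number of trials
#' @param seed integer seed
#' @return data.frame with columns `trial`, `pair`, `correct_response`
#' @export
make_trial_sequence <- function(n_trials, seed = 1L) {
  stopifnot(n_trials > 0)
  set.seed(seed)
  n_blocks <- ceiling(n_trials / 4)
  pairs <- unlist(lapply(seq_len(n_blocks),
                         function(b) sample(.pairs)))[seq_len(n_trials)]
  data.frame(trial = seq_len(n_trials), pair = pairs,
             correct_response = correct_response(pairs),
             stringsAsFactors = FALSE)
}

#' Train an associative network (and optionally the decision layer)
#'
#' The study's main loop. For each trial: generate Poisson inputs for
#' the trial's stimulus pair, run the associative layer with the
#' condition's plasticity hooks, optionally run the decision circuit on
#' the associative spikes and apply the dopamine reward update to its
#' afferents, apply homeostatic scaling, and log the outcome.
#' Selectivity probe blocks (frozen plasticity) run before training,
#' every `probe_every` trials, and after the last trial.
#'
#' Condition `"initial"` disables associative plasticity and, by
#' default, homeostasis; reward plasticity on the decision afferents
#' stays active whenever a decision network is supplied, which is how
#' untrained-network decision performance is measured.
#'
#' @param network an [build_associative_network()] result
#' @param condition plasticity condition (see [run_trial()])
#' @param n_trials number of training trials
#' @param decision optional [build_decision_network()] result; NULL
#'   skips the decision layer entirely
#' @param seed integer seed governing trial order, inputs and noise
#' @param probe_every probe-block period in trials (NA: only initial and
#'   final probes)
#' @param probe_reps probe trials per stimulus pair
#' @param homeostasis logical; defaults to TRUE except for the
#'   `"initial"` condition
#' @param reward_cfg a [reward_rule_config()]
#' @param dec_opts a [decision_opts()]
#' @param verbose print a line per probe block
#' @return object of class `pairnet_training`: the trained `network`
#'   and `decision`, the per-trial outcome `log`, the selectivity
#'   `probes`, and initial/final weight blocks
#' @export
train_network <- function(network, condition = "ltpi", n_trials = 200,
                          decision = NULL, seed = 1L,
                          probe_every = 40, probe_reps = 5,
                          homeostasis = NULL,
                          reward_cfg = reward_rule_config(),
                          dec_opts = decision_opts(),
                          verbose = FALSE) {
  stopifnot(inherits(network, "assoc_network"))
  hooks <- .condition_hooks(condition)
  if (is.null(homeostasis)) homeostasis <- hooks$condition != "initial"
  ms <- seed
  sequence <- make_trial_sequence(n_trials,
                                  seed = child_seed(ms, "trials"))
  w_initial <- network$weights
  aff_initial <- if (!is.null(decision)) decision$afferents

  probes <- list()
  probe_trials <- integer(0)
  do_probe <- function(label, at) {
    pr <- measure_selectivity(network, reps = probe_reps,
                              seed = .child_seed(ms, 5000L + at))
    probes[[length(probes) + 1]] <<- c(list(trial = at), pr)
    probe_trials <<- c(probe_trials, at)
    if (verbose)
      message(sprintf("[trial %4d] mean selectivity %.3f (%s)", at,
                      pr$selectivity$mean, label))
  }
  do_probe("initial", 0L)

  log <- data.frame(trial = sequence$trial, pair = sequence$pair,
                    correct_response = sequence$correct_response,
                    choice = NA_character_, correct = NA,
                    reward = NA_integer_,
                    pool_rate_release = NA_real_,
                    pool_rate_hold = NA_real_,
                    mean_rate_e = NA_real_,
                    stringsAsFactors = FALSE)

  for (k in seq_len(n_trials)) {
    trial_seed <- .child_seed(ms, 10L * k)
    inp <- generate_poisson_inputs(network$ensemble, sequence$pair[k],
                                   network$config$integration$cue_ms,
                                   seed = trial_seed)
    tr <- run_trial(network, inp, condition = hooks$condition,
                    seed = .child_seed(trial_seed, 2L))
    trial_start <- network$weights
    network <- tr$network
    log$mean_rate_e[k] <- mean(tr$rates_e)

    if (!is.null(decision)) {
      out <- run_decision(decision, tr$spikes,
                          integration = network$config$integration,
                          opts = dec_opts,
                          kinetics = network$config$kinetics,
                          seed = .child_seed(trial_seed, 3L))
      correct <- out$choice == sequence$correct_response[k]
      decision <- da_reward_update(decision, tr$rates_e, out$choice,
                                   correct, reward_cfg)
      log$choice[k] <- out$choice
      log$correct[k] <- correct
      log$reward[k] <- if (correct) 1L else -1L
      log$pool_rate_release[k] <- out$pool_rates[["Release"]]
      log$pool_rate_hold[k] <- out$pool_rates[["Hold"]]
    }
    if (homeostasis)
      network <- apply_homeostasis(network, tr$rates_e,
                                   trial_start = trial_start)
    if (!is.na(probe_every) && k %% probe_every == 0 && k < n_trials)
      do_probe("probe", k)
  }
  do_probe("final", n_trials)

  structure(list(
    network = network, decision = decision, condition = hooks$condition,
    n_trials = n_trials, log = log, probes = probes,
    probe_trials = probe_trials,
    initial_weights = w_initial, final_weights = network$weights,
    initial_afferents = aff_initial,
    initial_selectivity = probes[[1]]$selectivity$mean,
    final_selectivity = probes[[length(probes)]]$selectivity$mean,
    seed = seed), class = "pairnet_training")
}

#' @export
print.pairnet_training <- function(x, ...) {
  cat(sprintf("pairnet training: condition '%s', %d trials\n",
              x$condition, x$n_trials))
  cat(sprintf("  network-mean selectivity: %.3f -> %.3f (%s)\n",
              x$initial_selectivity, x$final_selectivity,
              classify_change(x$initial_selectivity,
                              x$final_selectivity)))
  if (!is.null(x$decision) && any(!is.na(x$log$correct))) {
    ok <- x$log$correct[!is.na(x$log$correct)]
    if (length(ok) >= 40) print(performance_bins(ok))
    else cat(sprintf("  fraction correct: %.2f\n", mean(ok)))
  }
  invisible(x)
}

#' @export
summary.pairnet_training <- function(object, ...) {
  sel <- vapply(object$probes, function(p) p$selectivity$mean, 0)
  out <- list(
    condition = object$condition, n_trials = object$n_trials,
    selectivity_by_probe = data.frame(trial = object$probe_trials,
                                      mean_selectivity = sel),
    change = classify_change(object$initial_selectivity,
                             object$final_selectivity),
    performance = if (!is.null(object$decision) &&
                      sum(!is.na(object$log$correct)) >= 40)
      performance_bins(object$log$correct[!is.na(object$log$correct)]))
  class(out) <- "summary.pairnet_training"
  out
}

#' @export
print.summary.pairnet_training <- function(x, ...) {
  cat(sprintf("Training summary (condition '%s', %d trials)\n",
              x$condition, x$n_trials))
  print(x$selectivity_by_probe, row.names = FALSE)
  cat(sprintf("selectivity change: %s\n", x$change))
  if (!is.null(x$performance)) print(x$performance)
  invisible(x)
}

#' @export
plot.pairnet_training <- function(x, ...) {
  sel <- vapply(x$probes, function(p) p$selectivity$mean, 0)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$probe_trials, sel, type = "b", xlab = "trial",
                 ylab = "network mean selectivity",
                 main = x$condition, ylim = c(0, 3), ...)
  ok <- x$log$correct[!is.na(x$log$correct)]
  if (length(ok) >= 40) {
    pb <- performance_bins(ok)
    graphics::plot(seq_along(pb$fraction_correct) * pb$bin,
                   100 * pb$fraction_correct, type = "b",
                   xlab = "trial", ylab = "% correct", ylim = c(0, 100))
    graphics::abline(h = c(50, 85), lty = 2)
  } else {
    s_final <- x$probes[[length(x$probes)]]$selectivity$per_cell
    graphics::hist(s_final, breaks = seq(0, 3, 0.25),
                   xlab = "stimulus-pair selectivity",
                   main = "final distribution")
  }
  invisible(x)
}

#' Run a set of conditions over grid cells
#'
#' Desk-scale grid runner: for each supplied network configuration and
#' plasticity condition, builds the network, trains it, and summarizes
#' initial/final network-mean selectivity and (if a decision layer is
#' requested) decision performance. The full study grid is
#' [grid_configs()] with 800-trial training; any subset runs the same
#' way at reduced trial counts.
#'
#' @param configs list of [network_config()] objects (e.g. a subset of
#'   [grid_configs()])
#' @param conditions character vector of plasticity conditions
#' @param n_trials trials per training run
#' @param decision logical; train a decision layer per run
#' @param seed integer master seed
#' @param ... further arguments to [train_network()]
#' @return data.frame of class `grid_result`, one row per (config,
#'   condition)
#' @export
run_condition_grid <- function(configs, conditions = "ltpi",
                               n_trials = 200, decision = FALSE,
                               seed = 1L, ...) {
  if (inherits(configs, "network_config")) configs <- list(configs)
  rows <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    for (cond in conditions) {
      net <- build_associative_network(cfg)
      dec <- if (decision) build_decision_network(cfg)
      fit <- train_network(net, condition = cond, n_trials = n_trials,
                           decision = dec,
                           seed = .child_seed(seed, 997L * ci), ...)
      ok <- fit$log$correct[!is.na(fit$log$correct)]
      rows[[length(rows) + 1]] <- data.frame(
        probability = cfg$input_probability,
        groups = cfg$groups_per_stimulus,
        condition = cond,
        initial_selectivity = fit$initial_selectivity,
        final_selectivity = fit$final_selectivity,
        change = classify_change(fit$initial_selectivity,
                                 fit$final_selectivity),
        performance = if (length(ok) > 0) mean(ok) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("grid_result", "data.frame")
  out
}
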