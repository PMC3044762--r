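#' Pair STDP weight change for a single spike-time difference
#'
#' Exponential window: potentiation for post-after-pre
#' (`delta_t = t_post - t_pre > 0`), depression for post-before-pre.
#' Simultaneous spikes (`delta_t = 0`) produce no change.
#'
#' @param delta_t spike-time difference t_post - t_pre, ms (vectorized)
#' @param config a [pair_stdp_config()]
#' @return weight change(s)
#' @export
pair_stdp_delta <- function(delta_t, config = pair_stdp_config()) {
  stopifnot(all(is.finite(delta_t)))
  dw <- numeric(length(delta_t))
  pos <- delta_t > 0
  neg <- delta_t < 0
  dw[pos] <- config$dw * config$a_plus * exp(-delta_t[pos] / config$tau_plus)
  dw[neg] <- -config$dw * config$a_minus *
    exp(-abs(delta_t[neg]) / config$tau_minus)
  dw
}

#' Initialize triplet STDP traces for one synapse
#'
#' Presynaptic fast (`r1`) and slow (`r2`) traces and postsynaptic fast
#' (`o1`) and slow (`o2`) traces, each decaying exponentially with its
#' configured time constant and incremented by 1 on the corresponding
#' spike.
#'
#' @param t0 initial time, ms
#' @return list of class `triplet_traces`
#' @export
triplet_traces <- function(t0 = 0) {
  structure(list(r1 = 0, r2 = 0, o1 = 0, o2 = 0, t = t0),
            class = "triplet_traces")
}

.decay_traces <- function(traces, t, config) {
  dt <- t - traces$t
  if (dt < 0) stop("stale traces: event precedes trace time", call. = FALSE)
  traces$r1 <- traces$r1 * exp(-dt / config$tau2_plus)
  traces$r2 <- traces$r2 * exp(-dt / config$tau_x)
  traces$o1 <- traces$o1 * exp(-dt / config$tau2_minus)
  traces$o2 <- traces$o2 * exp(-dt / config$tau_y)
  traces$t <- t
  traces
}

#' Triplet STDP update for one spike event
#'
#' All-to-all trace implementation: on a postsynaptic spike the synapse
#' potentiates in proportion to the fast presynaptic trace times
#' `(A2+ + A3+ * o2)`, where `o2` is the slow postsynaptic trace before
#' its own increment; on a presynaptic spike it depresses in proportion
#' to the fast postsynaptic trace times `(A2- + A3- * r2)` with `r2` the
#' slow presynaptic trace before increment. Traces are then incremented.
#'
#' @param event `"pre"` or `"post"`
#' @param t event time, ms (must not precede the trace time)
#' @param traces a [triplet_traces()] state
#' @param config a [triplet_stdp_config()]
#' @return list with elements `dw` and the updated `traces`
#' @export
triplet_update_on_spike <- function(event = c("pre", "post"), t, traces,
                                    config = triplet_stdp_config()) {
  event <- match.arg(event)
  traces <- .decay_traces(traces, t, config)
  if (event == "pre") {
    dw <- -config$dw * traces$o1 * (config$a2_minus +
                                      config$a3_minus * traces$r2)
    traces$r1 <- traces$r1 + 1
    traces$r2 <- traces$r2 + 1
  } else {
    dw <- config$dw * traces$r1 * (config$a2_plus +
                                     config$a3_plus * traces$o2)
    traces$o1 <- traces$o1 + 1
    traces$o2 <- traces$o2 + 1
  }
  list(dw = dw, traces = traces)
}

#' Closed-form expected triplet-STDP drift for independent Poisson trains
#'
#' For independent presynaptic and postsynaptic Poisson trains the
#' expected weight change per second under the all-to-all triplet rule is
#' `dw * r_pre * r_post * (tau2+ * (A2+ + A3+ * r_post * tau_y)
#'  - tau2- * (A2- + A3- * r_pre * tau_x))` with time constants in
#' seconds. Serves as the analytic oracle for the event-driven rule.
#'
#' @param r_pre,r_post rates, Hz (vectorized)
#' @param config a [triplet_stdp_config()]
#' @return expected drift, weight units per second
#' @export
expected_triplet_drift <- function(r_pre, r_post,
                                   config = triplet_stdp_config()) {
  stopifnot(all(r_pre >= 0), all(r_post >= 0))
  s <- 1e-3  # ms -> s
  config$dw * r_pre * r_post *
    (config$tau2_plus * s *
       (config$a2_plus + config$a3_plus * r_post * config$tau_y * s) -
     config$tau2_minus * s *
       (config$a2_minus + config$a3_minus * r_pre * config$tau_x * s))
}

#' Matched-rate crossover of the triplet rule
#'
#' The rate at which the expected drift for matched independent Poisson
#' pre/post trains changes sign from depression to potentiation.
#'
#' @param config a [triplet_stdp_config()]
#' @return rate, Hz
#' @export
triplet_crossover_rate <- function(config = triplet_stdp_config()) {
  s <- 1e-3
  num <- config$tau2_minus * config$a2_minus -
    config$tau2_plus * config$a2_plus
  den <- config$tau2_plus * config$a3_plus * config$tau_y * s -
    config$tau2_minus * config$a3_minus * config$tau_x * s
  num / den
}

#' Simulate triplet-STDP drift for independent Poisson trains
#'
#' Event-driven Monte-Carlo: draws independent Poisson pre and post
#' trains, applies [triplet_update_on_spike()] at every event (exact
#' exponential trace decay between events) and returns the accumulated
#' weight change.
#'
#' @param r_pre,r_post rates, Hz
#' @param duration_s train duration, seconds
#' @param seed integer seed
#' @param config a [triplet_stdp_config()]
#' @return total weight change over the train
#' @export
simulate_triplet_drift <- function(r_pre, r_post, duration_s = 100,
                                   seed = 1L,
                                   config = triplet_stdp_config()) {
  set.seed(seed)
  t_max <- duration_s * 1000
  n_pre <- rpois(1, r_pre * duration_s)
  n_post <- rpois(1, r_post * duration_s)
  times <- c(sort(runif(n_pre, 0, t_max)), sort(runif(n_post, 0, t_max)))
  kind <- c(rep("pre", n_pre), rep("post", n_post))
  o <- order(times)
  times <- times[o]; kind <- kind[o]
  tr <- triplet_traces()
  total <- 0
  for (k in seq_along(times)) {
    up <- triplet_update_on_spike(kind[k], times[k], tr, config)
    total <- total + up$dw
    tr <- up$traces
  }
  total
}

#' LTPi update for one inhibitory spike
#'
#' The inhibitory-to-excitatory synapse potentiates by `idw` if and only
#' if (i) no postsynaptic excitatory spike falls within the veto window
#' around the inhibitory spike and (ii) the postsynaptic voltage at the
#' inhibitory spike time is above the depolarization threshold. The
#' change is never negative.
#'
#' @param inh_spike_time inhibitory spike time, ms
#' @param post_spike_times postsynaptic excitatory spike times, ms
#' @param post_voltage postsynaptic voltage at the inhibitory spike, mV
#' @param config an [ltpi_config()]
#' @return weight change (0 or `idw`)
#' @export
ltpi_update <- function(inh_spike_time, post_spike_times, post_voltage,
                        config = ltpi_config()) {
  vetoed <- length(post_spike_times) > 0 &&
    any(abs(post_spike_times - inh_spike_time) <= config$veto_ms)
  if (!vetoed && post_voltage > config$v_threshold) config$idw else 0
}

#' Homeostatic multiplicative scaling for one postsynaptic cell
#'
#' Scales all synapses of one class onto a cell by a factor proportional
#' to the difference between the cell's cue-window mean rate and its goal
#' rate. Excitatory synapses scale by `1 + eps * (goal - rate)` and
#' inhibitory synapses onto an excitatory cell by `1 + eps * (rate -
#' goal)`, so both push the rate toward the goal. Resulting negative
#' weights are clamped to zero.
#'
#' @param weights synaptic weights onto the cell
#' @param mean_rate cue-window mean rate, Hz
#' @param goal_rate goal rate, Hz
#' @param epsilon rate constant
#' @param synapse_class `"excitatory"` or `"inhibitory"`
#' @return scaled weights
#' @export
homeostasis_step <- function(weights, mean_rate, goal_rate, epsilon,
                             synapse_class = c("excitatory",
                                               "inhibitory")) {
  synapse_class <- match.arg(synapse_class)
  diff <- if (synapse_class == "excitatory") goal_rate - mean_rate
          else mean_rate - goal_rate
  pmax(weights * (1 + epsilon * diff), 0)
}

#' Enforce per-trial and global weight bounds
#'
#' Clamps each weight to within 50% change of its trial-start value (the
#' per-trial cap) and to the global interval `[0, 20 * W0]`.
#'
#' @param weights proposed weights
#' @param trial_start_weights weights at the start of the trial
#' @param bounds a [weight_bounds()]
#' @return clamped weights
#' @export
enforce_bounds <- function(weights, trial_start_weights, bounds) {
  stopifnot(length(weights) == length(trial_start_weights))
  lo <- pmax(bounds$w_min, (1 - bounds$trial_cap) * trial_start_weights)
  hi <- pmin(bounds$w_max, (1 + bounds$trial_cap) * trial_start_weights)
  out <- pmin(pmax(weights, lo), hi)
  # a zero-start weight may still not leave the global interval
  pmin(pmax(out, bounds$w_min), bounds$w_max)
}
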