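#' NMDA magnesium-block gating factor
#'
#' Voltage dependence of the NMDA conductance,
#' `1 / (1 + [Mg] * exp(-0.062 V) / 3.57)` with `[Mg] = 1` mM:
#' monotonically increasing in V and approaching 1 at depolarized
#' voltages.
#'
#' @param v membrane voltage, mV (vectorized)
#' @param kinetics a [kinetics_config()]
#' @return gating factor in (0, 1]
#' @export
nmda_gating <- function(v, kinetics = kinetics_config()) {
  stopifnot(all(is.finite(v)))
  1 / (1 + kinetics$mg * exp(-kinetics$mg_slope * v) / kinetics$mg_scale)
}

.normalize_pair <- function(stimulus_pair) {
  if (length(stimulus_pair) == 1 && nchar(stimulus_pair) == 2)
    stimulus_pair <- strsplit(stimulus_pair, "")[[1]]
  stimulus_pair <- toupper(stimulus_pair)
  if (length(unique(stimulus_pair)) != 2 ||
      !all(stimulus_pair %in% c("A", "B", "C", "D")))
    stop("stimulus pair must be two distinct stimuli from {A, B, C, D}",
         call. = FALSE)
  # canonical order: A/C before B/D (pair names AB, AD, CB, CD)
  u <- unique(stimulus_pair)
  u[order(match(u, c("A", "C", "B", "D")))]
}

#' Generate Poisson input spikes for one stimulus pair
#'
#' Draws independent homogeneous Poisson spike trains for every input
#' group belonging to the two active stimuli, each at the ensemble's
#' per-group rate, over the cue duration. Groups of inactive stimuli
#' stay silent.
#'
#' @param ensemble an [build_input_ensemble()] result
#' @param stimulus_pair two stimuli, e.g. `c("A","B")` or `"AB"`
#' @param duration_ms cue duration, ms
#' @param seed integer seed
#' @return data.frame of class `spike_record` with columns `time_ms`
#'   (sorted) and `group` (1-based group index)
#' @export
generate_poisson_inputs <- function(ensemble, stimulus_pair,
                                    duration_ms = 1000, seed = 1L) {
  stopifnot(inherits(ensemble, "input_ensemble"))
  pair <- .normalize_pair(stimulus_pair)
  set.seed(seed)
  active <- which(ensemble$group_stimulus %in% pair)
  rate <- ensemble$rate_per_group
  times <- lapply(active, function(g) {
    n <- rpois(1, rate * duration_ms / 1000)
    sort(runif(n, 0, duration_ms))
  })
  out <- data.frame(
    time_ms = unlist(times),
    group = rep(active, vapply(times, length, 1L)))
  out <- out[order(out$time_ms), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pair") <- paste(pair, collapse = "")
  attr(out, "duration_ms") <- duration_ms
  class(out) <- c("spike_record", "data.frame")
  out
}

#' Advance a neuron population by one integration step
#'
#' Reference single-step Euler-Maruyama update used for analytic checks:
#' conductances decay exponentially and jump by weight-scaled increments
#' on incoming spikes; the voltage follows the leak, synaptic,
#' refractory and noise currents; a spike is emitted when the voltage
#' crosses the dynamic threshold, incrementing the refractory
#' conductance and the threshold. The compiled trial integrator
#' implements the same scheme.
#'
#' @param state list with vectors `v`, `g_ampa`, `g_nmda`, `g_gaba`,
#'   `g_ref`, `v_th` (one entry per neuron); see [init_state()]
#' @param params data.frame of cell parameters ([sample_cell_params()])
#' @param kinetics a [kinetics_config()]
#' @param noise a [noise_config()] or NULL for noise-free
#' @param dt time step, ms
#' @param incoming list with optional weight-sum vectors `exc` and `inh`
#'   (per postsynaptic neuron, in W0 units; scaled by `g_unit`)
#' @return list with the updated `state` and logical `spiked`
#' @export
step_population <- function(state, params, kinetics = kinetics_config(),
                            noise = NULL, dt = 0.02,
                            incoming = list()) {
  n <- length(state$v)
  k <- kinetics
  # exponential conductance decay, then incoming jumps
  state$g_ampa <- state$g_ampa * exp(-dt / k$tau_ampa)
  state$g_nmda <- state$g_nmda * exp(-dt / k$tau_nmda)
  state$g_gaba <- state$g_gaba * exp(-dt / k$tau_gaba)
  state$g_ref <- state$g_ref * exp(-dt / params$tau_reset)
  state$v_th <- params$V_th + (state$v_th - params$V_th) * exp(-dt / k$th_tau)
  if (!is.null(incoming$exc)) {
    state$g_ampa <- state$g_ampa + incoming$exc * k$g_unit
    state$g_nmda <- state$g_nmda + incoming$exc * k$g_unit * k$nmda_frac
  }
  if (!is.null(incoming$inh))
    state$g_gaba <- state$g_gaba + incoming$inh * k$g_unit

  g_a <- state$g_ampa
  g_g <- state$g_gaba
  if (!is.null(noise)) {
    g_a <- g_a + noise$g_noise_assoc * runif(n)
    g_g <- g_g + noise$g_noise_assoc * runif(n)
  }
  s <- nmda_gating(state$v, k)
  current <- params$g_L * (params$V_L - state$v) +
    g_a * (k$E_ampa - state$v) +
    state$g_nmda * s * (k$E_nmda - state$v) +
    g_g * (k$E_gaba - state$v) +
    state$g_ref * (k$V_gref - state$v)
  state$v <- state$v + dt * current / (params$g_L * params$tau_m)
  if (!is.null(noise) && noise$sigma_v > 0)
    state$v <- state$v + noise$sigma_v * sqrt(dt) * rnorm(n)
  if (any(!is.finite(state$v)))
    stop("integration fault: non-finite voltage", call. = FALSE)

  spiked <- state$v >= state$v_th
  if (any(spiked)) {
    state$g_ref[spiked] <- state$g_ref[spiked] +
      k$delta_gref * k$gref_gain
    state$v_th[spiked] <- pmin(state$v_th[spiked] + k$th_increment,
                               k$Vth_max)
    if (k$hard_reset) state$v[spiked] <- params$V_reset[spiked]
  }
  list(state = state, spiked = spiked)
}

#' Initialize neuron state at rest
#'
#' @param params cell parameter data.frame
#' @return state list for [step_population()]
#' @export
init_state <- function(params) {
  n <- nrow(params)
  list(v = params$V_L, g_ampa = numeric(n), g_nmda = numeric(n),
       g_gaba = numeric(n), g_ref = numeric(n), v_th = params$V_th)
}

.condition_hooks <- function(condition) {
  condition <- match.arg(condition,
    c("initial", "pair_stdp", "triplet_stdp", "ltpi",
      "ltpi+pair_stdp", "ltpi+triplet_stdp"))
  list(condition = condition,
       rule = if (grepl("triplet_stdp", condition)) 2L
              else if (grepl("pair_stdp", condition)) 1L else 0L,
       ltpi = grepl("ltpi", condition))
}

#' Simulate one trial of the associative layer
#'
#' Simulates the inter-trial relaxation (inputs off) followed by the 1 s
#' cue, with the chosen plasticity hooks active during the cue, and
#' returns the spikes, the per-neuron cue-window rates and the updated
#' plastic weight blocks. Weight changes respect the per-trial 50% cap
#' and the global `[0, 20 W0]` bounds at every update.
#'
#' @param network an [build_associative_network()] result
#' @param inputs input spikes from [generate_poisson_inputs()]
#' @param condition plasticity condition: `"initial"` (no associative
#'   plasticity), `"pair_stdp"`, `"triplet_stdp"`, `"ltpi"`,
#'   `"ltpi+pair_stdp"` or `"ltpi+triplet_stdp"`
#' @param seed integer seed for the noise
#' @param record_v integer neuron ids whose voltage traces to record
#' @param pair_cfg,triplet_cfg,ltpi_cfg plasticity configurations
#' @param apply_weights if TRUE (default) the returned network carries
#'   the updated weights
#' @return list of class `trial_result` with `spikes`, `rates`,
#'   `network` (with updated weights), `ltpi_applied` and `v_rec`
#' @export
run_trial <- function(network, inputs, condition = "initial", seed = 1L,
                      record_v = integer(0),
                      pair_cfg = pair_stdp_config(),
                      triplet_cfg = triplet_stdp_config(),
                      ltpi_cfg = NULL,
                      apply_weights = TRUE) {
  stopifnot(inherits(network, "assoc_network"))
  cfg <- network$config
  hooks <- .condition_hooks(condition)
  if (is.null(ltpi_cfg))
    ltpi_cfg <- ltpi_config(w_max = 20 * network$w0_eff)
  intg <- cfg$integration
  cells <- network$cells
  rulecfg <- if (hooks$rule == 1L) pair_cfg
             else if (hooks$rule == 2L) triplet_cfg
             else list()

  res <- .sim_trial_cpp(
    network$n_e, network$n_i,
    cells$V_L, cells$tau_m, cells$g_L, cells$V_th, cells$V_reset,
    cells$tau_reset,
    network$ensemble$mask, network$weights$input,
    network$masks$ee, network$weights$ee,
    network$masks$ie, network$weights$ie,
    network$masks$ii, network$weights$ii,
    network$masks$ei, network$weights$ei,
    inputs$time_ms, as.integer(inputs$group) - 1L,
    unclass(cfg$kinetics),
    list(sigma_v = cfg$noise$sigma_v,
         g_noise = cfg$noise$g_noise_assoc),
    intg$dt, intg$relax_ms, intg$cue_ms,
    hooks$rule, unclass(rulecfg), hooks$ltpi, unclass(ltpi_cfg),
    20 * network$w0_eff, cfg$bounds$trial_cap,
    as.integer(record_v), as.double(seed))

  if (apply_weights) {
    network$weights$input <- res$w_in
    network$weights$ee <- res$w_ee
    network$weights$ie <- res$w_ie
  }
  spikes <- data.frame(neuron = res$spike_id, time_ms = res$spike_t)
  structure(list(
    spikes = spikes, rates = res$rates,
    rates_e = res$rates[seq_len(network$n_e)],
    network = network, condition = condition,
    ltpi_candidates = res$ltpi_candidates,
    ltpi_applied = res$ltpi_applied,
    v_rec = res$v_rec,
    cue_ms = intg$cue_ms, relax_ms = intg$relax_ms),
    class = "trial_result")
}

#' Apply homeostatic scaling after a trial
#'
#' Multiplicative postsynaptic scaling of the plastic blocks toward each
#' excitatory cell's goal rate: input-to-E and E-to-E synapses scale
#' with rate constant `eps_e`, I-to-E synapses with `eps_ie` and
#' opposite sign, both pushing the cue rate toward the goal. Weights are
#' then re-clamped to the trial bounds.
#'
#' @param network an `assoc_network`
#' @param rates_e cue-window rates of the excitatory cells, Hz
#' @param trial_start optional list of trial-start weight blocks for the
#'   per-trial cap (defaults to current weights, i.e. cap not
#'   re-tightened)
#' @return the network with scaled weights
#' @export
apply_homeostasis <- function(network, rates_e, trial_start = NULL) {
  hc <- network$config$homeostasis
  bounds <- weight_bounds(w0 = network$w0_eff,
                          trial_cap = network$config$bounds$trial_cap)
  n_e <- network$n_e
  stopifnot(length(rates_e) == n_e)
  fac_e <- 1 + hc$eps_e * (network$goal_rates$e - rates_e)
  fac_ie <- 1 + hc$eps_ie * (rates_e - network$goal_rates$ie)
  w_in <- sweep(network$weights$input[, seq_len(n_e), drop = FALSE], 2,
                fac_e, "*")
  w_ee <- sweep(network$weights$ee, 2, fac_e, "*")
  w_ie <- sweep(network$weights$ie, 2, fac_ie, "*")
  if (is.null(trial_start))
    trial_start <- list(input = network$weights$input,
                        ee = network$weights$ee, ie = network$weights$ie)
  network$weights$input[, seq_len(n_e)] <- enforce_bounds(
    w_in, trial_start$input[, seq_len(n_e), drop = FALSE], bounds)
  network$weights$ee <- enforce_bounds(w_ee, trial_start$ee, bounds)
  network$weights$ie <- enforce_bounds(w_ie, trial_start$ie, bounds)
  network
}

#' Probe stimulus-pair responses with frozen plasticity
#'
#' Runs `reps` trials per stimulus pair with all plasticity disabled and
#' returns the per-cell mean cue-window rates for each of the four
#' pairs, the input to the selectivity metric.
#'
#' @param network an `assoc_network`
#' @param reps trials per pair
#' @param seed integer seed
#' @return list with `rates` (excitatory cells x 4 pairs, Hz) and the
#'   [network_selectivity()] result
#' @export
measure_selectivity <- function(network, reps = 5, seed = 1L) {
  pairs <- c("AB", "AD", "CB", "CD")
  intg <- network$config$integration
  rates <- matrix(0, network$n_e, 4, dimnames = list(NULL, pairs))
  for (p in seq_along(pairs)) {
    for (r in seq_len(reps)) {
      s <- .child_seed(seed, 37L * p + r)
      inp <- generate_poisson_inputs(network$ensemble, pairs[p],
                                     intg$cue_ms, seed = s)
      tr <- run_trial(network, inp, condition = "initial",
                      seed = .child_seed(s, 1L), apply_weights = FALSE)
      rates[, p] <- rates[, p] + tr$rates_e
    }
    rates[, p] <- rates[, p] / reps
  }
  list(rates = rates, selectivity = network_selectivity(rates))
}
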