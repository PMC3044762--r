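#' @useDynLib pairnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm coef predict median sd nls resid quantile
#' @importFrom utils read.csv write.csv modifyList
NULL

# Printed parameter tables for each (cell class, layer) combination.
# Spreads are half-widths of uniform heterogeneity about the mean; the
# decision layer is homogeneous (spread 0 everywhere).
.cell_param_table <- function(regime = "standard") {
  gL_assoc <- switch(regime,
    high_threshold_40 = 40,
    high_threshold_50 = 50,
    35)
  list(
    associative = list(
      excitatory = list(
        mean = c(V_L = -70, tau_m = 10, g_L = gL_assoc, V_th = -50,
                 V_reset = -60, tau_reset = 2),
        spread = c(V_L = 2.5, tau_m = 0.75, g_L = 1, V_th = 2,
                   V_reset = 2, tau_reset = 0.25)),
      inhibitory = list(
        mean = c(V_L = -70, tau_m = 10, g_L = gL_assoc, V_th = -50,
                 V_reset = -60, tau_reset = 1),
        spread = c(V_L = 2.5, tau_m = 0.75, g_L = 1, V_th = 2,
                   V_reset = 2, tau_reset = 0.25))),
    decision = list(
      excitatory = list(
        mean = c(V_L = -70, tau_m = 20, g_L = 35, V_th = -48,
                 V_reset = -55, tau_reset = 2),
        spread = c(V_L = 0, tau_m = 0, g_L = 0, V_th = 0,
                   V_reset = 0, tau_reset = 0)),
      inhibitory = list(
        mean = c(V_L = -70, tau_m = 10, g_L = 30, V_th = -50,
                 V_reset = -55, tau_reset = 1),
        spread = c(V_L = 0, tau_m = 0, g_L = 0, V_th = 0,
                   V_reset = 0, tau_reset = 0))))
}

#' Receptor and spiking kinetics
#'
#' Reversal potentials and decay time constants for AMPA, NMDA and GABA_A
#' conductances, the magnesium gating of NMDA, the spike-triggered
#' refractory conductance that repolarizes the cell (there is no hard
#' voltage reset by default), and the dynamic spike threshold.
#'
#' `g_unit` converts unitless synaptic weights (initial mean `W0 = 0.05`)
#' into microsiemens of conductance per presynaptic spike, and `gref_gain`
#' scales the per-spike refractory increment `delta_gref`; both are
#' calibrated once so that a densely connected network fires at tens of Hz
#' while sparse networks stay nearly silent (see the methods vignette).
#'
#' @param g_unit conductance per unit weight, uS
#' @param gref_gain multiplier on `delta_gref`
#' @param nmda_frac NMDA conductance jump per unit weight, relative to
#'   the AMPA jump
#' @param th_increment dynamic-threshold jump per spike, mV
#' @param th_tau dynamic-threshold relaxation time constant, ms
#' @param hard_reset logical; if TRUE the voltage is reset to `V_reset`
#'   on each spike (used by analytic tests), otherwise repolarization is
#'   left to the refractory conductance
#' @return a list of class `kinetics_config`
#' @export
kinetics_config <- function(g_unit = 220, gref_gain = 5e5,
                            nmda_frac = 0.15,
                            th_increment = 10, th_tau = 200,
                            hard_reset = FALSE) {
  structure(list(
    E_ampa = 0, tau_ampa = 2,
    E_nmda = 0, tau_nmda = 100,
    E_gaba = -70, tau_gaba = 10,
    mg = 1, mg_slope = 0.062, mg_scale = 3.57,
    delta_gref = 0.002, V_gref = -70,
    Vth_max = 150,
    th_increment = th_increment, th_tau = th_tau,
    g_unit = g_unit, gref_gain = gref_gain,
    nmda_frac = nmda_frac,
    hard_reset = hard_reset), class = "kinetics_config")
}

#' Noise model configuration
#'
#' Two noise sources: Gaussian voltage noise (zero mean, unit variance,
#' Euler-Maruyama sqrt(dt) scaling) in the associative layer, and uniform
#' [0,1] conductance noise added to the AMPA and GABA_A conductances with
#' layer-specific amplitudes. The decision layer receives conductance
#' noise only. Amplitudes are free parameters of the model calibrated to
#' the target activity regimes (see the methods vignette).
#'
#' @param sigma_v voltage noise amplitude, mV per sqrt(ms)
#' @param g_noise_assoc conductance noise amplitude, associative layer, uS
#' @param g_noise_decision conductance noise amplitude, decision layer, uS
#' @return a list of class `noise_config`
#' @export
noise_config <- function(sigma_v = 0.5, g_noise_assoc = 1,
                         g_noise_decision = 1) {
  stopifnot(sigma_v >= 0, g_noise_assoc >= 0, g_noise_decision >= 0)
  structure(list(sigma_v = sigma_v, g_noise_assoc = g_noise_assoc,
                 g_noise_decision = g_noise_decision),
            class = "noise_config")
}

#' Integration configuration
#'
#' @param dt integration step, ms
#' @param cue_ms cue presentation time, ms
#' @param relax_ms inter-trial relaxation (inputs off) before each cue, ms
#' @return list of class `integration_config`
#' @export
integration_config <- function(dt = 0.02, cue_ms = 1000, relax_ms = 500) {
  stopifnot(dt > 0, cue_ms > 0, relax_ms >= 0)
  structure(list(dt = dt, cue_ms = cue_ms, relax_ms = relax_ms),
            class = "integration_config")
}

#' Pair (standard) STDP configuration
#'
#' Exponential-window spike-timing-dependent plasticity, implemented
#' all-to-all through presynaptic and postsynaptic traces. `dw` is the
#' global per-event scale multiplying the windowed amplitudes.
#'
#' @param a_plus LTP amplitude
#' @param a_minus LTD amplitude
#' @param tau_plus LTP window time constant, ms
#' @param tau_minus LTD window time constant, ms
#' @param dw per-event weight change scale
#' @return list of class `pair_stdp_config`
#' @export
pair_stdp_config <- function(a_plus = 1.20, a_minus = 0.80,
                             tau_plus = 16, tau_minus = 25, dw = 0.005) {
  stopifnot(a_plus > 0, a_minus > 0, tau_plus > 0, tau_minus > 0)
  structure(list(a_plus = a_plus, a_minus = a_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus, dw = dw),
            class = "pair_stdp_config")
}

#' Triplet STDP configuration
#'
#' All-to-all triplet rule: recent postsynaptic spikes (slow trace,
#' `tau_y`) boost potentiation of pre-before-post pairings and recent
#' presynaptic spikes (slow trace, `tau_x`) boost depression of
#' post-before-pre pairings. Amplitudes default to the full-model
#' all-to-all cortical set; with these values uncorrelated Poisson trains
#' at matched rates cross from depression to potentiation near 20 Hz.
#'
#' @param a2_plus,a2_minus doublet LTP/LTD amplitudes
#' @param a3_plus,a3_minus triplet LTP/LTD amplitudes
#' @param tau2_plus,tau2_minus fast trace time constants, ms
#' @param tau_x,tau_y slow trace time constants, ms
#' @param dw global per-event scale multiplying the amplitudes
#' @return list of class `triplet_stdp_config`
#' @export
triplet_stdp_config <- function(a2_plus = 5e-10, a2_minus = 7e-3,
                                a3_plus = 6.2e-3, a3_minus = 2.3e-4,
                                tau2_plus = 16.68, tau2_minus = 33.7,
                                tau_x = 101, tau_y = 125, dw = 0.005) {
  structure(list(a2_plus = a2_plus, a2_minus = a2_minus,
                 a3_plus = a3_plus, a3_minus = a3_minus,
                 tau2_plus = tau2_plus, tau2_minus = tau2_minus,
                 tau_x = tau_x, tau_y = tau_y, dw = dw),
            class = "triplet_stdp_config")
}

#' LTPi configuration
#'
#' Long-term potentiation of inhibitory-to-excitatory synapses: each
#' inhibitory spike potentiates the synapse by `idw` provided (i) the
#' postsynaptic excitatory cell emits no spike within `veto_ms` of the
#' inhibitory spike (the veto), and (ii) its membrane voltage at the
#' inhibitory spike time is above `v_threshold` (depolarization
#' requirement). The rule only increases weights.
#'
#' @param idw potentiation per non-vetoed inhibitory spike
#' @param veto_ms half-width of the symmetric veto window, ms
#' @param v_threshold depolarization threshold, mV; `-Inf` disables the
#'   voltage dependence (the "none" sweep level)
#' @param w_max hard upper bound on inhibitory weight (default 20 * W0)
#' @return list of class `ltpi_config`
#' @export
ltpi_config <- function(idw = 0.005, veto_ms = 20, v_threshold = -65,
                        w_max = 20 * 0.05) {
  stopifnot(idw >= 0, veto_ms >= 0)
  structure(list(idw = idw, veto_ms = veto_ms, v_threshold = v_threshold,
                 w_max = w_max), class = "ltpi_config")
}

#' Homeostasis configuration
#'
#' Trial-by-trial multiplicative postsynaptic scaling pushing each cell's
#' cue-window mean rate toward a goal rate. Goal rates for excitatory
#' cells and for inhibitory-to-excitatory scaling are heterogeneous with
#' an added uniform spread about their means.
#'
#' @param eps_ie rate constant, inhibitory-to-excitatory synapses
#' @param eps_e rate constant, input-to-excitatory and recurrent
#'   excitatory synapses
#' @param r_goal_e excitatory goal rate, Hz (4 in the low-goal regime)
#' @param r_goal_ie goal rate for inhibitory-to-excitatory scaling, Hz
#' @param r_goal_i inhibitory-cell goal rate, Hz (diagnostic only;
#'   inhibitory-to-inhibitory synapses are not plastic)
#' @param goal_spread uniform half-spread added to r_goal_e and
#'   r_goal_ie per cell, Hz
#' @return list of class `homeostasis_config`
#' @export
homeostasis_config <- function(eps_ie = 0.01, eps_e = 1e-4,
                               r_goal_e = 8, r_goal_ie = 8, r_goal_i = 8,
                               goal_spread = 5) {
  stopifnot(eps_ie > 0, eps_e > 0, r_goal_e > 0, r_goal_ie > 0)
  structure(list(eps_ie = eps_ie, eps_e = eps_e, r_goal_e = r_goal_e,
                 r_goal_ie = r_goal_ie, r_goal_i = r_goal_i,
                 goal_spread = goal_spread), class = "homeostasis_config")
}

#' Weight bounds
#'
#' Per-trial changes are capped at 50% of the trial-start weight and
#' weights are globally bounded between zero and `20 * W0`.
#'
#' @param w0 initial mean weight of the block
#' @param trial_cap maximal fractional change per trial
#' @return list of class `weight_bounds`
#' @export
weight_bounds <- function(w0 = 0.05, trial_cap = 0.5) {
  stopifnot(w0 > 0, trial_cap >= 0)
  structure(list(w_min = 0, w_max = 20 * w0, trial_cap = trial_cap,
                 w0 = w0), class = "weight_bounds")
}

.input_probabilities <- c(1/2, 1/3, 1/5, 1/10, 1/20)
.input_group_counts <- c(2L, 4L, 6L, 10L, 20L)
.regimes <- c("standard", "high_threshold_40", "high_threshold_50",
              "inhibition_x4", "low_goal_rate", "recurrent_inhibition",
              "homogeneous_inputs", "homogeneous_ee", "homogeneous_ie",
              "homogeneous_cells")

#' Network configuration
#'
#' Assembles the full configuration of one associative-layer network:
#' size, excitatory:inhibitory ratio 4:1, grid coordinates (input
#' connection probability and number of independent input groups per
#' stimulus), regime flags and the master seed from which all child seeds
#' are derived.
#'
#' The recurrent weight scale is size-invariant: the effective initial
#' mean weight is `w0 * 400 / n_associative` so that total recurrent
#' drive is preserved when the network is scaled down.
#'
#' @param n_associative number of associative-layer cells (4:1 E:I)
#' @param groups_per_stimulus one of 2, 4, 6, 10, 20
#' @param input_probability one of 1/2, 1/3, 1/5, 1/10, 1/20
#' @param regime one of `"standard"`, `"high_threshold_40"`,
#'   `"high_threshold_50"`, `"inhibition_x4"`, `"low_goal_rate"`,
#'   `"recurrent_inhibition"`, `"homogeneous_inputs"`,
#'   `"homogeneous_ee"`, `"homogeneous_ie"`, `"homogeneous_cells"`
#' @param master_seed integer master seed
#' @param w0 initial mean synaptic weight before size scaling
#' @param allow_nonstandard if TRUE, grid values outside the stated sets
#'   are accepted
#' @param kinetics,noise,integration,homeostasis,bounds optional
#'   sub-configuration overrides
#' @return list of class `network_config`
#' @export
network_config <- function(n_associative = 400,
                           groups_per_stimulus = 6,
                           input_probability = 1/3,
                           regime = "standard",
                           master_seed = 1L,
                           w0 = 0.05,
                           allow_nonstandard = FALSE,
                           kinetics = kinetics_config(),
                           noise = noise_config(),
                           integration = integration_config(),
                           homeostasis = NULL,
                           bounds = NULL) {
  regime <- match.arg(regime, .regimes)
  if (!allow_nonstandard) {
    if (!any(abs(input_probability - .input_probabilities) < 1e-12))
      stop("input_probability must be one of 1/2, 1/3, 1/5, 1/10, 1/20 ",
           "(set allow_nonstandard = TRUE to override)", call. = FALSE)
    if (!groups_per_stimulus %in% .input_group_counts)
      stop("groups_per_stimulus must be one of 2, 4, 6, 10, 20 ",
           "(set allow_nonstandard = TRUE to override)", call. = FALSE)
  }
  stopifnot(n_associative > 0, n_associative %% 5 == 0)
  if (is.null(homeostasis)) {
    homeostasis <- if (regime == "low_goal_rate")
      homeostasis_config(r_goal_e = 4) else homeostasis_config()
  }
  if (is.null(bounds)) bounds <- weight_bounds(w0 = w0)
  structure(list(
    n_associative = as.integer(n_associative),
    n_e = as.integer(n_associative * 4 / 5),
    n_i = as.integer(n_associative / 5),
    groups_per_stimulus = as.integer(groups_per_stimulus),
    input_probability = input_probability,
    regime = regime,
    master_seed = as.integer(master_seed),
    w0 = w0,
    w0_eff = w0 * 400 / n_associative,
    kinetics = kinetics, noise = noise, integration = integration,
    homeostasis = homeostasis, bounds = bounds),
    class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat("Associative network configuration\n")
  cat(sprintf("  cells: %d (%d E / %d I), regime: %s\n",
              x$n_associative, x$n_e, x$n_i, x$regime))
  cat(sprintf("  input grid: %d groups/stimulus at p = %.3g (%.3g Hz/group)\n",
              x$groups_per_stimulus, x$input_probability,
              480 / x$groups_per_stimulus))
  cat(sprintf("  W0 = %.3g (effective %.3g), master seed %d\n",
              x$w0, x$w0_eff, x$master_seed))
  invisible(x)
}

# Fixed counter scheme deriving independent child seeds from the master
# seed, one stream per randomness source. Kept below 2^31 - 1.
.child_seed <- function(master_seed, stream) {
  as.integer((as.double(master_seed) * 7919 + 104729 * stream) %% 2147483629)
}

#' Derive a child seed from a master seed
#'
#' One master seed governs a whole run; each independent randomness
#' source (structure, cell parameters, inputs, noise, trial ordering...)
#' draws its own child seed by a fixed counter scheme, so each source is
#' reproducible in isolation.
#'
#' @param master_seed integer
#' @param stream small integer or known stream name
#' @return integer seed
#' @export
child_seed <- function(master_seed, stream) {
  if (is.character(stream)) {
    streams <- c(structure = 1L, cell_params = 2L, weights = 3L,
                 inputs = 4L, noise = 5L, trials = 6L, decision = 7L,
                 goal_rates = 8L)
    stream <- streams[[match.arg(stream, names(streams))]]
  }
  .child_seed(master_seed, as.integer(stream))
}
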