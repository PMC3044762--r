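#' Urgency ramp conductance
#'
#' Linear ramping excitatory input to both decision pools, zero before
#' cue onset, reaching its maximal value (5 uS by default) at cue end.
#' It guarantees that one pool wins by the end of every trial.
#'
#' @param t time within the trial, ms
#' @param cue_onset,cue_end cue window, ms
#' @param g_max maximal urgency conductance, uS
#' @return conductance, uS (vectorized in `t`)
#' @export
urgency_conductance <- function(t, cue_onset = 500, cue_end = 1500,
                                g_max = 5) {
  ifelse(t <= cue_onset, 0,
         pmin(g_max, g_max * (t - cue_onset) / (cue_end - cue_onset)))
}

#' Decision-layer run options
#'
#' The decision layer has its own conductance scale (`g_unit`), strong
#' enough for the all-to-all within-pool excitation at `W0 = 0.25` to
#' sustain winner-take-all competition, conductance noise only, and the
#' urgency ramp. `urg_gain` converts the printed maximal urgency
#' conductance into the same effective scale.
#'
#' @param g_urgency maximal urgency conductance, uS
#' @param urg_gain gain applied to the urgency conductance
#' @param g_unit decision-layer conductance per unit weight, uS
#' @param g_noise conductance noise amplitude, uS
#' @param readout_ms readout window at cue end, ms
#' @param th_increment,th_tau decision-layer dynamic-threshold jump (mV)
#'   and relaxation (ms); milder than the associative layer so the
#'   winning pool can sustain persistent activity
#' @param nmda_frac decision-layer NMDA jump relative to AMPA; the slow
#'   NMDA component dominates the recurrence so the pools integrate
#'   evidence and compete
#' @param gref_gain decision-layer multiplier on the per-spike
#'   refractory increment; weaker than the associative layer so
#'   per-cell adaptation does not quench the pool competition
#' @param anomaly_margin minimal Release/Hold readout-rate ratio below
#'   which the trial is flagged anomalous
#' @return list of class `decision_opts`
#' @export
decision_opts <- function(g_urgency = 5, urg_gain = 5, g_unit = 1.2,
                          g_noise = 1, readout_ms = 100,
                          th_increment = 2, th_tau = 50,
                          nmda_frac = 1.5, gref_gain = 5e4,
                          anomaly_margin = 2) {
  structure(list(g_urgency = g_urgency, urg_gain = urg_gain,
                 g_unit = g_unit, g_noise = g_noise,
                 readout_ms = readout_ms,
                 th_increment = th_increment, th_tau = th_tau,
                 nmda_frac = nmda_frac, gref_gain = gref_gain,
                 anomaly_margin = anomaly_margin),
            class = "decision_opts")
}

#' Run the winner-take-all decision circuit for one trial
#'
#' Feeds the associative layer's excitatory spikes through the afferent
#' weights into both pools, applies the urgency ramp, and reads out the
#' winner as the pool with the higher mean excitatory rate over the
#' final readout window (exact ties resolved uniformly at random).
#'
#' @param decision a [build_decision_network()] result
#' @param assoc_spikes data.frame with columns `neuron`, `time_ms` (the
#'   associative trial's spikes, on the same trial clock); only
#'   excitatory associative cells (ids `1..n_aff`) drive the afferents
#' @param integration an [integration_config()] (shared trial clock)
#' @param opts a [decision_opts()]
#' @param kinetics a [kinetics_config()] (receptor kinetics; the
#'   decision-layer `g_unit` in `opts` overrides the associative one)
#' @param seed integer seed
#' @return list of class `decision_outcome` with `choice`,
#'   `pool_rates`, `readout_rates`, `anomalous`
#' @export
run_decision <- function(decision, assoc_spikes,
                         integration = integration_config(),
                         opts = decision_opts(),
                         kinetics = kinetics_config(), seed = 1L) {
  stopifnot(inherits(decision, "decision_network"))
  cells <- decision$cells
  kin <- unclass(kinetics)
  kin$g_unit <- opts$g_unit
  kin$th_increment <- opts$th_increment
  kin$th_tau <- opts$th_tau
  kin$nmda_frac <- opts$nmda_frac
  kin$gref_gain <- opts$gref_gain
  n_aff <- nrow(decision$afferents)
  keep <- assoc_spikes$neuron <= n_aff
  res <- .sim_decision_cpp(
    decision$n_e, decision$n_i,
    cells$V_L, cells$tau_m, cells$g_L, cells$V_th, cells$V_reset,
    cells$tau_reset,
    decision$mask, decision$weights, decision$afferents,
    assoc_spikes$time_ms[keep], as.integer(assoc_spikes$neuron[keep]),
    kin, opts$g_noise, opts$g_urgency, opts$urg_gain,
    integration$dt, integration$relax_ms, integration$cue_ms,
    opts$readout_ms, as.double(seed))
  ro <- res$readout_rates
  r1 <- mean(ro[decision$e1]); r2 <- mean(ro[decision$e2])
  choice <- if (r1 > r2) "Release" else if (r2 > r1) "Hold"
            else sample(c("Release", "Hold"), 1)
  lo <- min(r1, r2); hi <- max(r1, r2)
  anomalous <- lo > 0 && hi / lo < opts$anomaly_margin
  structure(list(
    choice = choice,
    pool_rates = c(Release = mean(res$rates[decision$e1]),
                   Hold = mean(res$rates[decision$e2])),
    readout_rates = c(Release = r1, Hold = r2),
    anomalous = anomalous,
    spikes = data.frame(neuron = res$spike_id, time_ms = res$spike_t)),
    class = "decision_outcome")
}

#' @export
print.decision_outcome <- function(x, ...) {
  cat(sprintf(
    "Decision: %s (readout Release %.1f Hz vs Hold %.1f Hz)%s\n",
    x$choice, x$readout_rates[["Release"]], x$readout_rates[["Hold"]],
    if (x$anomalous) " [anomalous co-activity]" else ""))
  invisible(x)
}

#' Reward-rule configuration
#'
#' Dopamine-modulated Hebbian plasticity of the associative-to-decision
#' afferents: after each trial the afferents from coactive associative
#' cells onto the winning pool change by `eta * DA * activity`, with
#' `DA = +1` on rewarded (correct) trials and `-1` on the dopamine dip
#' of unrewarded trials. Eligibility is the presynaptic cue rate
#' (`"rate"`) or a 0/1 indicator (`"binary"`); cells below the
#' coactivity threshold are not eligible.
#'
#' @param eta learning rate
#' @param coactivity_threshold minimal presynaptic cue rate, Hz
#' @param eligibility `"rate"` or `"binary"`
#' @param w_max upper afferent bound (default 20 * DW0)
#' @return list of class `reward_rule_config`
#' @export
reward_rule_config <- function(eta = 5e-4, coactivity_threshold = 1,
                               eligibility = c("rate", "binary"),
                               w_max = 20 * 0.075) {
  eligibility <- match.arg(eligibility)
  stopifnot(eta > 0)
  structure(list(eta = eta,
                 coactivity_threshold = coactivity_threshold,
                 eligibility = eligibility, w_max = w_max),
            class = "reward_rule_config")
}

#' Dopamine-modulated reward update of the afferent weights
#'
#' Only afferents onto the winning pool change; losing-pool afferents
#' are untouched, silent presynaptic cells are not eligible, and weights
#' are clamped to `[0, w_max]`.
#'
#' @param decision a `decision_network`
#' @param assoc_rates cue-window rates of the associative excitatory
#'   cells, Hz
#' @param choice the winning pool, `"Release"` or `"Hold"`
#' @param correct logical; was the choice correct (reward) or not (dip)
#' @param config a [reward_rule_config()]
#' @return the decision network with updated afferents
#' @export
da_reward_update <- function(decision, assoc_rates, choice, correct,
                             config = reward_rule_config()) {
  stopifnot(inherits(decision, "decision_network"),
            length(assoc_rates) == nrow(decision$afferents),
            choice %in% c("Release", "Hold"))
  da <- if (correct) 1 else -1
  act <- ifelse(assoc_rates >= config$coactivity_threshold,
                if (config$eligibility == "rate") assoc_rates else 1, 0)
  cols <- if (choice == "Release") decision$e1 else decision$e2
  dw <- config$eta * da * act
  decision$afferents[, cols] <- pmin(pmax(
    decision$afferents[, cols] + dw, 0), config$w_max)
  decision
}
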