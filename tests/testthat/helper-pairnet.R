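# Small networks used across tests. Reduced sizes and dt = 0.05 ms keep
# the suite fast; the full-scale defaults are exercised only where a
# test needs them.

tiny_config <- function(master_seed = 1L, n = 100L, groups = 2L,
                        p = 1/2, dt = 0.1, cue_ms = 200, relax_ms = 50,
                        noise = noise_config(), ...) {
  network_config(n_associative = n, groups_per_stimulus = groups,
                 input_probability = p, master_seed = master_seed,
                 noise = noise,
                 integration = integration_config(dt = dt,
                                                  cue_ms = cue_ms,
                                                  relax_ms = relax_ms),
                 ...)
}

desk_config <- function(master_seed = 1L, n = 200L, groups = 6L,
                        p = 1/3, dt = 0.05, ...) {
  network_config(n_associative = n, groups_per_stimulus = groups,
                 input_probability = p, master_seed = master_seed,
                 integration = integration_config(dt = dt),
                 ...)
}

quiet_noise <- function() noise_config(sigma_v = 0, g_noise_assoc = 0)

# Poisson surrogate spikes for decision-layer tests: one spike train per
# associative excitatory cell at the given rates over [t0, t1] ms.
surrogate_spikes <- function(rates, seed, t0 = 500, t1 = 1500) {
  set.seed(seed)
  n <- rpois(length(rates), rates * (t1 - t0) / 1000)
  out <- data.frame(neuron = rep(seq_along(rates), n),
                    time_ms = runif(sum(n), t0, t1))
  out[order(out$time_ms), , drop = FALSE]
}
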