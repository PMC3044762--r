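test_that("NMDA gating follows the magnesium-block curve", {
  expect_equal(nmda_gating(0), 1 / (1 + 1 / 3.57), tolerance = 1e-9)
  expect_equal(nmda_gating(0), 0.7812, tolerance = 1e-3)
  expect_equal(nmda_gating(-70), 1 / (1 + exp(0.062 * 70) / 3.57),
               tolerance = 1e-9)
  expect_equal(nmda_gating(-70), 0.0445, tolerance = 1e-3)
  v <- seq(-90, 60, by = 1)
  expect_true(all(diff(nmda_gating(v)) > 0))       # monotone
  expect_gt(nmda_gating(500), 0.999)               # saturation
  expect_error(nmda_gating(Inf))
})

test_that("Poisson inputs activate only the cued stimuli at the stated rates", {
  ens <- build_input_ensemble(10, 1/3, seed = 1)
  inp <- generate_poisson_inputs(ens, "CD", 1000, seed = 2)
  active_stims <- unique(ens$group_stimulus[unique(inp$group)])
  expect_true(all(active_stims %in% c("C", "D")))
  # per-group counts: 48 Hz +/- 3 SD over repeats
  counts <- unlist(lapply(1:10, function(s) {
    x <- generate_poisson_inputs(ens, "AB", 1000, seed = s)
    tabulate(x$group, nbins = 40)[1:20]
  }))
  expect_lt(abs(mean(counts) - 48), 3 * sqrt(48) / sqrt(length(counts)))
  expect_identical(generate_poisson_inputs(ens, "AB", 500, seed = 9),
                   generate_poisson_inputs(ens, "AB", 500, seed = 9))
  expect_error(generate_poisson_inputs(ens, c("A", "A")), "distinct")
  expect_error(generate_poisson_inputs(ens, c("A", "B", "C")), "distinct")
})

test_that("resting state is a fixed point and conductances decay exponentially", {
  params <- sample_cell_params(5, "excitatory", "associative", seed = 1)
  st <- init_state(params)
  for (k in 1:100) st <- step_population(st, params, dt = 0.02)$state
  expect_equal(st$v, params$V_L, tolerance = 1e-10)
  # single AMPA jump decays by a factor e over tau_ampa = 2 ms
  st2 <- init_state(params)
  st2$g_ampa <- rep(1, 5)
  for (k in 1:100) st2 <- step_population(st2, params, dt = 0.02)$state
  expect_equal(st2$g_ampa, rep(exp(-1), 5), tolerance = 1e-9)
})

test_that("noise-free LIF spike times match the analytic interspike interval", {
  kin <- kinetics_config(gref_gain = 0, th_increment = 0,
                         nmda_frac = 0, hard_reset = TRUE, g_unit = 1)
  params <- data.frame(V_L = -70, tau_m = 10, g_L = 35, V_th = -50,
                       V_reset = -60, tau_reset = 2)
  gc <- 30  # constant excitatory conductance, uS: suprathreshold
  v_inf <- (params$g_L * params$V_L) / (params$g_L + gc)
  tau_eff <- params$g_L * params$tau_m / (params$g_L + gc)
  isi <- tau_eff * log((v_inf - params$V_reset) / (v_inf - params$V_th))
  dt <- 0.01
  st <- init_state(params)
  st$v <- params$V_reset
  st$g_ampa <- gc
  hold <- gc * (1 - exp(-dt / kin$tau_ampa))  # keep the drive constant
  spikes <- c()
  for (k in 1:20000) {
    out <- step_population(st, params, kin, noise = NULL, dt = dt,
                           incoming = list(exc = hold))
    st <- out$state
    if (out$spiked) spikes <- c(spikes, k * dt)
  }
  expect_gt(length(spikes), 5)
  isis <- diff(spikes)
  expect_lt(max(abs(isis - isi)), 0.05)
  expect_lt(diff(range(isis)), 2 * dt + 1e-12)  # periodic
})

test_that("compiled trial integrator reproduces the reference stepper", {
  cfg <- tiny_config(master_seed = 3, n = 20, dt = 0.1, cue_ms = 200,
                     relax_ms = 50, noise = quiet_noise())
  net <- build_associative_network(cfg)
  # feedforward-only comparison: silence recurrent blocks
  net$weights$ee[] <- 0; net$weights$ie[] <- 0; net$weights$ii[] <- 0
  inp <- generate_poisson_inputs(net$ensemble, "AB", 200, seed = 5)
  tr <- run_trial(net, inp, "initial", seed = 1)

  params <- net$cells
  kin <- cfg$kinetics
  st <- init_state(params)
  dt <- 0.1
  n_steps <- round(250 / dt)
  w_in <- net$weights$input
  spikes_r <- data.frame(neuron = integer(0), time_ms = numeric(0))
  ptr <- 1
  for (k in seq_len(n_steps)) {
    t <- k * dt
    exc <- numeric(nrow(params))
    while (ptr <= nrow(inp) && inp$time_ms[ptr] + 50 <= t) {
      g <- inp$group[ptr]
      exc <- exc + w_in[g, ] * net$ensemble$mask[g, ]
      ptr <- ptr + 1
    }
    out <- step_population(st, params, kin, noise = NULL, dt = dt,
                           incoming = list(exc = exc))
    st <- out$state
    if (any(out$spiked))
      spikes_r <- rbind(spikes_r,
                        data.frame(neuron = which(out$spiked),
                                   time_ms = t))
  }
  spikes_r <- spikes_r[order(spikes_r$time_ms, spikes_r$neuron), ]
  cpp <- tr$spikes[order(tr$spikes$time_ms, tr$spikes$neuron), ]
  expect_equal(nrow(cpp), nrow(spikes_r))
  expect_equal(cpp$neuron, spikes_r$neuron)
  expect_equal(cpp$time_ms, spikes_r$time_ms, tolerance = 1e-9)
})

test_that("trials are silent without input and noise, and deterministic", {
  cfg <- tiny_config(master_seed = 2, noise = quiet_noise())
  net <- build_associative_network(cfg)
  empty <- generate_poisson_inputs(net$ensemble, "AB", 200, seed = 1)
  empty <- empty[0, , drop = FALSE]
  tr0 <- run_trial(net, empty, "initial", seed = 1)
  expect_equal(nrow(tr0$spikes), 0)
  expect_true(all(tr0$rates == 0))
  cfg2 <- tiny_config(master_seed = 2)
  net2 <- build_associative_network(cfg2)
  inp <- generate_poisson_inputs(net2$ensemble, "AD", 200, seed = 3)
  a <- run_trial(net2, inp, "initial", seed = 7)
  b <- run_trial(net2, inp, "initial", seed = 7)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$rates, b$rates)
})

test_that("a dense standard network is active while the sparse one is quiet", {
  cfg_dense <- network_config(groups_per_stimulus = 6,
                              input_probability = 1/3, master_seed = 21,
                              integration = integration_config(dt = 0.05))
  net <- build_associative_network(cfg_dense)
  inp <- generate_poisson_inputs(net$ensemble, "AB", 1000, seed = 4)
  tr <- run_trial(net, inp, "initial", seed = 5)
  expect_gt(mean(tr$rates_e), 5)   # "high" initial regime, tens of Hz
  cfg_sparse <- network_config(groups_per_stimulus = 6,
                               input_probability = 1/20,
                               master_seed = 21,
                               integration = integration_config(dt = 0.05))
  nets <- build_associative_network(cfg_sparse)
  inps <- generate_poisson_inputs(nets$ensemble, "AB", 1000, seed = 4)
  trs <- run_trial(nets, inps, "initial", seed = 5)
  expect_lt(mean(trs$rates_e), mean(tr$rates_e) / 3)
})

test_that("halving dt changes noise-free spike counts by at most one per neuron", {
  counts <- lapply(c(0.1, 0.05), function(dt) {
    cfg <- tiny_config(master_seed = 3, n = 20, dt = dt, cue_ms = 200,
                       relax_ms = 50, noise = quiet_noise())
    net <- build_associative_network(cfg)
    net$weights$ee[] <- 0; net$weights$ie[] <- 0; net$weights$ii[] <- 0
    inp <- generate_poisson_inputs(net$ensemble, "AB", 200, seed = 5)
    tabulate(run_trial(net, inp, "initial", seed = 1)$spikes$neuron, 20)
  })
  expect_lte(max(abs(counts[[1]] - counts[[2]])), 1)
})

test_that("the dynamic threshold stays within its bounds under heavy firing", {
  kin <- kinetics_config(gref_gain = 0, th_increment = 30, th_tau = 50,
                         nmda_frac = 0, g_unit = 1)
  params <- data.frame(V_L = -70, tau_m = 10, g_L = 35, V_th = -50,
                       V_reset = -60, tau_reset = 2)
  st <- init_state(params)
  st$g_ampa <- 5000  # far suprathreshold
  hold <- 5000 * (1 - exp(-0.05 / kin$tau_ampa))
  th_track <- numeric(4000)
  for (k in 1:4000) {
    st <- step_population(st, params, kin, dt = 0.05,
                          incoming = list(exc = hold))$state
    th_track[k] <- st$v_th
  }
  expect_lte(max(th_track), 150)
  expect_gte(min(th_track), params$V_th - 1e-9)
  # it climbed until the voltage could no longer reach it (the drive
  # reversal at 0 mV caps the attainable threshold)
  expect_gt(max(th_track), -30)
  # the 150 mV ceiling binds when a spike would overshoot it
  st$v_th <- 149
  kin2 <- kinetics_config(gref_gain = 0, th_increment = 300,
                          nmda_frac = 0, g_unit = 1)
  st$g_ampa <- 0  # drop the drive so one leak step stays suprathreshold
  st$v <- 160  # force a crossing
  out <- step_population(st, params, kin2, dt = 0.05)
  expect_true(out$spiked)
  expect_equal(out$state$v_th, 150)
})
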