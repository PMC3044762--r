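test_that("cell parameters are uniform within the printed spreads", {
  p <- sample_cell_params(320, "excitatory", "associative", seed = 2)
  expect_true(all(p$tau_reset >= 1.75 & p$tau_reset <= 2.25))
  expect_true(all(p$V_L >= -72.5 & p$V_L <= -67.5))
  expect_true(all(p$V_th >= -52 & p$V_th <= -48))
  pi <- sample_cell_params(80, "inhibitory", "associative", seed = 2)
  expect_true(all(pi$tau_reset >= 0.75 & pi$tau_reset <= 1.25))
  # decision layer is homogeneous: every field equals its mean
  d <- sample_cell_params(10, "excitatory", "decision", seed = 5)
  expect_true(all(d$tau_m == 20) && all(d$V_th == -48))
  # law of large numbers on uniform(-72.5, -67.5)
  big <- sample_cell_params(10000, "excitatory", "associative", seed = 3)
  expect_lt(abs(mean(big$V_L) + 70), 0.1)
  expect_error(sample_cell_params(10, "excitatory", "cortex"))
})

test_that("associative connectivity matches the stated block statistics", {
  net <- build_associative_network(network_config(master_seed = 7))
  expect_equal(net$n_e, 320)
  expect_equal(net$n_i, 80)
  expect_equal(sum(net$masks$ii), 80 * 79)           # all-to-all, no self
  dens_ee <- mean(net$masks$ee)
  expect_gt(dens_ee, 0.08); expect_lt(dens_ee, 0.12)
  dens_ie <- mean(net$masks$ie)
  expect_gt(dens_ie, 0.22); expect_lt(dens_ie, 0.28)
  expect_false(any(net$masks$ei))                    # feedforward only
  expect_false(any(diag(net$masks$ee)))
  # initial weights uniform within W0 +/- 50%
  w <- net$weights$ee[net$masks$ee]
  expect_true(all(w >= 0.5 * net$w0_eff & w <= 1.5 * net$w0_eff))
})

test_that("regime flags switch connectivity variants", {
  rec <- build_associative_network(
    network_config(regime = "recurrent_inhibition", master_seed = 7))
  dens_ei <- mean(rec$masks$ei)
  expect_gt(dens_ei, 0.21); expect_lt(dens_ei, 0.29)
  hom <- build_associative_network(
    network_config(regime = "homogeneous_inputs", master_seed = 7))
  expect_true(all(hom$ensemble$mask))
  x4 <- build_associative_network(
    network_config(regime = "inhibition_x4", master_seed = 7))
  base <- build_associative_network(network_config(master_seed = 7))
  expect_equal(mean(x4$weights$ie[x4$masks$ie]),
               4 * mean(base$weights$ie[base$masks$ie]))
})

test_that("network building is bit-reproducible from the master seed", {
  a <- build_associative_network(network_config(master_seed = 11))
  b <- build_associative_network(network_config(master_seed = 11))
  expect_identical(a$weights, b$weights)
  expect_identical(a$masks, b$masks)
  expect_identical(a$cells, b$cells)
  c <- build_associative_network(network_config(master_seed = 12))
  expect_false(identical(a$weights$ee, c$weights$ee))
})

test_that("input ensembles split 480 Hz over the groups", {
  e10 <- build_input_ensemble(10, 1/3, seed = 1)
  expect_equal(e10$rate_per_group, 48)
  expect_equal(build_input_ensemble(2, 1/2, seed = 1)$rate_per_group, 240)
  expect_equal(nrow(e10$mask), 40)
  # expected connections per group: 320 * 1/20 = 16
  e <- build_input_ensemble(20, 1/20, n_e = 320, n_i = 80, seed = 4)
  per_group <- rowSums(e$mask[, 1:320])
  expect_lt(abs(mean(per_group) - 16), 3 * sqrt(16 * 0.95) / sqrt(80))
  expect_error(build_input_ensemble(3, 1/3), "groups_per_stimulus")
  expect_error(build_input_ensemble(10, 0.4), "probability")
  expect_silent(build_input_ensemble(3, 0.4, allow_nonstandard = TRUE))
})

test_that("decision network has two pools with the stated strengths", {
  cfg <- network_config(master_seed = 1)
  dec <- build_decision_network(cfg)
  expect_equal(dec$n_e_pool, 200)
  expect_equal(dec$n_i_pool, 50)
  expect_equal(dec$n_e + dec$n_i, 500)
  expect_true(all(dec$afferents == 0.075))
  expect_equal(dim(dec$afferents), c(320, 400))
  # within-pool excitatory recurrence complete (minus self)
  expect_equal(sum(dec$mask[dec$e1, dec$e1]), 200 * 199)
  # cross-inhibition present, within-pool I->E absent
  expect_true(all(dec$mask[dec$i1, dec$e2]))
  expect_false(any(dec$mask[dec$i1, dec$e1]))
  expect_true(all(dec$weights[dec$mask] == 0.25))
  # untrained sparse networks use the stronger afferent strength
  sparse <- network_config(input_probability = 1/20,
                           groups_per_stimulus = 6, master_seed = 1)
  expect_equal(build_decision_network(sparse, trained = FALSE)$dw0, 0.125)
  expect_equal(build_decision_network(sparse, trained = TRUE)$dw0, 0.075)
  dense <- network_config(input_probability = 1/3, master_seed = 1)
  expect_equal(build_decision_network(dense, trained = FALSE)$dw0, 0.075)
})

test_that("the grid enumerates 25 distinct configurations deterministically", {
  g1 <- grid_configs("standard", master_seed = 5)
  g2 <- grid_configs("standard", master_seed = 5)
  expect_length(g1, 25)
  keys <- vapply(g1, function(cfg)
    paste(cfg$input_probability, cfg$groups_per_stimulus), "")
  expect_equal(length(unique(keys)), 25)
  expect_identical(vapply(g1, `[[`, 1L, "master_seed"),
                   vapply(g2, `[[`, 1L, "master_seed"))
})

test_that("child seeds are deterministic and distinct across streams", {
  expect_identical(child_seed(42, "inputs"), child_seed(42, "inputs"))
  streams <- c("structure", "cell_params", "weights", "inputs", "noise",
               "trials", "decision", "goal_rates")
  seeds <- vapply(streams, function(s) child_seed(42, s), 1L)
  expect_equal(length(unique(seeds)), length(streams))
  expect_true(all(seeds >= 0 & seeds < 2^31))
})

test_that("nonstandard grid values are rejected unless overridden", {
  expect_error(network_config(input_probability = 0.4), "1/20")
  expect_error(network_config(groups_per_stimulus = 7), "20")
  expect_silent(network_config(input_probability = 0.4,
                               allow_nonstandard = TRUE))
})
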