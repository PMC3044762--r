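test_that("urgency ramp is linear from zero to its maximum", {
  expect_equal(urgency_conductance(500), 0)
  expect_equal(urgency_conductance(100), 0)
  expect_equal(urgency_conductance(1500), 5)
  expect_equal(urgency_conductance(1000), 2.5)
  t <- seq(500, 1500, by = 50)
  g <- urgency_conductance(t)
  expect_true(all(diff(g) > 0))
  expect_true(all(g >= 0 & g <= 5))
})

test_that("strong afferent drive to one pool forces that pool to win", {
  cfg <- network_config(master_seed = 2,
                        integration = integration_config(dt = 0.05))
  dec <- build_decision_network(cfg)
  dec$afferents[, dec$e2] <- 0  # Hold pool receives nothing
  sp <- surrogate_spikes(rep(20, 320), seed = 1)
  out <- run_decision(dec, sp, cfg$integration, seed = 3)
  expect_s3_class(out, "decision_outcome")
  expect_equal(out$choice, "Release")
  expect_gt(out$readout_rates[["Release"]], out$readout_rates[["Hold"]])
})

test_that("symmetric drive gives both outcomes across seeds", {
  cfg <- network_config(master_seed = 2,
                        integration = integration_config(dt = 0.05))
  dec <- build_decision_network(cfg)
  wins <- vapply(1:8, function(s) {
    sp <- surrogate_spikes(rep(8, 320), seed = s)
    run_decision(dec, sp, cfg$integration, seed = 50 + s)$choice
  }, "")
  n_release <- sum(wins == "Release")
  expect_gte(n_release, 1)   # binomial(8, .5): neither pool dominates
  expect_lte(n_release, 7)
})

test_that("urgency alone produces activity and a winner by cue end", {
  cfg <- network_config(master_seed = 2,
                        integration = integration_config(dt = 0.05))
  dec <- build_decision_network(cfg)
  none <- data.frame(neuron = integer(0), time_ms = numeric(0))
  out <- run_decision(dec, none, cfg$integration, seed = 11)
  expect_gt(max(out$readout_rates), 10)
  expect_true(out$choice %in% c("Release", "Hold"))
})

test_that("reward updates touch only eligible cells of the winning pool", {
  cfg <- network_config(master_seed = 1)
  dec <- build_decision_network(cfg)
  rates <- c(20, 0, 5, rep(0, 317))   # cell 2 silent, cell 3 active
  rcfg <- reward_rule_config(eta = 0.01)
  up <- da_reward_update(dec, rates, "Release", correct = TRUE, rcfg)
  expect_equal(up$afferents[2, ], dec$afferents[2, ])       # silent cell
  expect_true(all(up$afferents[1, up$e1] > dec$afferents[1, up$e1]))
  expect_equal(up$afferents[1, up$e2], dec$afferents[1, up$e2])  # loser
  down <- da_reward_update(dec, rates, "Hold", correct = FALSE, rcfg)
  expect_true(all(down$afferents[1, down$e2] < dec$afferents[1, dec$e2]))
  expect_equal(down$afferents[1, down$e1], dec$afferents[1, dec$e1])
  # weights never go negative
  strong <- reward_rule_config(eta = 10)
  neg <- da_reward_update(dec, rates, "Hold", correct = FALSE, strong)
  expect_true(all(neg$afferents >= 0))
  # binary eligibility ignores the rate magnitude
  bin <- da_reward_update(dec, rates, "Release", TRUE,
                          reward_rule_config(eta = 0.01,
                                             eligibility = "binary"))
  expect_equal(unname(bin$afferents[1, 1] - dec$afferents[1, 1]),
               unname(bin$afferents[3, 1] - dec$afferents[3, 1]))
})

test_that("expected afferent drift favors the pool rewarded for a cell's pair", {
  # two-cell toy: an AB-selective cell is active (20 Hz) on AB trials
  # where Release usually wins and is rewarded, and rarely active
  # elsewhere; its Release afferent must drift up relative to Hold
  cfg <- network_config(master_seed = 1)
  dec <- build_decision_network(cfg)
  rcfg <- reward_rule_config(eta = 1e-3)
  outcomes <- rep(c("Release", "Hold"), times = c(8, 2))
  correct <- c(rep(TRUE, 8), rep(FALSE, 2))  # Hold on an AB trial is wrong
  for (k in seq_along(outcomes))
    dec <- da_reward_update(dec, c(20, rep(0, 319)), outcomes[k],
                            correct[k], rcfg)
  drift_release <- mean(dec$afferents[1, dec$e1]) - 0.075
  drift_hold <- mean(dec$afferents[1, dec$e2]) - 0.075
  expect_gt(drift_release, 0)
  expect_lt(drift_hold, 0)
})

test_that("reward learning on pair-selective surrogates reaches high accuracy", {
  cfg <- network_config(master_seed = 4,
                        integration = integration_config(dt = 0.05))
  dec <- build_decision_network(cfg)
  pairs <- c("AB", "AD", "CB", "CD")
  sel <- rep(1:4, each = 80)
  seq_tr <- make_trial_sequence(80, seed = 8)
  correct <- logical(80)
  set.seed(99)
  for (k in 1:80) {
    p <- match(seq_tr$pair[k], pairs)
    rates <- ifelse(sel == p, 20, 2)
    sp <- surrogate_spikes(rates, seed = 7000 + k)
    out <- run_decision(dec, sp, cfg$integration, seed = 1000 + k)
    correct[k] <- out$choice == seq_tr$correct_response[k]
    dec <- da_reward_update(dec, rates, out$choice, correct[k])
  }
  expect_gt(mean(correct[41:80]), 0.7)
})
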