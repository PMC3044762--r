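test_that("selectivity metric matches its defining cases", {
  expect_equal(selectivity(c(10, 10, 10, 10)), 0)
  expect_equal(selectivity(c(12, 0, 0, 0)), 3)
  expect_equal(selectivity(c(8, 8, 0, 0)), 1)
  # linear single-stimulus cell and linear two-stimulus cell both score 1
  for (ra in c(0.5, 7, 31)) {
    expect_equal(selectivity(c(ra, ra, 0, 0)), 1)
    for (rb in c(2, 11)) {
      expect_equal(selectivity(c(ra + rb, ra, rb, 0)), 1)
    }
  }
  expect_equal(selectivity(c(0, 0, 0, 0)), 0)  # silent cell
  expect_error(selectivity(c(-1, 1, 1, 1)), "nonnegative")
})

test_that("selectivity is bounded in [0, 3] and scale invariant", {
  set.seed(42)
  for (k in 1:200) {
    r <- runif(4, 0, 50) * rbinom(4, 1, 0.7)
    s <- selectivity(r)
    expect_gte(s, 0)
    expect_lte(s, 3)
    if (any(r > 0)) {
      expect_equal(selectivity(3.7 * r), s)
      expect_equal(selectivity(sample(r)), s)  # column permutation
    }
  }
})

test_that("network selectivity averages all cells or active cells only", {
  rates <- rbind(matrix(rep(c(12, 0, 0, 0), 5), 5, 4, byrow = TRUE),
                 matrix(0, 5, 4))
  res_all <- network_selectivity(rates, "all")
  res_act <- network_selectivity(rates, "active_only")
  expect_equal(res_all$mean, 1.5)
  expect_equal(res_act$mean, 3)
  expect_equal(res_act$n_used, 5)
  uniform <- matrix(10, 7, 4)
  expect_equal(network_selectivity(uniform)$mean, 0)
})

test_that("performance binning and classification use the stated thresholds", {
  ok <- c(rep(TRUE, 34), rep(FALSE, 6))          # 85%: reliable boundary
  expect_equal(performance_bins(ok)$classification, "reliable")
  ok2 <- c(rep(TRUE, 30), rep(FALSE, 10))        # 75%: unreliable
  pb2 <- performance_bins(ok2)
  expect_equal(pb2$final, 0.75)
  expect_equal(pb2$classification, "unreliable")
  ok3 <- c(rep(TRUE, 32), rep(FALSE, 8))         # 80%: borderline
  expect_equal(performance_bins(ok3)$classification, "borderline")
  expect_equal(performance_bins(rep(TRUE, 80))$fraction_correct, c(1, 1))
  # binning conserves counts
  set.seed(1)
  x <- runif(200) < 0.6
  pb <- performance_bins(x, bin = 40)
  expect_equal(sum(pb$fraction_correct * 40), sum(x[1:200]))
})

test_that("selectivity-change classification uses the 5% rule", {
  expect_equal(classify_change(1.00, 1.10), "improved")
  expect_equal(classify_change(1.00, 1.04), "unchanged")
  expect_equal(classify_change(1.00, 0.96), "unchanged")
  expect_equal(classify_change(1.00, 0.90), "worsened")
  expect_equal(classify_change(0, 0.2), "improved")
  expect_equal(classify_change(0, 0), "unchanged")
})

test_that("group weight matrix localizes changes and marks empty groups", {
  set.seed(3)
  n_pre <- 12; n_post <- 20
  mask <- matrix(TRUE, n_pre, n_post)
  w0 <- matrix(0.05, n_pre, n_post)
  pref_pre <- rep(1:4, each = 3)
  pref_post <- rep(1:4, each = 5)
  expect_true(all(group_weight_matrix(w0, w0, mask, pref_pre,
                                      pref_post)$delta == 0))
  # raise only AB(pre) -> AD(post) synapses by 0.1
  w1 <- w0
  w1[pref_pre == 1, pref_post == 2] <- w0[pref_pre == 1,
                                          pref_post == 2] + 0.1
  gw <- group_weight_matrix(w0, w1, mask, pref_pre, pref_post)
  expect_equal(gw$delta["AB", "AD"], 0.1)
  expect_equal(sum(gw$delta != 0), 1)
  expect_equal(gw$delta_diagsub["AB", "AD"], 0.1)
  # empty pre group -> NA row, not zero
  gw2 <- group_weight_matrix(w0, w1, mask, rep(1:3, each = 4), pref_post)
  expect_true(all(is.na(gw2$delta["CD", ])))
})

test_that("preferred pair assignment is argmax with lowest-index ties", {
  rates <- rbind(c(1, 5, 2, 0), c(3, 3, 1, 1), c(0, 0, 0, 9))
  expect_equal(preferred_pair(rates), c(2L, 1L, 4L))
})

test_that("cross-correlogram counts coincidences at the right lags", {
  a <- c(10, 50, 90)
  cc <- cross_correlogram(a, a, max_lag = 20, bin_width = 2)
  expect_equal(cc$counts[cc$lag == 0], 3)   # self pairs at lag 0
  expect_equal(sum(cc$counts), 3)
  cc5 <- cross_correlogram(a, a + 5, max_lag = 20, bin_width = 1)
  expect_equal(cc5$counts[cc5$lag == 5], 3)
  expect_equal(sum(cross_correlogram(numeric(0), a)$counts), 0)
  # count conservation: all pairs within the window
  set.seed(7)
  x <- sort(runif(60, 0, 1000)); y <- sort(runif(50, 0, 1000))
  cc2 <- cross_correlogram(x, y, max_lag = 50, bin_width = 2)
  n_pairs <- sum(abs(outer(y, x, "-")) <= 50)
  expect_equal(sum(cc2$counts), n_pairs)
  # independent Poisson trains: roughly flat histogram
  set.seed(8)
  x <- sort(runif(2000, 0, 1e5)); y <- sort(runif(2000, 0, 1e5))
  cc3 <- cross_correlogram(x, y, max_lag = 50, bin_width = 10)
  expect_lt(max(cc3$counts) / max(mean(cc3$counts), 1), 1.5)
})

test_that("sigmoid fit recovers noiseless parameters and flags degenerate data", {
  x <- seq(0, 2.5, length.out = 30)
  y <- 50 + 50 / (1 + exp(-(x - 1) / 0.2))
  fit <- sigmoid_fit(x, y)
  expect_equal(unname(coef(fit)[["x0"]]), 1, tolerance = 1e-4)
  expect_equal(unname(coef(fit)[["delta"]]), 0.2, tolerance = 1e-4)
  expect_gt(fit$r_squared, 0.9999)
  expect_equal(predict(fit, newdata = 1), 75)       # y at x0
  expect_equal(predict(fit, newdata = 1e6), 100)    # asymptote
  expect_error(sigmoid_fit(x, rep(80, 30)), "degenerate")
})
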