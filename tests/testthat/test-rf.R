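test_that("input gradients of a near-linear network equal its weight product", {
  # push both dense layers deep into Swish's linear regime: swish(x + c) ~ x + c
  # for large positive c, so the network composes to an affine map whose
  # input gradient is W1 W2 W3 W4
  set.seed(12)
  w <- list(
    W1 = matrix(rnorm(50 * 20, sd = 0.05), 50, 20),
    b1 = rep(0, 20),
    W2 = matrix(rnorm(20 * 64, sd = 0.05), 20, 64),
    b2 = rep(40, 64),
    W3 = matrix(rnorm(64 * 64, sd = 0.02), 64, 64),
    b3 = rep(40, 64),
    W4 = matrix(rnorm(64, sd = 0.05), 64, 1),
    b4 = 0
  )
  lin <- w$W1 %*% w$W2 %*% w$W3 %*% w$W4
  X <- matrix(rnorm(20 * 50), 20, 50)
  g <- thermoplaid:::nn_input_grad(w, X)
  for (i in 1:20) expect_equal(g[i, ], drop(lin), tolerance = 1e-4)
})

test_that("extracted receptive field recovers the generative kernels", {
  pol <- generative_policy()
  m <- fixture_encoder()
  rf <- extract_rf(m, fixture_inputs(), seed = 6)
  expect_equal(rf$p_bar, m$p_bar)
  expect_equal(rf$lp_bar, log(rf$p_bar / (1 - rf$p_bar)))
  # smoke check at small scale: the refractory structure already emerges
  # (full-scale recovery is asserted in the acceptance suite)
  expect_gt(cor(rf$bout_coeffs, pol$bout_kernel), 0.5)
  expect_error(extract_rf(lm(y ~ x, list(y = 1:3, x = 1:3)), fixture_inputs()),
    class = "simpleError"
  )
})

test_that("backpropagated input gradients match finite differences", {
  m <- fixture_encoder()
  inp <- inputs_subset(fixture_inputs(), 1:100)
  g <- thermoplaid:::nn_input_grad(m$weights, thermoplaid:::encoder_design(m, inp))
  hb <- m$history_bins
  g[, 1:hb] <- g[, 1:hb] / m$temp_sd
  fd <- finite_difference_grad(m, inp)
  expect_lt(max(abs(g - fd)) / max(abs(g)), 1e-4)
})

test_that("probability modulation follows the logistic transform", {
  expect_equal(bout_probability_modulation(0, 0.04), 0)
  p_bar <- 0.04
  dlp <- -qlogis(p_bar) # 3.1780538
  expect_equal(bout_probability_modulation(dlp, p_bar), 0.46)
  expect_equal(bout_probability_modulation(dlp, p_bar) * 25, 11.5)
  # floor at minus the mean rate
  expect_equal(bout_probability_modulation(-1e9, p_bar), -p_bar)
  expect_error(bout_probability_modulation(0, 1.2), "p_bar")
})

test_that("logistic modulation agrees with an independent tanh formulation", {
  # independent oracle: plogis(x) = (1 + tanh(x / 2)) / 2
  set.seed(77)
  p_bar <- runif(1000, 0.001, 0.5)
  dlp <- runif(1000, -8, 8)
  oracle <- (1 + tanh((dlp + log(p_bar / (1 - p_bar))) / 2)) / 2 - p_bar
  expect_equal(bout_probability_modulation(dlp, p_bar), oracle,
    tolerance = 1e-10
  )
})

test_that("rf_effect centers the modulation around the mean rate", {
  rf <- structure(
    list(
      temp_coeffs = default_temp_kernel(), bout_coeffs = rep(0, 25),
      p_bar = 0.04, lp_bar = qlogis(0.04), bin_rate = 25,
      history_bins = 25, n_eval = NA
    ),
    class = "receptive_field"
  )
  set.seed(8)
  stim <- 26.5 + as.numeric(arima.sim(list(ar = 0.95), 2000, sd = 0.05))
  eff <- rf_effect(rf, stim)
  expect_lt(abs(mean(eff$dlp)), 0.2 * sd(eff$dlp)) # centered modulation
  expect_lt(abs(mean(eff$dp)), 0.2 * sd(eff$dp))
  expect_equal(eff$dbf_hz, eff$dp * 25)
  # zero kernel: no modulation at all
  rf0 <- rf
  rf0$temp_coeffs <- rep(0, 25)
  expect_lt(max(abs(rf_effect(rf0, stim)$dbf_hz)), 1e-12)
})

test_that("modulation summaries compare paired receptive-field effects", {
  rf <- structure(
    list(
      temp_coeffs = 0.05 * default_temp_kernel(), bout_coeffs = rep(0, 25),
      p_bar = 0.04, lp_bar = qlogis(0.04), bin_rate = 25,
      history_bins = 25, n_eval = NA
    ),
    class = "receptive_field"
  )
  half <- rf
  half$temp_coeffs <- rf$temp_coeffs / 2
  set.seed(14)
  stims <- lapply(1:6, function(i) 26.5 + cumsum(rnorm(1500, 0, 0.02)))
  same <- rf_modulation_summary(rf, rf, stims)
  expect_true(all(same$sd_pairs$sd_a == same$sd_pairs$sd_b))
  expect_equal(same$test$p_value, 1)
  sc <- rf_modulation_summary(rf, half, stims)
  # logistic is locally linear at small modulation: SD ratio tracks the scale
  expect_equal(sc$sd_pairs$sd_b / sc$sd_pairs$sd_a, rep(0.5, 6),
    tolerance = 0.05
  )
  expect_equal(sc$test$statistic, 0) # all pairs on one side of identity
})

test_that("per-lag comparisons use rank sums with Bonferroni correction", {
  mk <- function(temp) {
    structure(
      list(
        temp_coeffs = temp, bout_coeffs = rep(0, 25), p_bar = 0.04,
        lp_bar = qlogis(0.04), bin_rate = 25, history_bins = 25, n_eval = NA
      ),
      class = "receptive_field"
    )
  }
  set.seed(3)
  a <- lapply(1:10, function(i) mk(rnorm(25, 0, 0.1)))
  same <- compare_rf_timepoints(a, a)
  expect_true(all(same$p_adj == 1))
  # one lag displaced by 10 pooled SDs separates completely
  b <- lapply(1:10, function(i) {
    k <- rnorm(25, 0, 0.1)
    k[7] <- k[7] + 1.0
    mk(k)
  })
  cmp <- compare_rf_timepoints(a, b)
  expect_lt(cmp$p_adj[7], 0.001)
  expect_true(all(cmp$p_adj[-7] > 0.05))
  expect_equal(cmp$p_adj, pmin(cmp$p_raw * 25, 1))
  expect_error(compare_rf_timepoints(a[1:2], b), "at least 3")
})

test_that("bootstrap bands of null fits straddle zero", {
  mk <- function() {
    structure(
      list(
        temp_coeffs = rnorm(25, 0, 0.05), bout_coeffs = rnorm(25, 0, 0.05),
        p_bar = 0.04, lp_bar = qlogis(0.04), bin_rate = 25,
        history_bins = 25, n_eval = NA
      ),
      class = "receptive_field"
    )
  }
  set.seed(42)
  fits <- lapply(1:30, function(i) mk())
  ci <- rf_bootstrap_ci(fits, n_boot = 500, seed = 2)
  expect_equal(nrow(ci), 50)
  expect_gt(mean(ci$lo <= 0 & ci$hi >= 0), 0.9)
})
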