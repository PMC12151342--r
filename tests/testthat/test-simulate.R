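test_that("zero-kernel policy yields a homogeneous Bernoulli bout process", {
  pol <- generative_policy(
    temp_kernel = rep(0, 25), bout_kernel = rep(0, 25),
    base_logit = qlogis(0.04)
  )
  ex <- simulate_fish(pol, field = plaid_field(), duration_s = 600, seed = 11)
  n_bins <- 600 * 25
  n_starts <- nrow(true_bouts(ex))
  se <- sqrt(n_bins * 0.04 * 0.96)
  expect_lt(abs(n_starts - n_bins * 0.04), 3 * se) # 1 bout/s target
})

test_that("simulation is bitwise reproducible under a fixed seed", {
  pol <- generative_policy()
  a <- simulate_fish(pol, field = plaid_field(), duration_s = 60, seed = 7)
  b <- simulate_fish(pol, field = plaid_field(), duration_s = 60, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(true_bouts(a), true_bouts(b))
  c <- simulate_fish(pol, field = plaid_field(), duration_s = 60, seed = 8)
  expect_false(identical(a$x, c$x))
})

test_that("replay decouples temperature from position", {
  pol <- generative_policy()
  ex <- simulate_fish(pol,
    cal = calibration(), duration_s = 60, seed = 3,
    replay_temp = rep(25, 15000)
  )
  expect_true(all(ex$temp_c == 25))
  expect_gt(max(abs(diff(ex$x))), 0) # the fish still moves
  expect_identical(attr(ex, "condition"), "replay")
})

test_that("virtual fish stays inside the arena", {
  ex <- fixture_experiments()[[1]]
  expect_true(all(sqrt(ex$x^2 + ex$y^2) <= 50 + 1e-9))
})

test_that("replay pairing shares the exact temperature trace", {
  pol <- generative_policy()
  pl <- fixture_experiments()[[1]]
  pair <- make_replay_pair(pl, policy = pol, seed = 21)
  expect_identical(pair$replay$temp_c, pl$temp_c)
  # idempotence: replaying a replay hands on the same trace again
  pair2 <- make_replay_pair(pair$replay, policy = pol, seed = 22)
  expect_identical(pair2$replay$temp_c, pl$temp_c)
  # position determines temperature in plaid but not in replay
  field_pred <- function(ex) {
    power_to_temperature(calibration(), power_at(plaid_field(), ex$x, ex$y))
  }
  expect_equal(cor(pl$temp_c, field_pred(pl)), 1, tolerance = 1e-10)
  expect_lt(abs(cor(pair$replay$temp_c, field_pred(pair$replay))), 0.8)
})

test_that("synthetic tail traces drive vigor as designed", {
  none <- tibble::tibble(start_frame = integer(0), end_frame = integer(0))
  expect_identical(synth_tail_trace(none, 100, noise_sd = 0), rep(0, 100))
  one <- tibble::tibble(start_frame = 200L, end_frame = 240L)
  tr <- synth_tail_trace(one, 500, beat_amplitude = 0.5, noise_sd = 0)
  v <- swim_vigor(tr)
  expect_gt(max(v[205:240]), 0.1) # inside the bout
  expect_true(all(v[1:199] == 0))
  overlapping <- tibble::tibble(
    start_frame = c(10L, 30L),
    end_frame = c(50L, 60L)
  )
  expect_error(synth_tail_trace(overlapping, 100), "overlap")
  # baseline jitter alone stays below the detection threshold
  noise <- synth_tail_trace(none, 75000, noise_sd = 0.01, seed = 5)
  expect_lt(max(swim_vigor(noise)), 0.1)
})

test_that("neuron models gate on coincidence and decay with the calcium kernel", {
  flat <- simulate_neurons(
    tibble::tibble(
      id = 1, type = "additive", ws = 1, wm = 1, wc = 0,
      rectified = FALSE, tau_s = 2, noise_sd = 0, mixed = FALSE
    ),
    temperature = rep(26, 50), bouts = rep(0, 50), seed = 1
  )
  expect_true(all(flat == 0))

  coin <- tibble::tibble(
    id = 1, type = "coincidence", ws = 0, wm = 0, wc = 2,
    rectified = FALSE, tau_s = 2, noise_sd = 0, mixed = TRUE
  )
  bouts <- c(rep(0, 20), 1, rep(0, 29))
  const <- simulate_neurons(coin, rep(26, 50), bouts, seed = 1)
  expect_true(all(const == 0)) # bout without temperature change
  ramp <- simulate_neurons(coin, 26 + seq(0, 4.9, by = 0.1), bouts, seed = 1)
  expect_gt(ramp[21, 1], 0) # bout during a ramp responds

  motor <- tibble::tibble(
    id = 1, type = "motor", ws = 0, wm = 1, wc = 0,
    rectified = FALSE, tau_s = 2, noise_sd = 0, mixed = FALSE
  )
  act <- simulate_neurons(motor, rep(26, 50), bouts, rate = 5, seed = 1)
  expect_equal(act[31, 1] / act[21, 1], exp(-1), tolerance = 1e-10)

  expect_error(simulate_neurons(motor[0, ], rep(26, 5), rep(0, 5)), "empty")
  bad <- motor
  bad$tau_s <- 0
  expect_error(simulate_neurons(bad, rep(26, 5), rep(0, 5)), "tau")
})

test_that("experiments round-trip through flat files", {
  ex <- fixture_experiments()[[1]]
  dir <- withr::local_tempdir()
  write_experiment(ex, dir)
  back <- read_experiment(dir, attr(ex, "id"))
  expect_equal(back$temp_c, ex$temp_c)
  expect_equal(attr(back, "condition"), "plaid")
  expect_equal(
    as.data.frame(true_bouts(back)),
    as.data.frame(true_bouts(ex))
  )
  b <- extract_bouts(ex)
  p <- file.path(dir, "bouts.csv")
  write_bout_table(b, p)
  expect_true(all(c("start_s", "displacement_mm", "ibi_s") %in%
    names(readr::read_csv(p, show_col_types = FALSE))))
})
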