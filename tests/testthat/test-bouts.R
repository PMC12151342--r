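test_that("swim vigor matches closed-form windowed SDs", {
  expect_lt(max(swim_vigor(rep(0.3, 100))), 1e-6) # zero up to cumsum rounding
  # alternating +/- a has population SD a in steady state
  alt <- rep(c(0.2, -0.2), 50)
  v <- swim_vigor(alt)
  expect_equal(v[20:100], rep(0.2, 81), tolerance = 1e-12)
  # a single spike inflates exactly `window` trailing frames
  sp <- rep(0, 100)
  sp[50] <- 1
  v <- swim_vigor(sp, window = 10)
  expect_true(all(v[50:59] > 0))
  expect_true(all(v[c(1:49, 60:100)] == 0))
  # brute-force oracle on random data
  x <- rnorm(60)
  vb <- sapply(1:60, function(f) {
    w <- x[max(1, f - 9):f]
    sqrt(mean((w - mean(w))^2))
  })
  expect_equal(swim_vigor(x), vb, tolerance = 1e-12)
  expect_error(swim_vigor(x, window = 1), "window")
})

test_that("threshold crossings open and close bouts", {
  expect_equal(nrow(detect_bouts(rep(0.05, 100))), 0)
  v <- rep(0, 200)
  v[100:139] <- 0.2
  b <- detect_bouts(v)
  expect_equal(b$start_frame, 100L)
  expect_equal(b$end_frame, 140L)
  # vigor above threshold at trace end closes the bout at the final frame
  v2 <- c(rep(0, 50), rep(0.3, 50))
  b2 <- detect_bouts(v2)
  expect_equal(b2$end_frame, 101L)
})

test_that("bout kinematics use 5-frame averages and smallest-angle turns", {
  n <- 60
  traj <- tibble::tibble(x = rep(0, n), y = rep(0, n), heading = rep(0, n))
  b <- tibble::tibble(start_frame = 20L, end_frame = 40L)
  k <- bout_kinematics(traj, b)
  expect_equal(k$displacement_mm, 0)
  expect_equal(k$turn_deg, 0)
  # 3-4-5 triangle
  traj2 <- traj
  traj2$x[40:n] <- 3
  traj2$y[40:n] <- 4
  expect_equal(bout_kinematics(traj2, b)$displacement_mm, 5)
  # heading wrap: 170 deg to -170 deg is a 20 deg turn
  traj3 <- traj
  traj3$heading[1:19] <- 170 * pi / 180
  traj3$heading[40:n] <- -170 * pi / 180
  expect_equal(bout_kinematics(traj3, b)$turn_deg, 20, tolerance = 1e-8)
  # invariance to adding full turns to all headings
  traj4 <- traj3
  traj4$heading <- traj4$heading + 4 * pi
  expect_equal(
    bout_kinematics(traj4, b)$turn_deg,
    bout_kinematics(traj3, b)$turn_deg
  )
  # too close to the boundary: timing kept, kinematics flagged
  b_edge <- tibble::tibble(start_frame = 3L, end_frame = 10L)
  k_edge <- bout_kinematics(traj, b_edge)
  expect_false(k_edge$kinematics_ok)
  expect_true(is.na(k_edge$displacement_mm))
})

test_that("edge filter removes bouts starting within the wall margin", {
  traj <- tibble::tibble(x = c(0, 47, 45.9), y = c(0, 0, 0))
  b <- tibble::tibble(start_frame = 1:3, end_frame = 2:4)
  kept <- edge_filter(b, traj, arena_radius_mm = 50, margin_mm = 4)
  expect_equal(kept$start_frame, c(1L, 3L))
  expect_equal(nrow(edge_filter(b, traj, margin_mm = 0)), 3)
  expect_error(edge_filter(b, traj, margin_mm = 50), "margin")
})

test_that("per-bout temperature changes follow a linear ramp exactly", {
  r <- 0.001
  temp <- 25 + r * (0:9999)
  b <- tibble::tibble(
    start_frame = c(100L, 900L, 5000L),
    end_frame = c(140L, 950L, 5030L)
  )
  d <- per_bout_delta_t(b, temp, seed = 4)
  len <- b$end_frame - b$start_frame
  expect_equal(d$delta_t[d$interval == "bout"], r * len)
  expect_equal(d$delta_t[d$interval == "control"], r * len)
  expect_error(per_bout_delta_t(b[0, ], temp), "empty")
  # constant temperature: both samples identically zero
  d0 <- per_bout_delta_t(b, rep(26, 10000), seed = 4)
  expect_true(all(d0$delta_t == 0))
})

test_that("detection recovers separable synthetic bouts with no false alarms", {
  # Monte-Carlo bout trains with interbout gaps; a threshold detector cannot
  # split back-to-back bouts, so separability is part of the construction
  set.seed(19)
  hits <- 0
  total <- 0
  for (rep in 1:5) {
    starts <- cumsum(sample(150:500, 60, replace = TRUE))
    ends <- starts + sample(25:50, 60, replace = TRUE)
    tb <- tibble::tibble(start_frame = starts, end_frame = ends)
    n <- max(ends) + 200
    tr <- synth_tail_trace(tb, n, noise_sd = 0.02)
    det <- detect_bouts(swim_vigor(tr))
    near <- vapply(
      tb$start_frame,
      function(s) min(abs(det$start_frame - s)), numeric(1)
    )
    hits <- hits + sum(near <= 2)
    total <- total + nrow(tb)
    # false positives: every detection lies inside a true bout's span
    # (a mid-bout vigor dip may split one bout into two detections)
    claimed <- vapply(
      det$start_frame,
      function(s) min(abs(tb$start_frame - s)), numeric(1)
    )
    expect_true(all(claimed <= 60))
  }
  expect_gte(hits / total, 0.95)
})

test_that("vigor and detection commute with time reversal up to alignment", {
  ex <- fixture_experiments()[[1]]
  tr <- ex$tail_angle[1:5000]
  fwd <- detect_bouts(swim_vigor(tr))
  rev_b <- detect_bouts(swim_vigor(rev(tr)))
  expect_equal(nrow(fwd), nrow(rev_b))
  # mirrored starts agree with forward ends within one window length
  mirrored <- sort(5000 - rev_b$end_frame + 2L)
  expect_true(all(abs(sort(fwd$start_frame) - mirrored) <= 10))
})
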