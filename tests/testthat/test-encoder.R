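# minimal experiment scaffold: constant-rate frames with a chosen binned
# temperature trace and explicit bout table
toy_experiment <- function(temp_bin, id = "toy") {
  fpb <- 10
  frames <- tibble::tibble(temp_c = rep(temp_bin, each = fpb))
  structure(frames,
    class = c("fish_experiment", class(frames)),
    id = id, frame_rate = 250, bin_rate = 25
  )
}

test_that("history design matrices keep strict causality", {
  n_bins <- 120
  k <- 60 # a single bout ends in bin k
  ex <- toy_experiment(rep(26, n_bins))
  bouts <- tibble::tibble(
    start_frame = (k - 4) * 10 + 1L, # first frame of bin k - 3
    end_frame = k * 10 + 1L # last frame in bin k (half-open)
  )
  inp <- build_inputs(ex, bouts = bouts)
  expect_equal(inp$history_bins, 25)
  # sample rows are indexed by bin 26..n_bins
  row_of <- function(b) which(inp$bin == b)
  expect_equal(inp$bout_hist[row_of(k + 1), 1], 1) # most recent lag
  expect_equal(inp$bout_hist[row_of(k + 25), 25], 1) # oldest lag
  expect_equal(sum(inp$bout_hist[row_of(k + 26), ]), 0) # fell out of window
  expect_equal(sum(inp$bout_hist[row_of(k), ]), 0) # never its own predictor
  # labels mark the start bin
  expect_equal(inp$labels[row_of(k - 3)], 1)
  expect_equal(sum(inp$labels), 1)
  # constant temperature gives constant history rows
  expect_true(all(inp$temp_hist == 26))
  # no bouts: all labels and bout history zero
  inp0 <- build_inputs(ex, bouts = bouts[0, ])
  expect_true(all(inp0$labels == 0) && all(inp0$bout_hist == 0))
})

test_that("circular permutation conserves labels and composes to identity", {
  inp <- fixture_inputs()
  rot <- circular_permutation_control(inp, 1 / 3)
  expect_equal(sum(rot$labels), sum(inp$labels))
  expect_false(identical(rot$labels, inp$labels))
  # an even sample count makes two half rotations an exact identity
  ex <- toy_experiment(rep(26, 225)) # 200 samples after the history window
  bouts <- tibble::tibble(
    start_frame = c(301L, 1201L),
    end_frame = c(341L, 1241L)
  )
  inp2 <- build_inputs(ex, bouts = bouts)
  twice <- circular_permutation_control(
    circular_permutation_control(inp2, 1 / 2), 1 / 2
  )
  expect_identical(twice$labels, inp2$labels)
  expect_error(circular_permutation_control(inp2, 1e-9), "identity")
})

test_that("midrank ROC-AUC matches enumeration and an independent library", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.8, 0.3), c(1, 1, 0, 0)), 0.75)
  set.seed(9)
  sc <- round(rnorm(200), 1) # coarse scores force ties
  lb <- rbinom(200, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc,
    quiet = TRUE,
    direction = "<"
  )))
  expect_equal(roc_auc(sc, lb), ref, tolerance = 1e-12)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("training is deterministic and the loss decreases", {
  m1 <- fixture_encoder()
  m2 <- train_encoder(fixture_inputs(), epochs = 30, batch = 256, lr = 2e-3, seed = 3)
  expect_identical(m1$weights, m2$weights)
  expect_identical(
    predict(m1, fixture_inputs()),
    predict(m2, fixture_inputs())
  )
  lh <- m1$loss_history
  expect_lt(mean(utils::tail(lh, 3)), mean(utils::head(lh, 3)))
  expect_gt(evaluate_roc_auc(m1, fixture_inputs()), 0.6)
})

test_that("labels decoupled from inputs score near chance", {
  inp <- fixture_inputs()
  set.seed(31)
  shuf <- inp
  shuf$labels <- sample(inp$labels)
  m <- train_encoder(shuf, epochs = 6, batch = 1024, seed = 5)
  expect_gt(evaluate_roc_auc(m, shuf), 0.40)
  expect_lt(evaluate_roc_auc(m, shuf), 0.60)
})

test_that("single-class labels are rejected", {
  inp <- fixture_inputs()
  bad <- inp
  bad$labels <- rep(0, length(inp$labels))
  expect_error(train_encoder(bad), "single-class")
})

test_that("calibration table reflects predicted probabilities", {
  m <- fixture_encoder()
  inp <- fixture_inputs()
  # constant-output model: zeroed weights leave only the output bias
  const <- m
  const$weights <- lapply(m$weights, function(w) w * 0)
  const$weights$b4 <- qlogis(0.1)
  qq <- calibration_qq(const, inp, n_bins = 10, use = "all")
  occupied <- qq[!is.na(qq$pred_mean), ]
  expect_equal(nrow(occupied), 1)
  expect_equal(occupied$pred_mean, 0.1, tolerance = 1e-6)
  expect_equal(occupied$emp_prop, mean(inp$labels), tolerance = 1e-12)
  # trained model: bins ordered in probability, proportions increase overall
  qq2 <- calibration_qq(m, inp, n_bins = 8, use = "all")
  ok <- !is.na(qq2$pred_mean)
  expect_gt(
    cor(qq2$pred_mean[ok], qq2$emp_prop[ok], method = "spearman"), 0.5
  )
})
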