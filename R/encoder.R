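#' Build history design inputs for the swim-probability encoder
#'
#' Converts experiments into one sample per 40 ms bin: a trailing
#' one-second temperature history (25 bins, most recent lag first), a
#' trailing one-second bout-end history (binary), and a binary label marking
#' whether a swim bout starts in the current bin. History bins are strictly
#' causal: the current bin never appears among its own predictors.
#'
#' @param experiments A `fish_experiment` or list of them.
#' @param bouts Optional bout tibble or list of tibbles (half-open frame
#'   indices), one per experiment. By default bouts are extracted with
#'   [extract_bouts()]; pass [true_bouts()] tables to bypass detection.
#' @param bin_rate Policy bin rate in Hz.
#' @param history_s History window length in seconds.
#' @return An object of class `design_inputs`: temperature-history matrix,
#'   bout-history matrix, labels, experiment ids and bin bookkeeping.
#' @export
build_inputs <- function(experiments, bouts = NULL, bin_rate = 25,
                         history_s = 1.0) {
  if (inherits(experiments, "fish_experiment")) experiments <- list(experiments)
  if (!is.null(bouts) && is.data.frame(bouts)) bouts <- list(bouts)
  hb <- round(history_s * bin_rate)
  parts <- purrr::map2(experiments, seq_along(experiments), function(ex, i) {
    fr <- attr(ex, "frame_rate") %||% 250
    fpb <- fr / bin_rate
    n_bins <- floor(nrow(ex) / fpb)
    if (n_bins <= hb) stop("history window longer than experiment")
    b <- if (is.null(bouts)) extract_bouts(ex) else bouts[[i]]
    temp_bin <- colMeans(matrix(ex$temp_c[seq_len(n_bins * fpb)], nrow = fpb))
    start_bin <- pmin(ceiling(b$start_frame / fpb), n_bins)
    end_bin <- pmin(ceiling((b$end_frame - 1L) / fpb), n_bins)
    labels <- numeric(n_bins)
    labels[start_bin] <- 1
    bout_end <- numeric(n_bins)
    bout_end[end_bin] <- 1
    # embed() row t holds (v[t], v[t-1], ..., v[t-hb]); drop the current bin
    th <- stats::embed(temp_bin, hb + 1)[, -1, drop = FALSE]
    bh <- stats::embed(bout_end, hb + 1)[, -1, drop = FALSE]
    smp <- (hb + 1):n_bins
    list(
      temp_hist = th, bout_hist = bh, labels = labels[smp],
      exp_id = rep(attr(ex, "id") %||% paste0("exp", i), length(smp)),
      bin = smp
    )
  })
  structure(
    list(
      temp_hist = do.call(rbind, purrr::map(parts, "temp_hist")),
      bout_hist = do.call(rbind, purrr::map(parts, "bout_hist")),
      labels = unlist(purrr::map(parts, "labels")),
      exp_id = unlist(purrr::map(parts, "exp_id")),
      bin = unlist(purrr::map(parts, "bin")),
      bin_rate = bin_rate, history_bins = hb
    ),
    class = "design_inputs"
  )
}

#' @export
print.design_inputs <- function(x, ...) {
  cat(sprintf(
    "<design_inputs> %d samples, %d experiments, %d history bins at %d Hz, label rate %.4f\n",
    length(x$labels), length(unique(x$exp_id)), x$history_bins, x$bin_rate,
    mean(x$labels)
  ))
  invisible(x)
}

#' Subset design inputs by row
#' @param inputs A `design_inputs`.
#' @param idx Integer or logical row index.
#' @export
inputs_subset <- function(inputs, idx) {
  out <- inputs
  out$temp_hist <- inputs$temp_hist[idx, , drop = FALSE]
  out$bout_hist <- inputs$bout_hist[idx, , drop = FALSE]
  out$labels <- inputs$labels[idx]
  out$exp_id <- inputs$exp_id[idx]
  out$bin <- inputs$bin[idx]
  out
}

#' Circular-permutation null control
#'
#' Rotates the labels relative to both input channels, independently within
#' each experiment, by a fixed fraction of the experiment length. This
#' destroys the input-output coupling while preserving the autocorrelation
#' structure and the label marginal, giving a noise floor for encoder
#' performance and receptive fields.
#'
#' @param inputs A `design_inputs`.
#' @param shift_fraction Fraction of each experiment's samples to rotate by.
#' @return A `design_inputs` with permuted labels.
#' @export
circular_permutation_control <- function(inputs, shift_fraction = 1 / 3) {
  out <- inputs
  for (e in unique(inputs$exp_id)) {
    sel <- which(inputs$exp_id == e)
    k <- round(length(sel) * shift_fraction) %% length(sel)
    if (k == 0) stop("shift of zero samples would be the identity")
    l <- inputs$labels[sel]
    out$labels[sel] <- c(l[(k + 1):length(l)], l[1:k])
  }
  out
}

#' Train the convolutional swim-probability encoder
#'
#' Fits the network (one linear convolutional layer of `n_conv` units
#' spanning the full history of both channels, two Swish dense layers of
#' `n_dense` units with dropout after every layer, linear logit output) by
#' minibatch Adam on binary cross-entropy with L2 weight decay. Temperature
#' histories are standardized internally; the stored scale restores
#' receptive-field coefficients to per-degC units. The train/test split is a
#' random contiguous block of `1 - train_frac` of the samples within each
#' experiment, limiting autocorrelation leakage between splits.
#'
#' @param inputs A `design_inputs`.
#' @param n_conv,n_dense Layer widths.
#' @param epochs Training epochs.
#' @param batch Minibatch size.
#' @param lr Adam step size.
#' @param weight_decay L2 penalty coefficient.
#' @param dropout Dropout probability after each layer (training only).
#' @param train_frac Fraction of samples used for training.
#' @param max_train Optional cap on the number of training samples (a random
#'   subset is used beyond it); `Inf` uses all.
#' @param seed Seed controlling initialization, dropout, batching and split.
#' @return An object of class `swim_encoder`.
#' @export
train_encoder <- function(inputs, n_conv = 20, n_dense = 64, epochs = 100,
                          batch = 256, lr = 1e-3, weight_decay = 1e-5,
                          dropout = 0.5, train_frac = 0.8, max_train = Inf,
                          seed = 1) {
  if (length(unique(inputs$labels)) < 2) stop("labels are single-class")
  set.seed(seed)
  n <- length(inputs$labels)
  test_idx <- logical(n)
  for (e in unique(inputs$exp_id)) {
    sel <- which(inputs$exp_id == e)
    n_test <- max(1L, round(length(sel) * (1 - train_frac)))
    off <- sample.int(length(sel) - n_test + 1L, 1)
    test_idx[sel[off:(off + n_test - 1L)]] <- TRUE
  }
  train_idx <- which(!test_idx)
  if (is.finite(max_train) && length(train_idx) > max_train) {
    train_idx <- sort(sample(train_idx, max_train))
  }
  mu <- mean(inputs$temp_hist[train_idx, ])
  sd_t <- stats::sd(inputs$temp_hist[train_idx, ])
  if (sd_t == 0) sd_t <- 1
  X <- cbind((inputs$temp_hist - mu) / sd_t, inputs$bout_hist)
  y <- inputs$labels
  if (length(unique(y[train_idx])) < 2) stop("training split is single-class")

  w <- nn_train(
    X[train_idx, , drop = FALSE], y[train_idx],
    n_conv, n_dense, epochs, batch, lr, weight_decay, dropout
  )
  p_bar <- mean(y[train_idx])
  structure(
    list(
      weights = w[c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")],
      loss_history = as.numeric(w$loss),
      temp_mean = mu, temp_sd = sd_t,
      history_bins = inputs$history_bins, bin_rate = inputs$bin_rate,
      p_bar = p_bar, lp_bar = stats::qlogis(p_bar),
      train_idx = train_idx, test_idx = which(test_idx),
      n_conv = n_conv, n_dense = n_dense, epochs = epochs,
      weight_decay = weight_decay, dropout = dropout, seed = seed
    ),
    class = "swim_encoder"
  )
}

#' @export
print.swim_encoder <- function(x, ...) {
  cat(sprintf(
    "<swim_encoder> conv %d + dense %dx2, %d epochs, p_bar %.4f, final BCE %.4f\n",
    x$n_conv, x$n_dense, x$epochs, x$p_bar, utils::tail(x$loss_history, 1)
  ))
  invisible(x)
}

# design matrix in the model's standardized coordinates
encoder_design <- function(model, inputs) {
  cbind((inputs$temp_hist - model$temp_mean) / model$temp_sd, inputs$bout_hist)
}

#' Predict swim log-odds or probability
#'
#' @param object A `swim_encoder`.
#' @param inputs A `design_inputs`.
#' @param type `"logit"` (the network output) or `"prob"`.
#' @param ... Unused.
#' @export
predict.swim_encoder <- function(object, inputs,
                                 type = c("logit", "prob"), ...) {
  type <- match.arg(type)
  lg <- as.numeric(nn_forward(object$weights, encoder_design(object, inputs)))
  if (type == "prob") stats::plogis(lg) else lg
}

#' ROC-AUC of scores against binary labels
#'
#' Probability that a randomly chosen positive sample scores above a randomly
#' chosen negative one, with ties counted one half (midrank formula).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores) # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Held-out classification performance of an encoder
#'
#' @param model A `swim_encoder`.
#' @param inputs The `design_inputs` to evaluate on.
#' @param use `"test"` restricts to the model's held-out block (valid when
#'   `inputs` is the training design), `"all"` scores every sample.
#' @return ROC-AUC.
#' @export
evaluate_roc_auc <- function(model, inputs, use = c("test", "all")) {
  use <- match.arg(use)
  if (use == "test") inputs <- inputs_subset(inputs, model$test_idx)
  roc_auc(predict(model, inputs), inputs$labels)
}

#' Calibration of predicted swim probabilities
#'
#' Bins samples by model-predicted probability and reports the empirical
#' bout proportion per bin; a perfectly calibrated model lies on the
#' identity.
#'
#' @param model A `swim_encoder`.
#' @param inputs A `design_inputs`.
#' @param n_bins Number of probability bins (equal-count).
#' @param use `"test"` or `"all"` samples.
#' @return Tibble with `bin`, `pred_mean`, `emp_prop`, `n` (empty bins are
#'   `NA`, not zero).
#' @export
calibration_qq <- function(model, inputs, n_bins = 10, use = c("test", "all")) {
  use <- match.arg(use)
  if (use == "test") inputs <- inputs_subset(inputs, model$test_idx)
  p <- predict(model, inputs, type = "prob")
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) br <- c(br - 1e-9, br + 1e-9) # constant predictions
  bin <- cut(p, breaks = br, include.lowest = TRUE)
  tibble::tibble(p = p, y = inputs$labels, bin = bin) |>
    dplyr::group_by(.data$bin, .drop = FALSE) |>
    dplyr::summarise(
      pred_mean = if (dplyr::n() > 0) mean(.data$p) else NA_real_,
      emp_prop = if (dplyr::n() > 0) mean(.data$y) else NA_real_,
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(
      pred_mean = ifelse(.data$n == 0, NA_real_, .data$pred_mean),
      emp_prop = ifelse(.data$n == 0, NA_real_, .data$emp_prop)
    )
}
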