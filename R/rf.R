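#' Extract receptive fields by differentiating the encoder
#'
#' Computes the gradient of the network output (the log-odds of emitting a
#' swim bout) with respect to every input bin, averaged over a random subset
#' of data points. For a network driven by weakly correlated inputs this is
#' the analogue of a spike-triggered average, but it remains unbiased under
#' the strong stimulus autocorrelation of self-generated temperature
#' sequences. Temperature coefficients are returned in log-odds per degC
#' (the internal standardization is undone); bout coefficients are log-odds
#' per bout-end event. A positive temperature coefficient means warmer water
#' at that lag increases swim probability.
#'
#' @param model A trained `swim_encoder`.
#' @param inputs A `design_inputs` providing the expansion points.
#' @param n_eval_samples Number of samples over which gradients are averaged.
#' @param seed Seed for the sample draw.
#' @return An object of class `receptive_field` with `temp_coeffs`,
#'   `bout_coeffs` (one per history lag, most recent first), `p_bar`,
#'   `lp_bar` and `bin_rate`.
#' @export
extract_rf <- function(model, inputs, n_eval_samples = 10000, seed = 1) {
  if (!inherits(model, "swim_encoder")) stop("model must be a trained swim_encoder")
  set.seed(seed)
  n <- length(inputs$labels)
  idx <- if (n > n_eval_samples) sort(sample.int(n, n_eval_samples)) else seq_len(n)
  X <- encoder_design(model, inputs_subset(inputs, idx))
  g <- colMeans(nn_input_grad(model$weights, X))
  hb <- model$history_bins
  structure(
    list(
      temp_coeffs = g[1:hb] / model$temp_sd, # back to per-degC
      bout_coeffs = g[(hb + 1):(2 * hb)],
      p_bar = model$p_bar, lp_bar = model$lp_bar,
      bin_rate = model$bin_rate, history_bins = hb,
      n_eval = length(idx)
    ),
    class = "receptive_field"
  )
}

#' @export
print.receptive_field <- function(x, ...) {
  cat(sprintf(
    "<receptive_field> %d lags at %d Hz, p_bar %.4f, |temp| max %.3f /degC\n",
    x$history_bins, x$bin_rate, x$p_bar, max(abs(x$temp_coeffs))
  ))
  invisible(x)
}

#' Finite-difference input gradient (reference implementation)
#'
#' Central-difference derivative of the encoder logit with respect to each
#' input of the given samples, in the same per-degC / per-event units as
#' [extract_rf()]. Exact backpropagated gradients should agree with this to
#' tight tolerance; it exists as an independent check and for debugging.
#'
#' @param model A `swim_encoder`.
#' @param inputs A `design_inputs` (all rows are used).
#' @param h Step size in standardized input units.
#' @return Matrix of gradients, samples by inputs.
#' @export
finite_difference_grad <- function(model, inputs, h = 1e-4) {
  X <- encoder_design(model, inputs)
  out <- matrix(0, nrow(X), ncol(X))
  for (j in seq_len(ncol(X))) {
    Xp <- X
    Xm <- X
    Xp[, j] <- Xp[, j] + h
    Xm[, j] <- Xm[, j] - h
    out[, j] <- (as.numeric(nn_forward(model$weights, Xp)) -
      as.numeric(nn_forward(model$weights, Xm))) / (2 * h)
  }
  hb <- model$history_bins
  out[, 1:hb] <- out[, 1:hb] / model$temp_sd
  out
}

#' Bout-frequency modulation induced by a receptive field
#'
#' Projects a 25 Hz temperature stimulus onto the temperature receptive
#' field and converts the resulting log-odds modulation into probability and
#' bout-frequency changes around the mean rate:
#' `dlp(t) = k . s(t)`, `dp(t) = plogis(dlp(t) + lp_bar) - p_bar`,
#' `dbf(t) = dp(t) * bin_rate`. The stimulus history `s(t)` is taken as the
#' deviation from the trace mean, so `dlp` averages to zero and `dp`
#' describes modulation around the mean bout rate. `dbf` is floored at
#' `-p_bar * bin_rate` (the rate cannot drop below zero bouts/s).
#'
#' @param rf A `receptive_field`.
#' @param stimulus Temperature trace at the receptive field's bin rate.
#' @return Tibble with `bin`, `dlp`, `dp`, `dbf_hz`.
#' @export
rf_effect <- function(rf, stimulus) {
  if (!(rf$p_bar > 0 && rf$p_bar < 1)) stop("p_bar must lie in (0, 1)")
  hb <- rf$history_bins
  if (length(stimulus) < hb + 1) stop("stimulus shorter than the history window")
  s <- stimulus - mean(stimulus)
  H <- stats::embed(s, hb + 1)[, -1, drop = FALSE] # lag 1..hb, recent first
  dlp <- as.numeric(H %*% rf$temp_coeffs)
  dp <- bout_probability_modulation(dlp, rf$p_bar)
  tibble::tibble(
    bin = (hb + 1):length(stimulus),
    dlp = dlp, dp = dp, dbf_hz = dp * rf$bin_rate
  )
}

#' Log-odds modulation to bout-probability modulation
#'
#' The logistic transform at the heart of the receptive-field effect:
#' `dp = plogis(dlp + qlogis(p_bar)) - p_bar`. At `dlp = 0` the modulation
#' is exactly zero; as `dlp` tends to minus infinity it floors at `-p_bar`.
#'
#' @param dlp Change in log-odds induced by the stimulus.
#' @param p_bar Mean bout probability per bin, in (0, 1).
#' @return Change in bout probability per bin.
#' @export
bout_probability_modulation <- function(dlp, p_bar) {
  if (!all(p_bar > 0 & p_bar < 1)) stop("p_bar must lie in (0, 1)")
  stats::plogis(dlp + stats::qlogis(p_bar)) - p_bar
}

#' Compare stimulus-driven bout-frequency modulation between two receptive fields
#'
#' Applies a closed-loop and an open-loop receptive field to the same set of
#' stimuli (each experiment pair shares one temperature trace), pools the
#' per-time bout-frequency changes for a histogram, and compares the
#' per-experiment standard deviations of the modulation with a paired
#' Wilcoxon signed-rank test. A larger SD means the stimulus swings the
#' predicted bout rate over a wider range under that receptive field.
#'
#' @param rf_a,rf_b `receptive_field`s defined on the same bin rate
#'   (conventionally plaid and replay).
#' @param stimuli List of 25 Hz temperature traces.
#' @return A list of class `rf_modulation_summary`: `dbf` (pooled modulation
#'   traces), `sd_pairs` (per-experiment SD under each field) and `test`
#'   (paired signed-rank comparison, SD under `rf_a` vs `rf_b`).
#' @export
rf_modulation_summary <- function(rf_a, rf_b, stimuli) {
  if (rf_a$bin_rate != rf_b$bin_rate) stop("mismatched bin rates")
  eff <- purrr::imap(stimuli, function(s, i) {
    ea <- rf_effect(rf_a, s)
    eb <- rf_effect(rf_b, s)
    tibble::tibble(
      experiment = as.character(i),
      rf = rep(c("a", "b"), each = nrow(ea)),
      dbf_hz = c(ea$dbf_hz, eb$dbf_hz)
    )
  })
  dbf <- dplyr::bind_rows(eff)
  sd_pairs <- dbf |>
    dplyr::group_by(.data$experiment, .data$rf) |>
    dplyr::summarise(sd_dbf = stats::sd(.data$dbf_hz), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "rf", values_from = "sd_dbf", names_prefix = "sd_")
  d <- sd_pairs$sd_a - sd_pairs$sd_b
  test <- if (all(d == 0)) {
    list(statistic = 0, v = 0, p_value = 1) # identical fields
  } else {
    signed_rank(d)
  }
  structure(list(dbf = dbf, sd_pairs = sd_pairs, test = test),
    class = "rf_modulation_summary"
  )
}

#' @export
print.rf_modulation_summary <- function(x, ...) {
  cat(sprintf(
    "<rf_modulation_summary> %d experiments, median SD a %.4f vs b %.4f Hz, signed-rank p %.3g\n",
    nrow(x$sd_pairs), stats::median(x$sd_pairs$sd_a),
    stats::median(x$sd_pairs$sd_b), x$test$p_value
  ))
  invisible(x)
}

#' Per-lag comparison of receptive fields across fit replicates
#'
#' Rank-sum test at each history lag between two sets of fitted receptive
#' fields, Bonferroni-corrected across the lags. A lag is called significant
#' when the corrected p-value is at most the chosen level.
#'
#' @param rf_fits_a,rf_fits_b Lists of `receptive_field`s (equal length not
#'   required; at least 3 each).
#' @param channel `"temp"` or `"bout"`.
#' @return Tibble with `lag_s`, `p_raw`, `p_adj`.
#' @export
compare_rf_timepoints <- function(rf_fits_a, rf_fits_b,
                                  channel = c("temp", "bout")) {
  channel <- match.arg(channel)
  if (length(rf_fits_a) < 3 || length(rf_fits_b) < 3) {
    stop("need at least 3 fits per condition")
  }
  field <- if (channel == "temp") "temp_coeffs" else "bout_coeffs"
  A <- do.call(rbind, purrr::map(rf_fits_a, field))
  B <- do.call(rbind, purrr::map(rf_fits_b, field))
  hb <- ncol(A)
  bin_rate <- rf_fits_a[[1]]$bin_rate
  p_raw <- purrr::map_dbl(seq_len(hb), function(j) {
    if (stats::var(c(A[, j], B[, j])) == 0) return(1) # all values tied
    suppressWarnings(stats::wilcox.test(A[, j], B[, j])$p.value)
  })
  p_raw[is.na(p_raw)] <- 1
  tibble::tibble(
    lag_s = seq_len(hb) / bin_rate,
    p_raw = p_raw,
    p_adj = pmin(p_raw * hb, 1)
  )
}

#' Bootstrap confidence band of receptive-field coefficients across fits
#'
#' Percentile bootstrap interval of the across-fit mean coefficient at each
#' lag, used to test extracted fields against zero (e.g., after the
#' circular-permutation control, every interval should contain zero).
#'
#' @param rf_fits List of `receptive_field`s.
#' @param level Confidence level.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed.
#' @return Tibble with `channel`, `lag_s`, `mean`, `lo`, `hi`.
#' @export
rf_bootstrap_ci <- function(rf_fits, level = 0.95, n_boot = 2000, seed = 1) {
  set.seed(seed)
  a <- (1 - level) / 2
  res <- purrr::map(c(temp = "temp_coeffs", bout = "bout_coeffs"), function(f) {
    M <- do.call(rbind, purrr::map(rf_fits, f))
    boots <- replicate(n_boot, colMeans(M[sample.int(nrow(M), replace = TRUE), , drop = FALSE]))
    tibble::tibble(
      lag = seq_len(ncol(M)),
      mean = colMeans(M),
      lo = apply(boots, 1, stats::quantile, probs = a),
      hi = apply(boots, 1, stats::quantile, probs = 1 - a)
    )
  })
  bin_rate <- rf_fits[[1]]$bin_rate
  dplyr::bind_rows(res, .id = "channel") |>
    dplyr::mutate(lag_s = .data$lag / bin_rate, .keep = "unused", .before = 2)
}
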