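#' Tidy a receptive field into a long tibble
#'
#' @param x A `receptive_field`.
#' @param ... Unused.
#' @return Tibble with `channel` ("temp"/"bout"), `lag_s`, `estimate`.
#' @method tidy receptive_field
#' @export
tidy.receptive_field <- function(x, ...) {
  lag <- seq_len(x$history_bins) / x$bin_rate
  tibble::tibble(
    channel = rep(c("temp", "bout"), each = x$history_bins),
    lag_s = rep(lag, 2),
    estimate = c(x$temp_coeffs, x$bout_coeffs)
  )
}

#' One-row receptive-field summary
#' @param x A `receptive_field`.
#' @param ... Unused.
#' @method glance receptive_field
#' @export
glance.receptive_field <- function(x, ...) {
  tibble::tibble(
    p_bar = x$p_bar, lp_bar = x$lp_bar, bin_rate = x$bin_rate,
    history_bins = x$history_bins, n_eval = x$n_eval,
    temp_coef_max_abs = max(abs(x$temp_coeffs)),
    bout_coef_max_abs = max(abs(x$bout_coeffs))
  )
}

#' Training-loss history of an encoder
#' @param x A `swim_encoder`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`.
#' @method tidy swim_encoder
#' @export
tidy.swim_encoder <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' One-row encoder summary
#' @param x A `swim_encoder`.
#' @param ... Unused.
#' @method glance swim_encoder
#' @export
glance.swim_encoder <- function(x, ...) {
  tibble::tibble(
    p_bar = x$p_bar, lp_bar = x$lp_bar, epochs = x$epochs,
    final_loss = utils::tail(x$loss_history, 1),
    n_train = length(x$train_idx), n_test = length(x$test_idx),
    weight_decay = x$weight_decay, dropout = x$dropout, seed = x$seed
  )
}

#' Plot receptive-field coefficients against lag
#' @param object A `receptive_field`.
#' @param ... Unused.
#' @method autoplot receptive_field
#' @export
autoplot.receptive_field <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(-.data$lag_s, .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~ .data$channel, scales = "free_y") +
    ggplot2::labs(
      x = "time before bout (s)",
      y = "coefficient (log-odds per unit input)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot encoder training loss
#' @param object A `swim_encoder`.
#' @param ... Unused.
#' @method autoplot swim_encoder
#' @export
autoplot.swim_encoder <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training BCE") +
    ggplot2::theme_minimal()
}

#' Plot per-experiment modulation SDs under two receptive fields
#' @param object An `rf_modulation_summary`.
#' @param ... Unused.
#' @method autoplot rf_modulation_summary
#' @export
autoplot.rf_modulation_summary <- function(object, ...) {
  ggplot2::ggplot(object$sd_pairs, ggplot2::aes(.data$sd_a, .data$sd_b)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::geom_point(colour = "purple3") +
    ggplot2::labs(
      x = "SD of bout-frequency modulation, field A (Hz)",
      y = "SD of bout-frequency modulation, field B (Hz)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a calibration QQ table
#' @param qq Tibble from [calibration_qq()].
#' @export
plot_calibration_qq <- function(qq) {
  ggplot2::ggplot(
    tidyr::drop_na(qq),
    ggplot2::aes(.data$pred_mean, .data$emp_prop)
  ) +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "model-predicted bout probability",
      y = "empirical bout proportion"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the laser-power field over the arena
#' @param field A [plaid_field()].
#' @param arena_radius_mm Arena radius for the mask.
#' @param step Grid step in mm.
#' @export
plot_plaid_field <- function(field, arena_radius_mm = 50, step = 0.5) {
  g <- expand.grid(
    x = seq(-arena_radius_mm, arena_radius_mm, by = step),
    y = seq(-arena_radius_mm, arena_radius_mm, by = step)
  )
  g <- g[g$x^2 + g$y^2 <= arena_radius_mm^2, ]
  g$power <- power_at(field, g$x, g$y)
  ggplot2::ggplot(g, ggplot2::aes(.data$x, .data$y, fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "mW") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
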