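#' Generative swim-initiation policy
#'
#' Ground-truth policy of the virtual fish: in every 40 ms bin the
#' probability of initiating a swim bout is
#' `plogis(base_logit + sum(temp_kernel * temp_dev_history) +
#' sum(bout_kernel * bout_end_history))`, where `temp_dev_history` is the
#' deviation of the binned temperature from `temp_ref` (degC) over the last
#' second and `bout_end_history` marks bins in which a previous bout ended.
#' Kernel element 1 is the most recent lag (40 ms), element
#' `history_bins` the oldest. With both kernels zero, bout initiation is a
#' homogeneous Bernoulli process at rate `plogis(base_logit)` per bin.
#'
#' Kinematics are sampled per bout: duration uniform on
#' `bout_duration_s`, displacement lognormal with median
#' `displacement_median_mm`, turn angle a straight/turn mixture.
#'
#' @param base_logit Baseline log-odds of a bout per 40 ms bin. The default
#'   `qlogis(0.04)` gives a 1 bout/s homogeneous rate.
#' @param temp_kernel Numeric vector of length `history_bins`, log-odds per
#'   degC of temperature deviation at each lag.
#' @param bout_kernel Numeric vector of length `history_bins`, log-odds per
#'   bout-end event at each lag.
#' @param temp_ref Reference temperature (degC) about which deviations are
#'   taken; defaults to the arena midpoint 26.5 degC.
#' @param bout_duration_s Range of bout durations in seconds.
#' @param displacement_median_mm,displacement_sdlog Lognormal displacement
#'   parameters.
#' @param p_straight Probability a bout is a straight swim.
#' @param straight_sd_deg,turn_mean_deg,turn_sd_deg Turn-angle mixture
#'   parameters in degrees.
#' @param bin_rate Policy bin rate in Hz (40 ms bins).
#' @param history_bins Number of history bins (1 s at 25 Hz).
#' @return An object of class `generative_policy`.
#' @export
generative_policy <- function(base_logit = stats::qlogis(0.04),
                              temp_kernel = default_temp_kernel(),
                              bout_kernel = default_bout_kernel(),
                              temp_ref = 26.5,
                              bout_duration_s = c(0.1, 0.2),
                              displacement_median_mm = 2,
                              displacement_sdlog = 0.35,
                              p_straight = 0.7,
                              straight_sd_deg = 5,
                              turn_mean_deg = 30,
                              turn_sd_deg = 10,
                              bin_rate = 25,
                              history_bins = 25) {
  stopifnot(
    length(temp_kernel) == history_bins,
    length(bout_kernel) == history_bins,
    bout_duration_s[1] > 0, bout_duration_s[2] >= bout_duration_s[1]
  )
  structure(
    list(
      base_logit = base_logit, temp_kernel = temp_kernel,
      bout_kernel = bout_kernel, temp_ref = temp_ref,
      bout_duration_s = bout_duration_s,
      displacement_median_mm = displacement_median_mm,
      displacement_sdlog = displacement_sdlog,
      p_straight = p_straight, straight_sd_deg = straight_sd_deg,
      turn_mean_deg = turn_mean_deg, turn_sd_deg = turn_sd_deg,
      bin_rate = bin_rate, history_bins = history_bins
    ),
    class = "generative_policy"
  )
}

#' Default thermosensory kernel
#'
#' Biphasic kernel (log-odds per degC): recent warmth (~80 ms ago) promotes
#' swimming while warmth further in the past (~550 ms) suppresses it, so the
#' virtual fish is effectively sensitive to heating transients.
#'
#' @param history_bins Number of lags.
#' @param bin_rate Bin rate in Hz.
#' @export
default_temp_kernel <- function(history_bins = 25, bin_rate = 25) {
  lag <- seq_len(history_bins) / bin_rate
  0.8 * exp(-((lag - 0.08) / 0.10)^2) - 0.5 * exp(-((lag - 0.55) / 0.18)^2)
}

#' Default bout-history kernel
#'
#' Strong suppression right after a bout ends (refractory period) followed by
#' a mild rebound around 500 ms, shaping interbout intervals into the
#' 0.5-1.8 s range typical of larval zebrafish.
#'
#' @inheritParams default_temp_kernel
#' @export
default_bout_kernel <- function(history_bins = 25, bin_rate = 25) {
  lag <- seq_len(history_bins) / bin_rate
  -6 * exp(-lag / 0.25) + 0.8 * exp(-((lag - 0.5) / 0.15)^2)
}

#' @export
print.generative_policy <- function(x, ...) {
  cat(sprintf(
    "<generative_policy> base rate %.3f/bin (%.2f bouts/s at %d Hz), %d history bins\n",
    stats::plogis(x$base_logit), stats::plogis(x$base_logit) * x$bin_rate,
    x$bin_rate, x$history_bins
  ))
  invisible(x)
}
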