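#' Parameterized mixed-selectivity neuron population
#'
#' Samples a synthetic population of response models spanning four types:
#' sensory-only (driven by the temperature derivative), motor-only (driven
#' by swim bouts), additive (both drives) and coincidence detectors whose
#' response is gated by the product of temperature change and a bout. These
#' are explicit stand-ins for fitted encoding models of real
#' thermosensorimotor neurons: the coincidence term with rectification
#' captures the hallmark of nonlinear mixed selectivity, a response to
#' temperature change only when it co-occurs with a motor event. Responses
#' are low-pass filtered by an exponential calcium kernel.
#'
#' @param n Number of neurons.
#' @param proportions Named numeric vector of type proportions
#'   (`sensory`, `motor`, `additive`, `coincidence`), normalized internally.
#' @param tau_range Calcium kernel time-constant range in seconds.
#' @param noise_sd Gaussian noise SD added to the activity.
#' @param seed Seed.
#' @return Tibble with one row per neuron: weights `ws` (per degC/s), `wm`
#'   (per bout), `wc` (coincidence), `rectified`, `tau_s`, `noise_sd`,
#'   `type`, and `mixed` (`wc != 0` or rectified).
#' @export
neuron_population <- function(n = 200,
                              proportions = c(
                                sensory = 0.2, motor = 0.2,
                                additive = 0.2, coincidence = 0.4
                              ),
                              tau_range = c(1.5, 2.5),
                              noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  pr <- proportions / sum(proportions)
  type <- sample(names(pr), n, replace = TRUE, prob = pr)
  amp <- function(k) stats::runif(k, 0.5, 1.5) * sample(c(-1, 1), k, replace = TRUE)
  ws <- ifelse(type %in% c("sensory", "additive"), amp(n), 0)
  wm <- ifelse(type %in% c("motor", "additive"), amp(n), 0)
  wc <- ifelse(type == "coincidence", stats::runif(n, 1, 3) *
    sample(c(-1, 1), n, replace = TRUE), 0)
  rectified <- type == "coincidence"
  tibble::tibble(
    id = seq_len(n), type = type, ws = ws, wm = wm, wc = wc,
    rectified = rectified,
    tau_s = stats::runif(n, tau_range[1], tau_range[2]),
    noise_sd = noise_sd,
    mixed = wc != 0 | rectified
  )
}

#' Simulate calcium activity of a neuron population
#'
#' Per neuron, the instantaneous drive at 5 Hz is
#' `ws * dT/dt + wm * bout + wc * dT/dt * bout`, optionally rectified at
#' zero, convolved with an exponential calcium kernel of time constant
#' `tau_s` (impulse response decaying to 1/e after `tau_s`), plus Gaussian
#' noise.
#'
#' @param models Tibble from [neuron_population()].
#' @param temperature Temperature trace binned to `rate` Hz (degC).
#' @param bouts Bout raster at `rate` Hz (bout-start counts or 0/1).
#' @param rate Bin rate in Hz.
#' @param seed Seed for the noise.
#' @return Matrix of activity, time bins by neurons.
#' @export
simulate_neurons <- function(models, temperature, bouts, rate = 5, seed = 1) {
  if (nrow(models) == 0) stop("empty model list")
  if (any(models$tau_s <= 0)) stop("calcium kernel tau must be positive")
  if (length(temperature) != length(bouts)) stop("trace lengths differ")
  set.seed(seed)
  n_t <- length(temperature)
  dtdt <- c(0, diff(temperature)) * rate # degC/s
  act <- matrix(0, n_t, nrow(models))
  for (i in seq_len(nrow(models))) {
    drive <- models$ws[i] * dtdt + models$wm[i] * bouts +
      models$wc[i] * dtdt * bouts
    if (models$rectified[i]) drive <- pmax(drive, 0)
    a <- exp(-1 / (rate * models$tau_s[i]))
    act[, i] <- as.numeric(stats::filter(drive, a, method = "recursive"))
  }
  if (any(models$noise_sd > 0)) {
    act <- act + matrix(
      stats::rnorm(n_t * nrow(models), 0, rep(models$noise_sd, each = n_t)),
      n_t, nrow(models)
    )
  }
  act
}

#' Bin an experiment to 5 Hz input channels
#'
#' Produces the four per-bin input channels used both as neuron-model inputs
#' and as raw-input decoder features: mean temperature, bout-start count,
#' summed bout displacement and summed unsigned turn angle.
#'
#' @param experiment A `fish_experiment`.
#' @param bouts Bout tibble with kinematics (defaults to the true bout table
#'   of a simulated experiment).
#' @param rate Bin rate in Hz.
#' @return Tibble with `bin`, `temp`, `bout_start`, `displacement`, `turn`.
#' @export
bin_experiment <- function(experiment, bouts = true_bouts(experiment), rate = 5) {
  fr <- attr(experiment, "frame_rate") %||% 250
  fpb <- fr / rate
  n_bins <- floor(nrow(experiment) / fpb)
  temp <- colMeans(matrix(experiment$temp_c[seq_len(n_bins * fpb)], nrow = fpb))
  bout_start <- numeric(n_bins)
  displacement <- numeric(n_bins)
  turn <- numeric(n_bins)
  if (nrow(bouts) > 0) {
    bb <- pmin(ceiling(bouts$start_frame / fpb), n_bins)
    for (i in seq_along(bb)) {
      bout_start[bb[i]] <- bout_start[bb[i]] + 1
      d <- bouts$displacement_mm[i]
      t <- bouts$turn_deg[i]
      if (!is.na(d)) displacement[bb[i]] <- displacement[bb[i]] + d
      if (!is.na(t)) turn[bb[i]] <- turn[bb[i]] + abs(t)
    }
  }
  tibble::tibble(
    bin = seq_len(n_bins), temp = temp, bout_start = bout_start,
    displacement = displacement, turn = turn
  )
}

#' Centered PCA reduction of an activity matrix
#'
#' @param activity Matrix, time bins by neurons.
#' @param n_components Number of principal components to retain.
#' @return List with `scores` (time by components), `variance_explained`
#'   (fraction of total variance in the retained components) and `rotation`.
#' @export
pca_reduce <- function(activity, n_components = 10) {
  if (n_components > ncol(activity)) stop("n_components exceeds neuron count")
  if (nrow(activity) <= n_components) stop("need more time bins than components")
  pc <- stats::prcomp(activity, center = TRUE, scale. = FALSE)
  list(
    scores = pc$x[, seq_len(n_components), drop = FALSE],
    variance_explained = sum(pc$sdev[seq_len(n_components)]^2) / sum(pc$sdev^2),
    rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
    center = pc$center
  )
}
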