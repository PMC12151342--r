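#' Sinusoidal "thermal plaid" laser-power field
#'
#' Constructs the doubly periodic laser-power landscape used to couple
#' temperature to position in closed-loop experiments. The power at a point
#' is `offset + amplitude * (0.5 * sin(2*pi*x/p) + 0.5 * sin(2*pi*y/p))`,
#' so power is bounded in `[offset - amplitude, offset + amplitude]` and the
#' field repeats with period `axis_period` along each axis. Coordinates are
#' in mm from the top-left corner of the arena (x right, y down).
#'
#' @param amplitude Peak-to-mean laser power modulation in mW.
#' @param offset Mean laser power in mW.
#' @param axis_period Spatial period along each axis in mm.
#' @return An object of class `plaid_field`.
#' @examples
#' f <- plaid_field()
#' power_at(f, 3.75, 3.75) # warmest point: 2000 mW
#' @export
plaid_field <- function(amplitude = 750, offset = 1250, axis_period = 15) {
  stopifnot(amplitude >= 0, axis_period > 0)
  structure(
    list(amplitude = amplitude, offset = offset, axis_period = axis_period),
    class = "plaid_field"
  )
}

#' @export
print.plaid_field <- function(x, ...) {
  cat(sprintf(
    "<plaid_field> %g mW +/- %g mW, axis period %g mm (diagonal repeat %.1f mm)\n",
    x$offset, x$amplitude, x$axis_period, plaid_repeat_distance(x, "diagonal")
  ))
  invisible(x)
}

#' Laser power at a position
#'
#' @param field A [plaid_field()].
#' @param x,y Coordinates in mm (vectorised; recycled to common length).
#' @return Laser power in mW.
#' @export
power_at <- function(field, x, y) {
  stopifnot(inherits(field, "plaid_field"), all(is.finite(x)), all(is.finite(y)))
  p <- field$axis_period
  field$offset +
    field$amplitude * (0.5 * sin(2 * pi * x / p) + 0.5 * sin(2 * pi * y / p))
}

#' Spatial repeat distance of the plaid
#'
#' The field repeats with period `axis_period` along either axis and with
#' period `axis_period * sqrt(2)` along the (1,1) diagonal, the direction in
#' which the warmest and coolest points alternate. Both readouts are exposed.
#'
#' @param field A [plaid_field()].
#' @param direction `"diagonal"` (default) or `"axis"`.
#' @return Distance in mm.
#' @export
plaid_repeat_distance <- function(field, direction = c("diagonal", "axis")) {
  direction <- match.arg(direction)
  switch(direction,
    axis = field$axis_period,
    diagonal = field$axis_period * sqrt(2)
  )
}

#' Empirical diagonal repeat distance by autocorrelation
#'
#' Samples the power profile along the (1,1) direction and locates the first
#' non-zero peak of its autocorrelation; a numerical counterpart to
#' [plaid_repeat_distance()] that operates on the field itself.
#'
#' @param field A [plaid_field()].
#' @param step Sampling step along the diagonal in mm.
#' @param length_mm Length of the sampled profile in mm.
#' @return Estimated repeat distance in mm.
#' @export
plaid_diagonal_repeat_empirical <- function(field, step = 0.01, length_mm = 100) {
  d <- seq(0, length_mm, by = step)
  u <- d / sqrt(2)
  prof <- power_at(field, u, u) - field$offset
  n <- length(prof)
  max_lag <- floor(n / 2)
  ac <- stats::acf(prof, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1]
  # first local maximum above zero correlation
  peaks <- which(diff(sign(diff(ac))) == -2) + 1
  peaks <- peaks[ac[peaks] > 0]
  if (length(peaks) == 0) stop("no autocorrelation peak found")
  peaks[1] * step
}

#' Linear laser-power to temperature calibration
#'
#' Affine map between two anchor points, by default 500 mW -> 25 degC and
#' 2000 mW -> 28 degC, spanning the 25-28 degC range delivered at the sample.
#'
#' @param power_lo,power_hi Anchor powers in mW.
#' @param temp_lo,temp_hi Temperatures at the anchors in degC.
#' @return An object of class `thermal_calibration`.
#' @export
calibration <- function(power_lo = 500, temp_lo = 25,
                        power_hi = 2000, temp_hi = 28) {
  if (power_lo == power_hi) stop("degenerate calibration: power anchors equal")
  if (!(temp_hi > temp_lo && power_hi > power_lo)) {
    stop("calibration must be strictly increasing")
  }
  structure(
    list(
      power_lo = power_lo, temp_lo = temp_lo,
      power_hi = power_hi, temp_hi = temp_hi
    ),
    class = "thermal_calibration"
  )
}

#' Convert laser power to temperature
#'
#' @param cal A [calibration()].
#' @param power Laser power in mW (vectorised). Values outside the anchor
#'   range are extrapolated with a warning.
#' @return Temperature in degC.
#' @export
power_to_temperature <- function(cal, power) {
  stopifnot(inherits(cal, "thermal_calibration"))
  if (any(power < cal$power_lo | power > cal$power_hi)) {
    warning("power outside calibration anchors; extrapolating linearly")
  }
  slope <- (cal$temp_hi - cal$temp_lo) / (cal$power_hi - cal$power_lo)
  cal$temp_lo + (power - cal$power_lo) * slope
}
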