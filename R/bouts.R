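#' Swim vigor: sliding-window SD of the tail angle
#'
#' Computes the per-frame population standard deviation of the cumulative
#' tail-bend angle over a trailing (causal) window of `window` frames. The
#' first `window - 1` frames use the partial window available up to that
#' frame. Vigor is the standard swim-bout indicator for larval zebrafish:
#' tail beating during a bout inflates the local SD far above the baseline.
#'
#' @param tail_angle Numeric tail-angle trace in radians (250 Hz).
#' @param window Window length in frames.
#' @return Numeric vigor trace (rad/frame), same length as the input.
#' @export
swim_vigor <- function(tail_angle, window = 10) {
  if (window < 2) stop("window must be at least 2 frames")
  n <- length(tail_angle)
  if (n < window) stop("trace shorter than the window")
  s1 <- cumsum(tail_angle)
  s2 <- cumsum(tail_angle^2)
  f <- seq_len(n)
  cnt <- pmin(f, window)
  lo <- f - cnt # index before window start (0 for partial windows)
  sum1 <- s1 - ifelse(lo > 0, s1[pmax(lo, 1)], 0)
  sum2 <- s2 - ifelse(lo > 0, s2[pmax(lo, 1)], 0)
  v <- sum2 / cnt - (sum1 / cnt)^2
  sqrt(pmax(v, 0))
}

#' Detect swim bouts from a vigor trace
#'
#' A bout opens at each upward crossing of `threshold` and closes when vigor
#' falls back below it. A bout still open at the end of the trace is closed
#' at the final frame. Frame indices are half-open: `[start_frame,
#' end_frame)`.
#'
#' @param vigor Vigor trace from [swim_vigor()].
#' @param threshold Detection threshold in rad/frame.
#' @return Tibble with `start_frame`, `end_frame`; zero rows if no crossing.
#' @export
detect_bouts <- function(vigor, threshold = 0.1) {
  above <- vigor > threshold
  if (!any(above)) {
    return(tibble::tibble(start_frame = integer(0), end_frame = integer(0)))
  }
  r <- rle(above)
  ends_at <- cumsum(r$lengths)
  starts_at <- ends_at - r$lengths + 1L
  keep <- r$values
  tibble::tibble(
    start_frame = starts_at[keep],
    end_frame = ends_at[keep] + 1L # half-open; trace-end bouts close at n+1
  )
}

#' Per-bout kinematics
#'
#' Displacement is the Euclidean distance between the mean centroid position
#' over the five frames before bout start and over the five frames after bout
#' end. Turn angle is the difference between mean-vector headings over the
#' same two windows, mapped to the smallest angle in `[0, 180]` degrees.
#' Bouts whose pre/post windows fall outside the trace keep their timing but
#' get `NA` kinematics (`kinematics_ok = FALSE`). The interbout interval is
#' the time from the previous bout's end to the current bout's start.
#'
#' @param traj A data frame with `x`, `y` (mm) and `heading` (rad) per frame.
#' @param bouts Tibble with `start_frame`, `end_frame` (half-open).
#' @param frame_rate Frames per second.
#' @param n_avg Frames averaged on either side of the bout.
#' @return `bouts` augmented with `displacement_mm`, `turn_deg`,
#'   `interbout_interval_s` and `kinematics_ok`.
#' @export
bout_kinematics <- function(traj, bouts, frame_rate = 250, n_avg = 5) {
  n <- nrow(traj)
  res <- dplyr::mutate(
    bouts,
    displacement_mm = NA_real_, turn_deg = NA_real_,
    kinematics_ok = .data$start_frame > n_avg & .data$end_frame + n_avg - 1 <= n
  )
  for (i in seq_len(nrow(res))) {
    if (!res$kinematics_ok[i]) next
    pre <- (res$start_frame[i] - n_avg):(res$start_frame[i] - 1L)
    post <- res$end_frame[i]:(res$end_frame[i] + n_avg - 1L)
    dx <- mean(traj$x[post]) - mean(traj$x[pre])
    dy <- mean(traj$y[post]) - mean(traj$y[pre])
    res$displacement_mm[i] <- sqrt(dx^2 + dy^2)
    h_pre <- atan2(mean(sin(traj$heading[pre])), mean(cos(traj$heading[pre])))
    h_post <- atan2(mean(sin(traj$heading[post])), mean(cos(traj$heading[post])))
    d <- abs(h_post - h_pre) %% (2 * pi)
    res$turn_deg[i] <- min(d, 2 * pi - d) * 180 / pi
  }
  res$interbout_interval_s <- c(
    NA_real_,
    (res$start_frame[-1] - res$end_frame[-nrow(res)]) / frame_rate
  )[seq_len(nrow(res))]
  res
}

#' Exclude bouts near the arena wall
#'
#' Retains only bouts whose start position lies at least `margin_mm` from the
#' arena edge, removing data confounded by the wall limiting the movement
#' repertoire (thigmotaxis).
#'
#' @param bouts Bout tibble with `start_frame`.
#' @param traj Data frame with `x`, `y` per frame (arena-centered, mm).
#' @param arena_radius_mm Arena radius.
#' @param margin_mm Minimum distance from the wall.
#' @return Filtered bout tibble.
#' @export
edge_filter <- function(bouts, traj, arena_radius_mm = 50, margin_mm = 4) {
  if (margin_mm >= arena_radius_mm) stop("margin must be smaller than the arena radius")
  if (nrow(bouts) == 0) return(bouts)
  r <- sqrt(traj$x[bouts$start_frame]^2 + traj$y[bouts$start_frame]^2)
  bouts[arena_radius_mm - r >= margin_mm, ]
}

#' Temperature change during bouts versus matched random intervals
#'
#' For every bout, the absolute temperature change `|T(end) - T(start)|`
#' across the bout; as a control, one random interval of identical length is
#' placed uniformly within the same trace. In the closed-loop plaid
#' condition bouts move the fish through the field, so bout intervals carry
#' larger temperature changes than stationary ones; in replay the two
#' samples are exchangeable.
#'
#' @param bouts Bout tibble (`start_frame`, `end_frame`, half-open).
#' @param temperature Frame-level temperature trace in degC.
#' @param seed Seed for control-interval placement.
#' @return Tibble with one row per interval: `interval` ("bout"/"control"),
#'   `length_frames`, `delta_t`.
#' @export
per_bout_delta_t <- function(bouts, temperature, seed = 1) {
  if (nrow(bouts) == 0) stop("empty bout list")
  n <- length(temperature)
  if (any(bouts$end_frame - 1L > n)) stop("temperature trace does not cover all bouts")
  set.seed(seed)
  len <- bouts$end_frame - bouts$start_frame
  t_end <- pmin(bouts$end_frame, n)
  d_bout <- abs(temperature[t_end] - temperature[bouts$start_frame])
  ctrl_start <- floor(stats::runif(nrow(bouts), 1, n - len)) # uniform placement
  ctrl_end <- pmin(ctrl_start + len, n)
  d_ctrl <- abs(temperature[ctrl_end] - temperature[ctrl_start])
  tibble::tibble(
    interval = rep(c("bout", "control"), each = nrow(bouts)),
    length_frames = rep(len, 2),
    delta_t = c(d_bout, d_ctrl)
  )
}

#' Full bout-extraction pipeline for one experiment
#'
#' Vigor, threshold detection, kinematics and edge filtering in one call.
#'
#' @param experiment A `fish_experiment` (or any data frame with
#'   `tail_angle`, `x`, `y`, `heading`).
#' @param threshold Vigor threshold (rad/frame).
#' @param window Vigor window (frames).
#' @param arena_radius_mm,margin_mm Edge-filter geometry.
#' @return Edge-filtered bout tibble with kinematics.
#' @export
extract_bouts <- function(experiment, threshold = 0.1, window = 10,
                          arena_radius_mm = 50, margin_mm = 4) {
  fr <- attr(experiment, "frame_rate") %||% 250
  v <- swim_vigor(experiment$tail_angle, window = window)
  b <- detect_bouts(v, threshold = threshold)
  b <- bout_kinematics(experiment, b, frame_rate = fr)
  edge_filter(b, experiment, arena_radius_mm = arena_radius_mm, margin_mm = margin_mm)
}
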