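#' Simulate one virtual fish experiment
#'
#' Runs the bout-based locomotion model for `duration_s` seconds in a
#' 100 mm diameter circular arena at 250 Hz. In the closed-loop (plaid)
#' condition the temperature each frame is determined by the fish position
#' through the laser-power field and calibration; in the open-loop (replay)
#' condition a pre-recorded frame-level temperature trace is played back,
#' decoupled from position. Bout initiation follows the
#' [generative_policy()] on 40 ms bins; during a bout the fish turns and
#' then translates along its new heading, reflecting off the arena wall.
#' A synthetic tail-angle trace (sinusoidal beating during bouts, Gaussian
#' jitter elsewhere) is attached so the bout detector can run on the output.
#'
#' @param policy A [generative_policy()].
#' @param field A [plaid_field()], required unless `replay_temp` is given.
#' @param cal A [calibration()].
#' @param duration_s Experiment duration in seconds.
#' @param seed Integer seed; every stochastic element derives from it.
#' @param replay_temp Optional frame-level (250 Hz) temperature trace in
#'   degC; supplying it switches the experiment to the replay condition.
#' @param id Experiment identifier.
#' @param arena_radius_mm Arena radius (mm).
#' @param tail_noise_sd,tail_beat_amplitude,tail_beat_freq Tail-trace
#'   parameters passed to [synth_tail_trace()].
#' @param thermal_lag_s Optional first-order thermal lag time constant in
#'   seconds (0 = instantaneous laser-to-temperature coupling, the default).
#' @return A tibble of per-frame records (`time_s`, `x`, `y`, `heading`,
#'   `tail_angle`, `power_mw`, `temp_c`, `phase`) of class
#'   `fish_experiment`, with attributes `condition`, `frame_rate`,
#'   `bin_rate`, `bouts` (the true bout table), `temp_bin` (25 Hz binned
#'   temperature) and `seed`.
#' @export
simulate_fish <- function(policy, field = NULL, cal = calibration(),
                          duration_s = 1200, seed = 1, replay_temp = NULL,
                          id = "exp1", arena_radius_mm = 50,
                          tail_noise_sd = 0.01, tail_beat_amplitude = 0.5,
                          tail_beat_freq = 22, thermal_lag_s = 0) {
  if (duration_s <= 0) stop("duration_s must be positive")
  frame_rate <- 250L
  bin_rate <- policy$bin_rate
  fpb <- frame_rate / bin_rate # frames per bin
  n_bins <- floor(duration_s * bin_rate)
  n_frames <- n_bins * fpb
  if (n_bins < policy$history_bins) {
    stop("duration shorter than the policy history window")
  }
  replay <- !is.null(replay_temp)
  if (!replay && is.null(field)) stop("supply a field or a replay trace")
  if (replay && length(replay_temp) < n_frames) {
    stop("replay temperature trace shorter than the experiment")
  }

  set.seed(seed)
  hb <- policy$history_bins
  kT <- policy$temp_kernel
  kB <- policy$bout_kernel

  # state
  theta0 <- stats::runif(1, 0, 2 * pi)
  r0 <- sqrt(stats::runif(1)) * (arena_radius_mm * 0.6)
  pos <- c(r0 * cos(theta0), r0 * sin(theta0))
  heading <- stats::runif(1, -pi, pi)

  x <- numeric(n_frames)
  y <- numeric(n_frames)
  hd <- numeric(n_frames)
  temp_bin <- numeric(n_bins)
  temp_dev <- numeric(n_bins)
  bout_end_bin <- numeric(n_bins)

  starts <- integer(0)
  ends <- integer(0)
  disp_true <- numeric(0)
  turn_true <- numeric(0)

  if (replay) {
    # binned playback temperature, fixed in advance
    temp_bin <- colMeans(matrix(replay_temp[seq_len(n_frames)], nrow = fpb))
    temp_dev_all <- temp_bin - policy$temp_ref
  }

  # ongoing-bout state; the hazard is evaluated in every bin so that with
  # zero kernels bout starts are an exact Bernoulli process per bin. A
  # trigger during an ongoing bout truncates it and starts a new bout
  # (a "double bout"); refractoriness comes from the bout-history kernel.
  in_bout <- FALSE
  bins_left <- 0L
  step_len <- 0

  for (b in seq_len(n_bins)) {
    f0 <- (b - 1L) * fpb + 1L
    # policy decision for this bin from strictly causal history
    lags <- b - seq_len(hb)
    ok <- lags >= 1L
    lp <- policy$base_logit
    if (any(ok)) {
      lp <- lp + sum(kT[ok] * temp_dev[lags[ok]]) +
        sum(kB[ok] * bout_end_bin[lags[ok]])
    }
    if (stats::runif(1) < stats::plogis(lp)) {
      if (in_bout) { # truncate the ongoing bout at the new start
        ends <- c(ends, f0)
        bout_end_bin[b - 1L] <- 1
      }
      dur_bins <- max(1L, round(stats::runif(
        1, policy$bout_duration_s[1],
        policy$bout_duration_s[2]
      ) * bin_rate))
      dur_bins <- min(dur_bins, n_bins - b + 1L)
      displacement <- stats::rlnorm(
        1, log(policy$displacement_median_mm),
        policy$displacement_sdlog
      )
      if (stats::runif(1) < policy$p_straight) {
        turn <- stats::rnorm(1, 0, policy$straight_sd_deg)
      } else {
        turn <- sample(c(-1, 1), 1) *
          stats::rnorm(1, policy$turn_mean_deg, policy$turn_sd_deg)
      }
      heading <- wrap_angle(heading + turn * pi / 180)
      starts <- c(starts, f0)
      disp_true <- c(disp_true, displacement)
      turn_true <- c(turn_true, turn)
      in_bout <- TRUE
      bins_left <- dur_bins
      step_len <- displacement / (dur_bins * fpb)
    }
    if (in_bout) {
      for (k in seq_len(fpb)) {
        f <- f0 + k - 1L
        step <- step_len * c(cos(heading), sin(heading))
        prop <- pos + step
        if (sqrt(sum(prop^2)) > arena_radius_mm) {
          nrm <- pos / sqrt(sum(pos^2))
          v <- step - 2 * sum(step * nrm) * nrm
          heading <- atan2(v[2], v[1])
          prop <- pos + v
          if (sqrt(sum(prop^2)) > arena_radius_mm) {
            prop <- prop * (arena_radius_mm / sqrt(sum(prop^2)))
          }
        }
        pos <- prop
        x[f] <- pos[1]
        y[f] <- pos[2]
        hd[f] <- heading
      }
      bins_left <- bins_left - 1L
      if (bins_left == 0L) {
        in_bout <- FALSE
        ends <- c(ends, f0 + fpb) # half-open [start, end)
        bout_end_bin[b] <- 1
      }
    } else {
      fr <- f0:(f0 + fpb - 1L)
      x[fr] <- pos[1]
      y[fr] <- pos[2]
      hd[fr] <- heading
    }
    if (!replay) {
      fr <- f0:(f0 + fpb - 1L)
      tb <- mean(power_to_temperature(cal, power_at(field, x[fr], y[fr])))
      temp_bin[b] <- tb
      temp_dev[b] <- tb - policy$temp_ref
    } else {
      temp_dev[b] <- temp_dev_all[b]
    }
  }

  if (in_bout) ends <- c(ends, n_frames + 1L) # bout open at trace end

  if (!replay) {
    power <- power_at(field, x, y)
    temp <- power_to_temperature(cal, power)
    if (thermal_lag_s > 0) {
      a <- exp(-1 / (thermal_lag_s * frame_rate))
      temp <- stats::filter(temp * (1 - a), a, method = "recursive")
      temp <- as.numeric(temp) + temp[1] * 0 # strip ts attributes
      temp_bin <- colMeans(matrix(temp, nrow = fpb))
    }
  } else {
    temp <- replay_temp[seq_len(n_frames)]
    power <- temperature_to_power(cal, temp)
  }

  bouts <- tibble::tibble(
    start_frame = starts, end_frame = ends,
    displacement_mm = disp_true, turn_deg = abs(turn_true)
  )
  tail <- synth_tail_trace(
    bouts, n_frames,
    beat_amplitude = tail_beat_amplitude,
    beat_freq = tail_beat_freq, noise_sd = tail_noise_sd,
    frame_rate = frame_rate
  )

  out <- tibble::tibble(
    time_s = (seq_len(n_frames) - 1) / frame_rate,
    x = x, y = y, heading = hd, tail_angle = tail,
    power_mw = power, temp_c = temp, phase = "stimulus"
  )
  structure(
    out,
    class = c("fish_experiment", class(out)),
    condition = if (replay) "replay" else "plaid",
    id = id, frame_rate = frame_rate, bin_rate = bin_rate,
    arena_radius_mm = arena_radius_mm,
    bouts = bouts, temp_bin = temp_bin, seed = seed
  )
}

# inverse of the affine calibration (used to back out replay laser power)
temperature_to_power <- function(cal, temp) {
  slope <- (cal$temp_hi - cal$temp_lo) / (cal$power_hi - cal$power_lo)
  cal$power_lo + (temp - cal$temp_lo) / slope
}

wrap_angle <- function(a) atan2(sin(a), cos(a))

#' True bout table of a simulated experiment
#' @param experiment A `fish_experiment`.
#' @return Tibble of ground-truth bouts.
#' @export
true_bouts <- function(experiment) attr(experiment, "bouts")

#' Synthetic tail-angle trace
#'
#' Builds a 250 Hz cumulative tail-bend trace from a bout table: a sinusoidal
#' tail beat during bout frames and Gaussian baseline jitter elsewhere. Used
#' by the simulator so that bout detection can be exercised end to end.
#'
#' @param bouts Tibble with `start_frame`, `end_frame` (half-open).
#' @param n_frames Trace length in frames.
#' @param beat_amplitude Tail-beat amplitude in radians.
#' @param beat_freq Tail-beat frequency in Hz.
#' @param noise_sd Baseline jitter SD in radians.
#' @param frame_rate Frames per second.
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return Numeric tail-angle trace.
#' @export
synth_tail_trace <- function(bouts, n_frames, beat_amplitude = 0.5,
                             beat_freq = 22, noise_sd = 0.01,
                             frame_rate = 250, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(bouts) > 0) {
    o <- order(bouts$start_frame)
    b <- bouts[o, ]
    if (any(b$start_frame < 1 | b$end_frame > n_frames + 1L)) {
      stop("bouts outside [1, n_frames]")
    }
    if (nrow(b) > 1 && any(b$start_frame[-1] < b$end_frame[-nrow(b)])) {
      stop("overlapping bouts")
    }
  }
  trace <- if (noise_sd > 0) stats::rnorm(n_frames, 0, noise_sd) else numeric(n_frames)
  for (i in seq_len(nrow(bouts))) {
    fr <- bouts$start_frame[i]:(bouts$end_frame[i] - 1L)
    k <- seq_along(fr) - 1
    trace[fr] <- trace[fr] + beat_amplitude * sin(2 * pi * beat_freq * k / frame_rate)
  }
  trace
}

#' Create a yoked plaid/replay experiment pair
#'
#' Simulates a second fish whose temperature input is the exact frame-level
#' temperature trace experienced by the supplied closed-loop fish. The replay
#' fish moves freely under the same policy, but its temperature is
#' independent of its own position.
#'
#' @param plaid_experiment A `fish_experiment` from the plaid condition.
#' @param policy Policy for the replay fish (defaults to a fresh
#'   [generative_policy()]).
#' @param cal A [calibration()].
#' @param seed Seed for the replay fish.
#' @return A list of class `experiment_pair` with elements `plaid` and
#'   `replay`.
#' @export
make_replay_pair <- function(plaid_experiment, policy = generative_policy(),
                             cal = calibration(), seed = 1) {
  temp <- plaid_experiment$temp_c
  if (is.null(temp) || all(is.na(temp))) stop("missing temperature trace")
  dur <- nrow(plaid_experiment) / attr(plaid_experiment, "frame_rate")
  rep_exp <- simulate_fish(
    policy,
    cal = cal, duration_s = dur, seed = seed,
    replay_temp = temp, id = paste0(attr(plaid_experiment, "id"), "_replay")
  )
  structure(
    list(plaid = plaid_experiment, replay = rep_exp),
    class = "experiment_pair",
    pair_id = attr(plaid_experiment, "id")
  )
}

#' Simulate a cohort of yoked experiment pairs
#'
#' @param n_pairs Number of plaid/replay pairs.
#' @param duration_s Duration of each experiment in seconds.
#' @param policy A [generative_policy()] shared by all fish.
#' @param field A [plaid_field()].
#' @param cal A [calibration()].
#' @param seed Master seed; per-fish seeds are derived from it.
#' @return A list of `experiment_pair` objects.
#' @export
simulate_experiment_pairs <- function(n_pairs, duration_s = 1200,
                                      policy = generative_policy(),
                                      field = plaid_field(),
                                      cal = calibration(), seed = 1) {
  purrr::map(seq_len(n_pairs), function(i) {
    pl <- simulate_fish(
      policy,
      field = field, cal = cal, duration_s = duration_s,
      seed = seed + 1000L * i, id = sprintf("pair%02d", i)
    )
    make_replay_pair(pl, policy = policy, cal = cal, seed = seed + 1000L * i + 500L)
  })
}
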