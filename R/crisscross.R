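#' Configuration of the robotic Crisscross assessment
#'
#' Crisscross is a passive finger-proprioception test: a robot moves the
#' index and middle fingers in opposing directions at identical speed over a
#' fixed flexion range, and the participant presses a button when they feel
#' the fingers cross. Because both fingers traverse the same range at the
#' same speed, every crossing occurs at the midpoint of the range.
#'
#' @param speed_set Movement speeds in deg/s; the standard set is
#'   `{8, 8.5, 9, 10, 10.5, 11.5, 12.5, 14, 16, 18}`, randomized across
#'   trials so the crossing is unpredictable.
#' @param range_deg Flexion range in degrees (default 15 to 45, so crossings
#'   occur at 30 degrees).
#' @param n_trials Finger-crossing movements per assessment (default 20).
#' @param dt Trajectory sampling step in seconds (default 0.01) for
#'   [trajectory()].
#' @return An object of class `crisscross_config` with the derived
#'   `crossing_angle_deg`.
#' @export
crisscross_config <- function(speed_set = c(8, 8.5, 9, 10, 10.5, 11.5, 12.5,
                                            14, 16, 18),
                              range_deg = c(15, 45), n_trials = 20L,
                              dt = 0.01) {
  stopifnot(all(speed_set > 0), length(range_deg) == 2L,
            range_deg[1L] < range_deg[2L], n_trials >= 1L, dt > 0)
  structure(list(speed_set = speed_set, range_deg = range_deg,
                 n_trials = as.integer(n_trials), dt = dt,
                 crossing_angle_deg = mean(range_deg)),
            class = "crisscross_config")
}

#' Simulate one finger-crossing trial
#'
#' One finger moves from the range minimum to the maximum and the other in
#' the opposite direction, both as ideal constant-velocity ramps at the same
#' speed (no robot dynamics). The trajectories intersect exactly once, at the
#' range midpoint.
#'
#' @param config A [crisscross_config()].
#' @param speed Speed in deg/s; must belong to `config$speed_set` unless
#'   `allow_any_speed`.
#' @param direction `"index_flexing"` (index moves min to max) or
#'   `"index_extending"`.
#' @param allow_any_speed Permit speeds outside the configured set.
#' @return An object of class `crisscross_trial` with `speed`, `direction`,
#'   `t_cross` (seconds after motion onset), `crossing_angle_deg`,
#'   `duration` (time for a full traverse) and the range.
#' @export
simulate_trial <- function(config = crisscross_config(), speed,
                           direction = c("index_flexing", "index_extending"),
                           allow_any_speed = FALSE) {
  direction <- match.arg(direction)
  if (!allow_any_speed && !speed %in% config$speed_set)
    stop("speed ", speed, " deg/s is not in the configured speed set",
         call. = FALSE)
  lo <- config$range_deg[1L]
  hi <- config$range_deg[2L]
  span <- hi - lo
  t_cross <- (span / 2) / speed
  structure(list(speed = speed, direction = direction,
                 range_deg = config$range_deg, duration = span / speed,
                 t_cross = t_cross,
                 crossing_angle_deg = finger_angles(lo, hi, speed, direction,
                                                    t_cross)[["index"]],
                 dt = config$dt),
            class = "crisscross_trial")
}

# Piecewise-linear (here: single-segment) finger angles at time t after
# motion onset; exact for constant-velocity ramps.
finger_angles <- function(lo, hi, speed, direction, t) {
  up <- pmin(hi, lo + speed * t)
  down <- pmax(lo, hi - speed * t)
  if (direction == "index_flexing") c(index = unname(up), middle = unname(down))
  else c(index = unname(down), middle = unname(up))
}

#' Sampled angular trajectories of a trial
#'
#' @param trial A [simulate_trial()] result.
#' @param dt Sampling step (default the configured one).
#' @return Data frame with `t`, `index_deg`, `middle_deg`.
#' @export
trajectory <- function(trial, dt = trial$dt) {
  t <- seq(0, trial$duration, by = dt)
  lo <- trial$range_deg[1L]
  hi <- trial$range_deg[2L]
  up <- pmin(hi, lo + trial$speed * t)
  down <- pmax(lo, hi - trial$speed * t)
  if (trial$direction == "index_flexing")
    data.frame(t = t, index_deg = up, middle_deg = down)
  else data.frame(t = t, index_deg = down, middle_deg = up)
}

#' Crossing error at a button press
#'
#' The magnitude of the angular distance between the two finger joints at
#' the instant of the button press. A press outside the motion span censors
#' the trial (flag, not clamp), so late or absent presses do not bias the
#' participant mean.
#'
#' @param trial A [simulate_trial()] result.
#' @param press_time Seconds after motion onset.
#' @return List with `error_deg` (`NA` when censored) and `censored`.
#' @export
crossing_error <- function(trial, press_time) {
  if (!is.finite(press_time) || press_time < 0 || press_time > trial$duration)
    return(list(error_deg = NA_real_, censored = TRUE))
  ang <- finger_angles(trial$range_deg[1L], trial$range_deg[2L], trial$speed,
                       trial$direction, press_time)
  list(error_deg = abs(ang[["index"]] - ang[["middle"]]), censored = FALSE)
}

#' Mean crossing error of a participant
#'
#' Proprioceptive error is the average of the absolute crossing errors over
#' the trials with a (non-censored) button press.
#'
#' @param errors_deg Numeric vector of per-trial crossing errors; `NA` marks
#'   censored trials.
#' @return Mean error in degrees, or `NA` with a warning when no presses
#'   remain.
#' @export
participant_error <- function(errors_deg) {
  vals <- errors_deg[is.finite(errors_deg)]
  if (length(vals) == 0L) {
    warning("no button presses: participant error is missing")
    return(NA_real_)
  }
  mean(abs(vals))
}

#' Simulate a full Crisscross assessment for one participant
#'
#' Draws a random speed and direction per trial and a button press at
#' `crossing time + bias + N(0, sd)`. Presses falling outside the motion span
#' are censored. The mean crossing error of an unbiased participant with
#' press-latency SD `sd` at speed `v` follows the folded normal
#' `2 v sd sqrt(2/pi)` (the fingers separate at relative speed `2v`).
#'
#' @param config A [crisscross_config()].
#' @param latency_bias,latency_sd Press-latency model in seconds.
#' @param seed RNG seed (reproducible trials).
#' @return List with `trials` (data frame: `trial`, `speed`, `direction`,
#'   `press_time`, `press_offset_s`, `crossing_error_deg`, `censored`) and
#'   `mean_error_deg`.
#' @export
simulate_participant <- function(config = crisscross_config(),
                                 latency_bias = 0, latency_sd = 0.1,
                                 seed = NULL) {
  stopifnot(latency_sd >= 0)
  with_seed(seed, {
    speeds <- config$speed_set[sample.int(length(config$speed_set),
                                          config$n_trials, replace = TRUE)]
    dirs <- sample(c("index_flexing", "index_extending"), config$n_trials,
                   replace = TRUE)
    rows <- lapply(seq_len(config$n_trials), function(i) {
      trial <- simulate_trial(config, speeds[i], dirs[i])
      offset <- latency_bias + stats::rnorm(1, 0, latency_sd)
      press <- trial$t_cross + offset
      ce <- crossing_error(trial, press)
      data.frame(trial = i, speed = speeds[i], direction = dirs[i],
                 press_time = press, press_offset_s = offset,
                 crossing_error_deg = ce$error_deg, censored = ce$censored,
                 stringsAsFactors = FALSE)
    })
    trials <- do.call(rbind, rows)
    list(trials = trials,
         mean_error_deg = participant_error(trials$crossing_error_deg))
  })
}
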