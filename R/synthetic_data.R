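# Canonical 21-landmark adult hand geometry (cm, hand-local frame, wrist at
# the origin, fingers extending in +y). Values are plausible adult hand
# proportions; the template is rescaled so its skeleton edge-sum matches a
# requested metric hand size, so only the shape matters.
HAND_TEMPLATE_CM <- rbind(
  c(0.0, 0.0),     # 0 wrist
  c(-3.0, 2.0),    # 1 thumb CMC
  c(-5.0, 4.5),    # 2 thumb MCP
  c(-6.5, 6.5),    # 3 thumb IP
  c(-7.5, 8.0),    # 4 thumb tip
  c(-2.5, 9.0),    # 5 index MCP
  c(-3.0, 12.5),   # 6 index PIP
  c(-3.2, 14.5),   # 7 index DIP
  c(-3.3, 16.5),   # 8 index tip
  c(-0.5, 9.5),    # 9 middle MCP
  c(-0.5, 13.5),   # 10 middle PIP
  c(-0.5, 16.0),   # 11 middle DIP
  c(-0.5, 18.0),   # 12 middle tip
  c(1.5, 9.0),     # 13 ring MCP
  c(1.8, 12.5),    # 14 ring PIP
  c(2.0, 15.0),    # 15 ring DIP
  c(2.2, 17.0),    # 16 ring tip
  c(3.5, 8.0),     # 17 pinky MCP
  c(4.0, 10.5),    # 18 pinky PIP
  c(4.3, 12.5),    # 19 pinky DIP
  c(4.5, 14.0)     # 20 pinky tip
)

#' Canonical hand template with a configured metric hand size
#'
#' Rescales a canonical 21-landmark hand geometry so that the skeleton
#' edge-sum at the given level equals `handsize_cm`. The template is the
#' ground-truth geometry from which synthetic landmark streams are rendered.
#'
#' @param handsize_cm Target metric hand size (default 54.84, the male
#'   normative default).
#' @param level Landmark level at which the size is normalised.
#' @return Object of class `hand_template`: list with `pts_cm` (21 x 2),
#'   `handsize_cm`, `level`.
#' @export
hand_template <- function(handsize_cm = 54.84, level = "TIP") {
  raw <- hand_size_px(HAND_TEMPLATE_CM, level = level)  # cm here, same formula
  pts <- HAND_TEMPLATE_CM * (handsize_cm / raw)
  structure(list(pts_cm = pts, handsize_cm = handsize_cm, level = level),
            class = "hand_template")
}

# Minimal-jerk position profile: fraction of the path covered at normalised
# time tau in [0, 1].
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Describe a synthetic pointing trial
#'
#' Declares the ground truth of one simulated trial: the instructed target,
#' the endpoint bias and isotropic 2D endpoint noise (both in cm), the
#' movement kinematics (a minimal-jerk reach followed by a hold), the camera
#' mapping (uniform px/cm scale, optionally drifting linearly over the trial
#' to emulate a change of distance from the camera), and low-amplitude
#' tremor on the static target hand.
#'
#' @param target_finger Instructed finger (default `"index"`).
#' @param level Landmark level (default `"TIP"`).
#' @param bias_cm Length-2 systematic endpoint offset (cm).
#' @param noise_sd_cm SD of isotropic 2D endpoint noise (cm).
#' @param movement_s Reach duration (default 1.5 s).
#' @param hold_s Hold duration after the reach (default 2.5 s, long enough
#'   for the 2 s stop window to fill).
#' @param fps Frame rate (default 30).
#' @param camera_scale Pixels per cm at trial start (default 10).
#' @param camera_scale_end Optional px/cm at trial end; when set, the scale
#'   drifts linearly between the two (camera-distance change emulation).
#' @param tremor_sd_cm SD of per-frame rigid jitter on the target hand
#'   (default 0.02 cm, <= 0.05).
#' @param start_offset_cm Start-circle position relative to the target
#'   landmark (default `c(25, 8)` cm, comfortably outside the proximity
#'   radius).
#' @param correction Optional list `list(delay_s=, duration_s=, to_cm=)`
#'   appending a second minimal-jerk segment after a plateau, moving the
#'   fingertip to `target + to_cm` (emulates a forbidden corrective
#'   movement).
#' @return An object of class `pointing_scenario`.
#' @export
pointing_scenario <- function(target_finger = "index", level = "TIP",
                              bias_cm = c(0, 0), noise_sd_cm = 0,
                              movement_s = 1.5, hold_s = 2.5, fps = 30,
                              camera_scale = 10, camera_scale_end = NULL,
                              tremor_sd_cm = 0.02,
                              start_offset_cm = c(25, 8),
                              correction = NULL) {
  target_finger <- match.arg(target_finger, FINGERS)
  level <- match.arg(level, c("TIP", "PIP", "MCP"))
  stopifnot(length(bias_cm) == 2L, noise_sd_cm >= 0, movement_s > 0,
            hold_s >= 0, fps > 0, camera_scale > 0, tremor_sd_cm >= 0,
            tremor_sd_cm <= 0.05, length(start_offset_cm) == 2L)
  if (!is.null(camera_scale_end)) stopifnot(camera_scale_end > 0)
  if (!is.null(correction))
    stopifnot(is.list(correction), correction$delay_s >= 0,
              correction$duration_s > 0, length(correction$to_cm) == 2L)
  structure(list(target_finger = target_finger, level = level,
                 bias_cm = as.numeric(bias_cm), noise_sd_cm = noise_sd_cm,
                 movement_s = movement_s, hold_s = hold_s, fps = fps,
                 camera_scale = camera_scale,
                 camera_scale_end = camera_scale_end,
                 tremor_sd_cm = tremor_sd_cm,
                 start_offset_cm = as.numeric(start_offset_cm),
                 correction = correction),
            class = "pointing_scenario")
}

# Scene origin (cm) for the static target hand; keeps every rendered pixel
# coordinate positive across template shapes, biases and noise draws.
TARGET_ORIGIN_CM <- c(40, 40)

#' Render a synthetic two-hand landmark stream for one pointing trial
#'
#' The target hand is static (plus small rigid tremor) at a fixed scene
#' position; the pointing hand translates rigidly so that its index fingertip
#' follows a minimal-jerk path from the start position to
#' `target landmark + bias + noise`, then holds (and optionally "corrects").
#' All centimeter geometry is multiplied by the (possibly time-varying)
#' camera scale into pixels. Ground truth is stored in the stream metadata:
#' `truth_dx_cm`, `truth_dy_cm`, `truth_error_cm` (the realised endpoint
#' error) and the seed.
#'
#' @param scenario A [pointing_scenario()].
#' @param template A [hand_template()] for the target hand.
#' @param seed RNG seed for the endpoint noise and tremor.
#' @return A [frame_stream()] with `target` (left) and `pointing` (right)
#'   hands.
#' @export
render_stream <- function(scenario, template = hand_template(), seed = NULL) {
  with_seed(seed, {
    lvl <- landmark_level(scenario$level)
    t_idx <- lvl$indices[[scenario$target_finger]] + 1L
    n <- as.integer(round((scenario$movement_s + scenario$hold_s) * scenario$fps))
    t <- (seq_len(n) - 1L) / scenario$fps

    target_pts <- sweep(template$pts_cm, 2L, TARGET_ORIGIN_CM, `+`)
    target_lm <- target_pts[t_idx, ]

    noise <- stats::rnorm(2L, 0, scenario$noise_sd_cm)
    endpoint <- target_lm + scenario$bias_cm + noise
    start <- target_lm + scenario$start_offset_cm

    frac <- min_jerk(t / scenario$movement_s)
    tip_x <- start[1L] + (endpoint[1L] - start[1L]) * frac
    tip_y <- start[2L] + (endpoint[2L] - start[2L]) * frac
    if (!is.null(scenario$correction)) {
      co <- scenario$correction
      t0 <- scenario$movement_s + co$delay_s
      frac2 <- min_jerk((t - t0) / co$duration_s)
      end2 <- target_lm + co$to_cm
      tip_x <- tip_x + (end2[1L] - endpoint[1L]) * frac2
      tip_y <- tip_y + (end2[2L] - endpoint[2L]) * frac2
    }

    # pointing hand: mirrored template, rigid-translated with the fingertip
    point_local <- cbind(-template$pts_cm[, 1L], template$pts_cm[, 2L])
    tip_local <- point_local[9L, ]  # landmark 8, index fingertip
    point_rel <- sweep(point_local, 2L, tip_local)

    tremor <- matrix(stats::rnorm(2L * n, 0, scenario$tremor_sd_cm), n, 2L)
    scale_t <- if (is.null(scenario$camera_scale_end)) rep(scenario$camera_scale, n)
      else scenario$camera_scale +
        (scenario$camera_scale_end - scenario$camera_scale) * (t / max(t))

    tpts <- array(0, dim = c(n, 21L, 3L))
    ppts <- array(0, dim = c(n, 21L, 3L))
    for (d in 1:2) {
      tpts[, , d] <- (outer(rep(1, n), target_pts[, d]) + tremor[, d]) * scale_t
      tip <- if (d == 1L) tip_x else tip_y
      ppts[, , d] <- (tip + outer(rep(1, n), point_rel[, d])) * scale_t
    }

    md <- list(truth_dx_cm = endpoint[1L] - target_lm[1L],
               truth_dy_cm = endpoint[2L] - target_lm[2L],
               truth_error_cm = sqrt(sum((endpoint - target_lm)^2)),
               target_finger = scenario$target_finger, level = scenario$level,
               seed = if (is.null(seed)) NA else seed)
    new_frame_stream(
      list(target = new_hand_track(t, tpts, rep(1, n), "left"),
           pointing = new_hand_track(t, ppts, rep(1, n), "right")),
      fps = scenario$fps, metadata = md)
  })
}

#' Render a fake-hand session stream
#'
#' The fake hand (a cardboard cutout used in no-proprioception control
#' conditions) has a fixed metric hand size of 60 cm and does not tremble.
#' With a `scenario`, a pointing movement against the fake hand is rendered;
#' without one, a static target-only stream is returned (e.g. for
#' calibration checks).
#'
#' @param scenario Optional [pointing_scenario()]; its tremor is forced to 0
#'   and its level to the template normalisation level.
#' @param duration_s,fps Stream shape for the static (no-scenario) case.
#' @param camera_scale px/cm for the static case.
#' @param seed RNG seed.
#' @return A [frame_stream()].
#' @export
render_fake_hand_session <- function(scenario = NULL, duration_s = 2, fps = 30,
                                     camera_scale = 10, seed = NULL) {
  template <- hand_template(handsize_cm = FAKE_HAND_SIZE_CM, level = "TIP")
  if (!is.null(scenario)) {
    scenario$tremor_sd_cm <- 0
    return(render_stream(scenario, template = template, seed = seed))
  }
  n <- as.integer(round(duration_s * fps))
  t <- (seq_len(n) - 1L) / fps
  pts_cm <- sweep(template$pts_cm, 2L, TARGET_ORIGIN_CM, `+`)
  tpts <- array(0, dim = c(n, 21L, 3L))
  for (d in 1:2) tpts[, , d] <- outer(rep(1, n), pts_cm[, d]) * camera_scale
  new_frame_stream(
    list(target = new_hand_track(t, tpts, rep(1, n), "left")),
    fps = fps,
    metadata = list(fake_hand = TRUE, handsize_cm = FAKE_HAND_SIZE_CM,
                    camera_scale = camera_scale))
}

#' Render a synthetic cohort with known ground truth
#'
#' Generates per-participant trial streams for each group, with
#' participant-level endpoint bias and noise drawn from group
#' distributions, plus a ground-truth table for parameter-recovery tests.
#'
#' @param groups Named list; each element a list with `n` (participants),
#'   `noise_sd_cm` (endpoint noise SD), optional `bias_sd_cm` (SD of the
#'   participant's constant bias vector, default 0) and optional `n_trials`
#'   (default 15).
#' @param seed RNG seed.
#' @param template A [hand_template()].
#' @param scenario_args Extra arguments passed to [pointing_scenario()].
#' @return List with `streams` (nested: group / participant / trial) and
#'   `truth` (data frame: group, participant_id, trial, true noise SD, bias
#'   vector, realised endpoint error).
#' @export
render_cohort <- function(groups, seed = 1L, template = hand_template(),
                          scenario_args = list()) {
  with_seed(seed, {
    streams <- list()
    rows <- list()
    for (g in names(groups)) {
      sp <- groups[[g]]
      n_tr <- if (is.null(sp$n_trials)) 15L else sp$n_trials
      bias_sd <- if (is.null(sp$bias_sd_cm)) 0 else sp$bias_sd_cm
      streams[[g]] <- vector("list", sp$n)
      if (sp$n == 0L) next
      for (p in seq_len(sp$n)) {
        pid <- sprintf("%s_%02d", g, p)
        bias <- stats::rnorm(2L, 0, bias_sd)
        fingers <- rep(FINGERS, length.out = n_tr)
        trials <- vector("list", n_tr)
        for (tr in seq_len(n_tr)) {
          sc <- do.call(pointing_scenario,
                        c(list(target_finger = fingers[tr], bias_cm = bias,
                               noise_sd_cm = sp$noise_sd_cm), scenario_args))
          st <- render_stream(sc, template = template)
          trials[[tr]] <- st
          rows[[length(rows) + 1L]] <- data.frame(
            group = g, participant_id = pid, trial = tr,
            finger = fingers[tr], noise_sd_cm = sp$noise_sd_cm,
            bias_x_cm = bias[1L], bias_y_cm = bias[2L],
            true_error_cm = st$metadata$truth_error_cm,
            stringsAsFactors = FALSE)
        }
        streams[[g]][[p]] <- trials
      }
    }
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(group = character(), participant_id = character(),
                 trial = integer(), finger = character(),
                 noise_sd_cm = numeric(), bias_x_cm = numeric(),
                 bias_y_cm = numeric(), true_error_cm = numeric())
    list(streams = streams, truth = truth)
  })
}

#' Joint pointing / Crisscross cohort with a shared latent deficit
#'
#' Simulates participants whose proprioceptive deficit scales both their
#' pointing endpoint noise and their Crisscross press-latency SD. Each
#' participant's multiplier is `exp(sd_log * (sqrt(shared) z0 +
#' sqrt(1-shared) z))` with `z0` common to both measures and `z` independent,
#' so `shared` is the fraction of log-deficit variance the two assessments
#' share. Pointing is simulated at endpoint level (radial magnitude of 2D
#' isotropic endpoint noise, averaged over trials); the Crisscross side runs
#' the full trial simulator.
#'
#' @param n Participants (default 16).
#' @param shared Shared-variance fraction in \[0, 1\] (default 0.8).
#' @param n_pointing_trials Pointing trials per participant (default 30).
#' @param base_noise_cm Baseline pointing endpoint noise SD (default 1 cm).
#' @param base_latency_sd Baseline press-latency SD in s (default 0.08).
#' @param deficit_log_sd SD of the log-deficit (default 0.6).
#' @param config A [crisscross_config()].
#' @param seed RNG seed.
#' @return List with `participants` (data frame: pointing_mean_cm,
#'   crisscross_mean_deg, the latent multipliers) and `validity` (the
#'   [concurrent_validity()] result).
#' @export
simulate_validity_cohort <- function(n = 16L, shared = 0.8,
                                     n_pointing_trials = 30L,
                                     base_noise_cm = 1,
                                     base_latency_sd = 0.08,
                                     deficit_log_sd = 0.6,
                                     config = crisscross_config(),
                                     seed = NULL) {
  stopifnot(n >= 3L, shared >= 0, shared <= 1)
  with_seed(seed, {
    z0 <- stats::rnorm(n)
    zp <- stats::rnorm(n)
    zc <- stats::rnorm(n)
    mult_point <- exp(deficit_log_sd * (sqrt(shared) * z0 + sqrt(1 - shared) * zp))
    mult_cc <- exp(deficit_log_sd * (sqrt(shared) * z0 + sqrt(1 - shared) * zc))
    pointing <- vapply(seq_len(n), function(i) {
      sdp <- base_noise_cm * mult_point[i]
      ex <- stats::rnorm(n_pointing_trials, 0, sdp)
      ey <- stats::rnorm(n_pointing_trials, 0, sdp)
      mean(sqrt(ex^2 + ey^2))
    }, numeric(1))
    crisscross <- vapply(seq_len(n), function(i) {
      simulate_participant(config, latency_bias = 0,
                           latency_sd = base_latency_sd * mult_cc[i])$mean_error_deg
    }, numeric(1))
    participants <- data.frame(
      participant = seq_len(n), pointing_mean_cm = pointing,
      crisscross_mean_deg = crisscross,
      mult_pointing = mult_point, mult_crisscross = mult_cc)
    list(participants = participants,
         validity = concurrent_validity(pointing, crisscross))
  })
}
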