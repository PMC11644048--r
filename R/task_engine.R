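# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. Keeps protocol/simulation seeds from disturbing
# the global RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Pointing-session protocol specification
#'
#' Two standard variants: `unimpaired_15` (15 pointing movements, 3 per
#' finger) and `stroke_30` (30 movements; balanced at 6 per finger by
#' default). Target fingers change randomly from trial to trial; the order is
#' reproducible from `order_seed`.
#'
#' @param variant `"unimpaired_15"` or `"stroke_30"`.
#' @param level Landmark level pointed to throughout the session (fixed per
#'   session, never mixed).
#' @param order_seed Integer RNG seed for the target order.
#' @param fingers Fingers used as targets (default all five).
#' @param n_trials,reps_per_finger Optional overrides; must satisfy
#'   `n_trials == reps_per_finger * length(fingers)`.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(variant = c("unimpaired_15", "stroke_30"),
                          level = "TIP", order_seed = 1L,
                          fingers = FINGERS,
                          n_trials = NULL, reps_per_finger = NULL) {
  variant <- match.arg(variant)
  fingers <- match.arg(fingers, FINGERS, several.ok = TRUE)
  if (is.null(n_trials))
    n_trials <- switch(variant, unimpaired_15 = 15L, stroke_30 = 30L)
  if (is.null(reps_per_finger)) {
    if (n_trials %% length(fingers) != 0L)
      stop("n_trials (", n_trials, ") is not divisible by the number of ",
           "target fingers (", length(fingers), ")", call. = FALSE)
    reps_per_finger <- n_trials %/% length(fingers)
  }
  if (n_trials != reps_per_finger * length(fingers))
    stop("n_trials must equal reps_per_finger * number of fingers",
         call. = FALSE)
  level <- match.arg(level, c("TIP", "PIP", "MCP"))
  structure(list(variant = variant, n_trials = as.integer(n_trials),
                 reps_per_finger = as.integer(reps_per_finger),
                 fingers = fingers, level = level,
                 order_seed = as.integer(order_seed)),
            class = "protocol_spec")
}

#' Generate the randomized target sequence of a session
#'
#' A seed-reproducible permutation of the balanced target list: each finger
#' appears exactly `reps_per_finger` times, with no adjacency constraint.
#'
#' @param spec A [protocol_spec()].
#' @return Data frame with columns `trial`, `finger`, `target_index` (the
#'   0-based landmark index of that finger at the session's level).
#' @export
generate_protocol <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  pool <- rep(spec$fingers, each = spec$reps_per_finger)
  order <- with_seed(spec$order_seed, sample(pool))
  lvl <- landmark_level(spec$level)
  data.frame(trial = seq_along(order), finger = order,
             target_index = unname(lvl$indices[order]),
             level = spec$level, stringsAsFactors = FALSE)
}

#' Stop-detection thresholds
#'
#' A pointing movement is considered finished at the first frame where both
#' hold: the calibrated error is within `proximity_radius_cm` of the target
#' landmark, and the standard deviation of the trailing `window_seconds` of
#' the error series has dropped below `sd_threshold_cm` (movement has slowed
#' or stopped). The window is `round(window_seconds * fps)` samples, so the
#' default 2 s window is 60 samples at 30 fps.
#'
#' @param proximity_radius_cm Proximity criterion (default 15 cm).
#' @param window_seconds Trailing window length (default 2 s).
#' @param sd_threshold_cm SD criterion (default 5 cm).
#' @param fps Frame rate used to derive the sample window (default 30).
#' @return An object of class `stop_criteria` with the derived
#'   `window_samples`.
#' @export
stop_criteria <- function(proximity_radius_cm = 15, window_seconds = 2,
                          sd_threshold_cm = 5, fps = 30) {
  stopifnot(proximity_radius_cm > 0, window_seconds > 0, sd_threshold_cm > 0,
            fps > 0)
  structure(list(proximity_radius_cm = proximity_radius_cm,
                 window_seconds = window_seconds,
                 sd_threshold_cm = sd_threshold_cm,
                 window_samples = as.integer(round(window_seconds * fps)),
                 fps = fps),
            class = "stop_criteria")
}

# Population SD (divide by n) of every trailing window of length w;
# NA where fewer than w samples are available. Cumulative-sum formulation.
trailing_sd <- function(x, w) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < w) return(out)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  i <- w:n
  s <- cs[i] - c(0, cs)[i - w + 1L]
  s2 <- cs2[i] - c(0, cs2)[i - w + 1L]
  out[i] <- sqrt(pmax(0, s2 / w - (s / w)^2))
  out
}

#' Detect when a pointing movement has stopped
#'
#' Returns the earliest series index satisfying both stop conditions (see
#' [stop_criteria()]); the trailing-window SD is the population SD over the
#' last `window_samples` samples of the calibrated centimeter error. No
#' hysteresis: the first index where both criteria hold wins.
#'
#' @param series An error series from [build_error_series()], or a bare
#'   numeric vector of centimeter errors.
#' @param criteria A [stop_criteria()].
#' @return A list with `index` (1-based stop index, or `NA` if never
#'   satisfied) and `reason`: `"stopped"`, `"never"`, or `"too_short"` when
#'   the series is shorter than the window.
#' @export
detect_stop <- function(series, criteria = stop_criteria()) {
  x <- if (inherits(series, "error_series")) series$error_cm else as.numeric(series)
  w <- criteria$window_samples
  if (length(x) < w)
    return(list(index = NA_integer_, reason = "too_short"))
  sds <- trailing_sd(x, w)
  hit <- which(x <= criteria$proximity_radius_cm & !is.na(sds) &
                 sds < criteria$sd_threshold_cm)
  if (length(hit) == 0L) return(list(index = NA_integer_, reason = "never"))
  list(index = hit[[1L]], reason = "stopped")
}

#' Start gate: the green start circle
#'
#' The trial begins when the pointing fingertip enters a start circle; a
#' countdown then runs before the "go" instruction. Circle geometry is
#' configuration-supplied (the display default places it in the upper part
#' of the frame).
#'
#' @param circle_center_px Length-2 pixel center.
#' @param circle_radius_px Radius in pixels (> 0).
#' @param countdown_seconds Countdown after the trigger (default 3 s).
#' @return An object of class `start_gate`.
#' @export
start_gate <- function(circle_center_px = c(320, 100), circle_radius_px = 40,
                       countdown_seconds = 3) {
  stopifnot(length(circle_center_px) == 2L, circle_radius_px > 0,
            countdown_seconds >= 0)
  structure(list(circle_center_px = as.numeric(circle_center_px),
                 circle_radius_px = circle_radius_px,
                 countdown_seconds = countdown_seconds),
            class = "start_gate")
}

#' Detect the start trigger
#'
#' Finds the first frame in which the pointing fingertip lies inside the
#' start circle (boundary inclusive). Never entering the circle is a
#' no-trigger result, not an error.
#'
#' @param stream A [frame_stream()] with a pointing hand.
#' @param gate A [start_gate()].
#' @param pointing_index Fingertip landmark (default 8).
#' @return List with `triggered` (logical), `t_trigger` (timestamp or `NA`),
#'   `frame` (index or `NA`) and `t_go` (`t_trigger + countdown`).
#' @export
detect_start <- function(stream, gate = start_gate(), pointing_index = 8L) {
  pnt <- stream$hands$pointing
  if (is.null(pnt)) stop("stream has no pointing hand", call. = FALSE)
  dx <- pnt$pts[, pointing_index + 1L, 1L] - gate$circle_center_px[1L]
  dy <- pnt$pts[, pointing_index + 1L, 2L] - gate$circle_center_px[2L]
  inside <- dx^2 + dy^2 <= gate$circle_radius_px^2
  if (!any(inside))
    return(list(triggered = FALSE, t_trigger = NA_real_, frame = NA_integer_,
                t_go = NA_real_))
  i <- which(inside)[[1L]]
  list(triggered = TRUE, t_trigger = pnt$t[i], frame = i,
       t_go = pnt$t[i] + gate$countdown_seconds)
}

#' Occlusion polygon over the target hand
#'
#' The display hides the target hand behind an opaque polygon so the
#' participant cannot see it. The polygon is the convex hull of the 21
#' landmarks, dilated outward by at least `margin_px` (uniform scaling about
#' the hull centroid so that every edge moves out by the margin or more).
#' Degenerate (collinear) landmark sets fall back to a margin-padded
#' bounding box.
#'
#' @param target_frame A [landmark_frame()] of the target hand.
#' @param margin_px Dilation margin in pixels (>= 0).
#' @return A matrix of polygon vertices (columns `x`, `y`), counter-clockwise.
#' @export
occlusion_polygon <- function(target_frame, margin_px = 10) {
  stopifnot(margin_px >= 0)
  xy <- target_frame$pts[, 1:2, drop = FALSE]
  hull <- tryCatch(grDevices::chull(xy[, 1L], xy[, 2L]), error = function(e) integer())
  degenerate <- length(hull) < 3L
  if (!degenerate) {
    v <- xy[hull, , drop = FALSE]
    ctr <- colMeans(v)
    # distance from the centroid to each hull edge; zero means collinear
    d_edge <- vapply(seq_len(nrow(v)), function(i) {
      a <- v[i, ]
      b <- v[if (i == nrow(v)) 1L else i + 1L, ]
      ab <- b - a
      len <- sqrt(sum(ab^2))
      if (len == 0) return(0)
      abs(ab[1L] * (ctr[2L] - a[2L]) - ab[2L] * (ctr[1L] - a[1L])) / len
    }, numeric(1))
    if (min(d_edge) <= .Machine$double.eps^0.5) degenerate <- TRUE
  }
  if (degenerate) {
    r <- rbind(c(min(xy[, 1L]) - margin_px, min(xy[, 2L]) - margin_px),
               c(max(xy[, 1L]) + margin_px, min(xy[, 2L]) - margin_px),
               c(max(xy[, 1L]) + margin_px, max(xy[, 2L]) + margin_px),
               c(min(xy[, 1L]) - margin_px, max(xy[, 2L]) + margin_px))
    colnames(r) <- c("x", "y")
    return(r)
  }
  scale <- 1 + margin_px / min(d_edge)
  out <- sweep(sweep(v, 2L, ctr) * scale, 2L, ctr, `+`)
  colnames(out) <- c("x", "y")
  out
}

#' Test whether points lie inside a convex polygon
#'
#' @param poly Vertex matrix from [occlusion_polygon()].
#' @param xy An `n x 2` matrix of points.
#' @param strict Require strict interior (default `FALSE`).
#' @return Logical vector.
#' @export
points_in_polygon <- function(poly, xy, strict = FALSE) {
  xy <- as.matrix(xy)
  n <- nrow(poly)
  ctr <- colMeans(poly)
  # orient counter-clockwise
  area2 <- sum(poly[, 1L] * poly[c(2:n, 1L), 2L] - poly[c(2:n, 1L), 1L] * poly[, 2L])
  if (area2 < 0) poly <- poly[n:1L, , drop = FALSE]
  inside <- rep(TRUE, nrow(xy))
  for (i in seq_len(n)) {
    a <- poly[i, ]
    b <- poly[if (i == n) 1L else i + 1L, ]
    cr <- (b[1L] - a[1L]) * (xy[, 2L] - a[2L]) - (b[2L] - a[2L]) * (xy[, 1L] - a[1L])
    inside <- inside & if (strict) cr > 0 else cr >= 0
  }
  inside
}

#' Truncate a trial at a movement correction
#'
#' Participants are instructed not to correct their initial pointing
#' movement; when they do, the trial should be scored at the frame before
#' the correction. A manual annotation (frame index) always wins and is
#' clamped to the detected stop. Without one, an optional heuristic finds the
#' last index of the first plateau (trailing window of at least
#' `plateau_seconds` with SD below the stop threshold) that is followed by
#' renewed movement; results are flagged with the truncation mode.
#'
#' @param series An error series (or numeric cm vector).
#' @param stop_index Detected stop index.
#' @param annotation Optional manual frame index (must be <= `stop_index`).
#' @param heuristic Apply the automatic plateau heuristic when no annotation
#'   is given (default `FALSE`: the reference procedure is manual).
#' @param criteria [stop_criteria()] supplying the SD threshold and fps.
#' @param plateau_seconds Minimum plateau duration (default 0.3 s).
#' @return List with `index` (effective stop) and `mode` (`"manual"`,
#'   `"heuristic"` or `"none"`).
#' @export
truncate_correction <- function(series, stop_index, annotation = NULL,
                                heuristic = FALSE,
                                criteria = stop_criteria(),
                                plateau_seconds = 0.3) {
  x <- if (inherits(series, "error_series")) series$error_cm else as.numeric(series)
  if (!is.null(annotation)) {
    if (annotation > stop_index)
      stop("manual annotation (", annotation, ") lies after the detected stop (",
           stop_index, ")", call. = FALSE)
    if (annotation < 1L) stop("annotation must be a positive index", call. = FALSE)
    return(list(index = as.integer(annotation), mode = "manual"))
  }
  if (!heuristic) return(list(index = as.integer(stop_index), mode = "none"))
  w <- max(2L, as.integer(round(plateau_seconds * criteria$fps)))
  sds <- trailing_sd(x[seq_len(stop_index)], w)
  stable <- !is.na(sds) & sds < criteria$sd_threshold_cm
  if (!any(stable)) return(list(index = as.integer(stop_index), mode = "none"))
  first <- which(stable)[[1L]]
  run_end <- first
  while (run_end < stop_index && stable[run_end + 1L]) run_end <- run_end + 1L
  # renewed movement after the plateau means the plateau was the intended stop
  if (run_end < stop_index)
    return(list(index = as.integer(run_end), mode = "heuristic"))
  list(index = as.integer(stop_index), mode = "none")
}

#' Score one pointing trial end to end
#'
#' Builds the calibrated error series, runs stop detection and (optionally)
#' correction truncation, and returns the trial's result record.
#'
#' @param stream A two-hand [frame_stream()] for one trial.
#' @param target_index Instructed target landmark index.
#' @param profile A [calibration_profile()].
#' @param criteria A [stop_criteria()]; its window defaults to the stream fps.
#' @param annotation Optional manual correction frame.
#' @param heuristic Apply the plateau heuristic (default `FALSE`).
#' @param pointing_index Pointing landmark (default 8).
#' @return One-row data frame: `target_index`, `level`, `stop_time`,
#'   `stop_index`, `final_error_cm`, `n_gap_frames`, `stop_reason`,
#'   `truncation`.
#' @export
score_trial <- function(stream, target_index, profile,
                        criteria = NULL, annotation = NULL, heuristic = FALSE,
                        pointing_index = 8L) {
  if (is.null(criteria)) criteria <- stop_criteria(fps = stream$fps)
  series <- build_error_series(stream, target_index, profile,
                               pointing_index = pointing_index)
  stp <- detect_stop(series, criteria)
  if (is.na(stp$index)) {
    return(data.frame(target_index = target_index, level = profile$level,
                      stop_time = NA_real_, stop_index = NA_integer_,
                      final_error_cm = NA_real_, n_gap_frames = series$n_gaps,
                      stop_reason = stp$reason, truncation = "none",
                      stringsAsFactors = FALSE))
  }
  trunc <- truncate_correction(series, stp$index, annotation = annotation,
                               heuristic = heuristic, criteria = criteria)
  data.frame(target_index = target_index, level = profile$level,
             stop_time = series$t[trunc$index], stop_index = trunc$index,
             final_error_cm = final_error(series, trunc$index),
             n_gap_frames = series$n_gaps, stop_reason = stp$reason,
             truncation = trunc$mode, stringsAsFactors = FALSE)
}
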