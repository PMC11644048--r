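#' Frontal-plane pointing error between two frames, in pixels
#'
#' Euclidean distance in the image plane between the pointing landmark of one
#' frame and the target landmark of the other. Depth is ignored by
#' construction: monocular depth estimates are unreliable, so the assessment
#' scores errors in the frontal plane only.
#'
#' @param pointing,target [landmark_frame()]s captured at (nearly) the same
#'   instant; timestamps must agree within half a frame period.
#' @param pointing_index Landmark index on the pointing hand (default 8, the
#'   index fingertip).
#' @param target_index Landmark index on the target hand.
#' @param fps Frame rate used for the alignment tolerance (default 30).
#' @return Distance in pixels (>= 0).
#' @export
frontal_error_px <- function(pointing, target, pointing_index = 8L,
                             target_index, fps = 30) {
  if (abs(pointing$t - target$t) > 1 / (2 * fps))
    stop(sprintf("frames misaligned: |%g - %g| s exceeds half a frame period",
                 pointing$t, target$t), call. = FALSE)
  p <- landmark_point(pointing, pointing_index)
  q <- landmark_point(target, target_index)
  sqrt(sum((p - q)^2))
}

#' Per-frame pointing-error series for one trial
#'
#' Aligns the pointing and target hand tracks of a stream by timestamp
#' (nearest neighbour within half a frame period), measures the frontal-plane
#' pixel distance between the pointing landmark and the instructed target
#' landmark in every aligned frame, and converts it to centimeters with the
#' hand-size calibration identity. The per-frame pixel hand size of the
#' target hand is smoothed with a running median to resist single-frame
#' tracking glitches. Frames where either hand is missing are excluded and
#' counted in `n_gaps`.
#'
#' @param stream A [frame_stream()] containing both hands.
#' @param target_index Instructed target landmark index (0..20).
#' @param profile A [calibration_profile()] for the target hand.
#' @param pointing_index Pointing landmark index (default 8).
#' @param edge_set Optional edge-set override for the hand-size sum.
#' @param smooth_k Running-median window (odd; default 9, truncated to the
#'   series length).
#' @return An object of class `error_series`: list with `t`, `error_px`,
#'   `error_cm`, `dx_px`/`dy_px` (signed frontal components, kept for
#'   endpoint scatter, never used for scoring), `handsize_px` (smoothed),
#'   `target_index`, `pointing_index`, `n_gaps`, `fps`, `profile`.
#' @export
build_error_series <- function(stream, target_index, profile,
                               pointing_index = 8L, edge_set = NULL,
                               smooth_k = 9L) {
  trg <- stream$hands$target
  pnt <- stream$hands$pointing
  if (is.null(trg)) stop("stream has no target hand", call. = FALSE)
  if (is.null(pnt)) stop("stream has no pointing hand", call. = FALSE)
  fps <- stream$fps
  tol <- 1 / (2 * fps)
  # nearest target frame for each pointing frame
  idx <- findInterval(pnt$t, trg$t)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(trg$t))
  pick <- ifelse(abs(pnt$t - trg$t[lo]) <= abs(pnt$t - trg$t[hi]), lo, hi)
  ok <- abs(pnt$t - trg$t[pick]) <= tol
  n_gaps <- sum(!ok) + (length(trg$t) - length(unique(pick[ok])))
  if (!any(ok))
    stop("pointing and target tracks share no overlapping span", call. = FALSE)
  pi1 <- pointing_index + 1L
  ti1 <- target_index + 1L
  dx <- pnt$pts[ok, pi1, 1L] - trg$pts[pick[ok], ti1, 1L]
  dy <- pnt$pts[ok, pi1, 2L] - trg$pts[pick[ok], ti1, 2L]
  error_px <- sqrt(dx^2 + dy^2)
  edges <- if (is.null(edge_set)) hand_edges(profile$level) else edge_set
  a <- edges[, 1L] + 1L
  b <- edges[, 2L] + 1L
  tsel <- pick[ok]
  ex <- trg$pts[tsel, a, 1L, drop = FALSE] - trg$pts[tsel, b, 1L, drop = FALSE]
  ey <- trg$pts[tsel, a, 2L, drop = FALSE] - trg$pts[tsel, b, 2L, drop = FALSE]
  hs_px <- rowSums(sqrt(ex^2 + ey^2))
  k <- min(smooth_k, length(hs_px))
  if (k %% 2L == 0L) k <- k - 1L
  hs_smooth <- if (k >= 3L) as.numeric(stats::runmed(hs_px, k, endrule = "median"))
               else hs_px
  error_cm <- error_px_to_cm(error_px, profile$handsize_cm, hs_smooth)
  structure(list(t = pnt$t[ok], error_px = error_px, error_cm = error_cm,
                 dx_px = dx, dy_px = dy, handsize_px = hs_smooth,
                 target_index = target_index, pointing_index = pointing_index,
                 n_gaps = n_gaps, fps = fps, profile = profile),
            class = "error_series")
}

#' @export
print.error_series <- function(x, ...) {
  cat(sprintf(
    "<error_series> %d frames, target landmark %d, final sample %.2f cm, %d gap frames\n",
    length(x$t), x$target_index, x$error_cm[length(x$error_cm)], x$n_gaps))
  invisible(x)
}

#' @export
length.error_series <- function(x) length(x$t)

#' Final pointing error of a trial
#'
#' The calibrated centimeter error at the detected (or manually corrected)
#' stop frame; this is the trial's proprioception score.
#'
#' @param series An [build_error_series()] result.
#' @param stop_index Stop frame (1-based index into the series).
#' @return Error in cm.
#' @export
final_error <- function(series, stop_index) {
  n <- length(series$error_cm)
  if (length(stop_index) != 1L || !is.finite(stop_index) ||
      stop_index < 1L || stop_index > n)
    stop("stop_index out of range (series has ", n, " samples)", call. = FALSE)
  series$error_cm[[stop_index]]
}
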