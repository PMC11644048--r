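#' Landmark indices for a pointing level
#'
#' The 21-point hand skeleton indexes the wrist as 0 and each finger as a
#' chain of four landmarks. Participants may be instructed to point to the
#' fingertip (`TIP`), the proximal interphalangeal joint (`PIP`) or the
#' metacarpophalangeal joint (`MCP`), depending on how far they can extend
#' the target hand. This helper returns, for a level, the landmark index of
#' that joint on each finger.
#'
#' The thumb has no PIP/MCP in the four-finger sense; its interphalangeal
#' joint (index 3) stands in at `PIP` level and its first carpometacarpal /
#' metacarpophalangeal node (index 2) at `MCP` level.
#'
#' @param level One of `"TIP"`, `"PIP"`, `"MCP"`.
#' @return An object of class `landmark_level`: a list with `level` and
#'   `indices`, a named integer vector (thumb, index, middle, ring, pinky)
#'   of 0-based landmark indices.
#' @examples
#' landmark_level("TIP")$indices
#' @export
landmark_level <- function(level = c("TIP", "PIP", "MCP")) {
  level <- match.arg(level)
  indices <- switch(level,
    TIP = c(thumb = 4L, index = 8L, middle = 12L, ring = 16L, pinky = 20L),
    PIP = c(thumb = 3L, index = 6L, middle = 10L, ring = 14L, pinky = 18L),
    MCP = c(thumb = 2L, index = 5L, middle = 9L, ring = 13L, pinky = 17L)
  )
  structure(list(level = level, indices = indices), class = "landmark_level")
}

FINGERS <- c("thumb", "index", "middle", "ring", "pinky")

#' Construct a single landmark frame
#'
#' One time-stamped sample of a hand's 21 tracked landmarks in image pixel
#' coordinates (origin top-left, x right, y down). The relative-depth
#' coordinate `z` is carried through I/O but is never used by any error
#' computation: pointing errors are restricted to the frontal plane.
#'
#' @param t Timestamp in seconds.
#' @param hand `"target"` (the hand held still and occluded) or
#'   `"pointing"` (the hand doing the pointing).
#' @param side `"left"` or `"right"`.
#' @param pts A 21 x 3 numeric matrix of (x_px, y_px, z_rel) rows.
#' @param conf Tracking confidence in \[0, 1\].
#' @return An object of class `landmark_frame`.
#' @export
landmark_frame <- function(t, hand, side, pts, conf = 1) {
  pts <- as.matrix(pts)
  frame <- structure(
    list(t = as.numeric(t), hand = hand, side = side,
         pts = pts, conf = as.numeric(conf)),
    class = "landmark_frame"
  )
  validate_landmark_frame(frame)
  frame
}

validate_landmark_frame <- function(frame, where = "frame") {
  pts <- frame$pts
  if (!is.matrix(pts) || nrow(pts) != 21L || ncol(pts) != 3L)
    stop(where, ": expected a 21 x 3 landmark matrix, got ",
         paste(dim(pts), collapse = " x "), call. = FALSE)
  xy <- pts[, 1:2]
  if (any(!is.finite(xy)))
    stop(where, ": non-finite x/y pixel coordinate", call. = FALSE)
  if (any(xy < 0))
    stop(where, ": negative pixel coordinate (image origin is top-left)",
         call. = FALSE)
  if (!frame$hand %in% c("target", "pointing"))
    stop(where, ": hand must be 'target' or 'pointing'", call. = FALSE)
  if (!frame$side %in% c("left", "right"))
    stop(where, ": side must be 'left' or 'right'", call. = FALSE)
  if (!is.finite(frame$t))
    stop(where, ": non-finite timestamp", call. = FALSE)
  if (!is.finite(frame$conf) || frame$conf < 0 || frame$conf > 1)
    stop(where, ": confidence must lie in [0, 1]", call. = FALSE)
  invisible(frame)
}

#' Extract the 2D pixel position of one landmark
#'
#' @param frame A [landmark_frame()].
#' @param index Landmark index, 0 to 20 (0 = wrist, 8 = index fingertip).
#' @return Numeric length-2 vector `c(x_px, y_px)`; depth is discarded.
#' @export
landmark_point <- function(frame, index) {
  if (length(index) != 1L || !is.finite(index) || index < 0 || index > 20 ||
      index != as.integer(index))
    stop("landmark index must be a single integer in 0..20", call. = FALSE)
  unname(frame$pts[index + 1L, 1:2])
}

new_hand_track <- function(t, pts, conf, side) {
  list(t = as.numeric(t), pts = pts, conf = as.numeric(conf), side = side)
}

#' Construct a two-hand landmark frame stream
#'
#' A `frame_stream` holds per-hand sequences of landmark frames (one "target"
#' hand, one "pointing" hand; either may be absent) together with the nominal
#' tracking frame rate and free-form session metadata. Timestamps must be
#' strictly increasing within each hand. All sample-count windows downstream
#' (e.g. the stop detector's 2 s window) are derived as
#' `round(window_seconds * fps)`.
#'
#' @param frames A list of [landmark_frame()] objects (any hand order).
#' @param fps Nominal frame rate in Hz (default 30).
#' @param metadata Named list (session id, participant id, seed, ...).
#' @return An object of class `frame_stream` with elements `hands` (named
#'   list of per-hand tracks: `t`, `pts` an `n x 21 x 3` array, `conf`,
#'   `side`), `fps` and `metadata`.
#' @export
frame_stream <- function(frames, fps = 30, metadata = list()) {
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  hands <- list()
  for (h in c("target", "pointing")) {
    sel <- Filter(function(f) f$hand == h, frames)
    if (length(sel) == 0L) next
    for (i in seq_along(sel)) {
      validate_landmark_frame(sel[[i]], where = paste0(h, " frame ", i))
    }
    t <- vapply(sel, function(f) f$t, numeric(1))
    if (any(diff(t) <= 0))
      stop("timestamps must be strictly increasing within the ", h, " hand",
           call. = FALSE)
    pts <- array(NA_real_, dim = c(length(sel), 21L, 3L))
    for (i in seq_along(sel)) pts[i, , ] <- sel[[i]]$pts
    conf <- vapply(sel, function(f) f$conf, numeric(1))
    side <- sel[[1L]]$side
    hands[[h]] <- new_hand_track(t, pts, conf, side)
  }
  structure(list(hands = hands, fps = fps, metadata = metadata),
            class = "frame_stream")
}

new_frame_stream <- function(hands, fps = 30, metadata = list()) {
  structure(list(hands = hands, fps = fps, metadata = metadata),
            class = "frame_stream")
}

#' Number of frames per hand in a stream
#' @param stream A [frame_stream()].
#' @return Named integer vector of frame counts.
#' @export
n_frames <- function(stream) {
  vapply(stream$hands, function(h) length(h$t), integer(1))
}

#' Extract one frame of one hand as a `landmark_frame`
#' @param stream A [frame_stream()].
#' @param hand `"target"` or `"pointing"`.
#' @param i Frame number (1-based).
#' @return A [landmark_frame()].
#' @export
get_frame <- function(stream, hand, i) {
  trk <- stream$hands[[hand]]
  if (is.null(trk)) stop("stream has no '", hand, "' hand", call. = FALSE)
  if (i < 1 || i > length(trk$t)) stop("frame index out of range", call. = FALSE)
  landmark_frame(trk$t[i], hand, trk$side, trk$pts[i, , ], trk$conf[i])
}

#' @export
print.frame_stream <- function(x, ...) {
  cat("<frame_stream>", "\n")
  for (h in names(x$hands)) {
    trk <- x$hands[[h]]
    cat(sprintf("  %-8s: %d frames, side=%s, t=[%.3f, %.3f] s\n",
                h, length(trk$t), trk$side,
                if (length(trk$t)) min(trk$t) else NA,
                if (length(trk$t)) max(trk$t) else NA))
  }
  cat(sprintf("  fps_nominal: %g\n", x$fps))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

STREAM_FORMAT_VERSION <- 1L

#' Read a landmark frame stream from disk
#'
#' Two dialects are supported. JSONL: a header record
#' `{"type":"header","version":1,"fps":...,"metadata":{...}}` followed by one
#' record per frame,
#' `{"t":...,"hand":"target|pointing","side":"left|right","pts":[[x,y,z] x 21],"conf":...}`.
#' CSV: comment lines `#version=`/`#fps=` followed by columns
#' `t,hand,side,conf,x0..x20,y0..y20,z0..z20`. Frames violating the stream
#' invariants are rejected with an error naming the offending record; nothing
#' is silently repaired.
#'
#' @param path File path.
#' @param dialect `"jsonl"` or `"csv"`; default inferred from the extension.
#' @return A validated [frame_stream()].
#' @export
read_stream <- function(path, dialect = c("auto", "jsonl", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "jsonl") read_stream_jsonl(path) else read_stream_csv(path)
}

read_stream_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty stream file: ", path, call. = FALSE)
  header <- tryCatch(jsonlite::fromJSON(lines[[1L]], simplifyVector = FALSE),
                     error = function(e)
                       stop("line 1: malformed JSON header: ",
                            conditionMessage(e), call. = FALSE))
  if (is.null(header$type) || header$type != "header")
    stop("line 1: expected a header record", call. = FALSE)
  fps <- if (is.null(header$fps)) 30 else header$fps
  metadata <- if (is.null(header$metadata)) list() else header$metadata
  frames <- vector("list", length(lines) - 1L)
  for (i in seq_along(frames)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i + 1L]], simplifyVector = TRUE),
                    error = function(e)
                      stop("line ", i + 1L, ": malformed JSON record: ",
                           conditionMessage(e), call. = FALSE))
    for (fld in c("t", "hand", "side", "pts"))
      if (is.null(rec[[fld]]))
        stop("line ", i + 1L, ": missing field '", fld, "'", call. = FALSE)
    pts <- rec$pts
    if (is.list(pts)) pts <- do.call(rbind, pts)
    pts <- as.matrix(pts)
    if (nrow(pts) != 21L || ncol(pts) != 3L)
      stop("line ", i + 1L, ": expected 21 [x,y,z] points, got ",
           nrow(pts), " x ", ncol(pts), call. = FALSE)
    conf <- if (is.null(rec$conf)) 1 else rec$conf
    frames[[i]] <- tryCatch(
      landmark_frame(rec$t, rec$hand, rec$side, pts, conf),
      error = function(e) stop("line ", i + 1L, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  frame_stream(frames, fps = fps, metadata = metadata)
}

read_stream_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  fps <- 30
  metadata <- list()
  for (ml in meta_lines) {
    kv <- sub("^#", "", ml)
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    if (key == "fps") fps <- as.numeric(val)
    else if (key != "version") metadata[[key]] <- val
  }
  df <- utils::read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"),
                        stringsAsFactors = FALSE)
  needed <- c("t", "hand", "side", "conf",
              paste0("x", 0:20), paste0("y", 0:20), paste0("z", 0:20))
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("CSV stream missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  frames <- lapply(seq_len(nrow(df)), function(i) {
    pts <- cbind(as.numeric(df[i, paste0("x", 0:20)]),
                 as.numeric(df[i, paste0("y", 0:20)]),
                 as.numeric(df[i, paste0("z", 0:20)]))
    tryCatch(landmark_frame(df$t[i], df$hand[i], df$side[i], pts, df$conf[i]),
             error = function(e) stop("record ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
  frame_stream(frames, fps = fps, metadata = metadata)
}

#' Write a landmark frame stream to disk
#'
#' Writes the same JSONL or CSV dialect that [read_stream()] accepts.
#' Coordinates are written at full double precision so that a write/read
#' round trip reproduces the stream exactly. A stream containing non-finite
#' coordinates is refused.
#'
#' @param stream A [frame_stream()].
#' @param path Output file path.
#' @param dialect `"jsonl"` or `"csv"`; default inferred from the extension.
#' @export
write_stream <- function(stream, path, dialect = c("auto", "jsonl", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  for (h in names(stream$hands)) {
    if (any(!is.finite(stream$hands[[h]]$pts)))
      stop("refusing to write stream with non-finite coordinates (", h,
           " hand)", call. = FALSE)
  }
  rows <- stream_as_records(stream)
  if (dialect == "jsonl") {
    header <- jsonlite::toJSON(
      list(type = "header", version = STREAM_FORMAT_VERSION, fps = stream$fps,
           metadata = stream$metadata),
      auto_unbox = TRUE, digits = NA)
    recs <- vapply(rows, function(r) {
      as.character(jsonlite::toJSON(
        list(t = r$t, hand = r$hand, side = r$side, pts = r$pts, conf = r$conf),
        auto_unbox = TRUE, digits = NA, matrix = "rowmajor"))
    }, character(1))
    writeLines(c(as.character(header), recs), path)
  } else {
    df <- do.call(rbind, lapply(rows, function(r) {
      out <- data.frame(t = r$t, hand = r$hand, side = r$side, conf = r$conf,
                        stringsAsFactors = FALSE)
      for (j in 0:20) out[[paste0("x", j)]] <- r$pts[j + 1L, 1L]
      for (j in 0:20) out[[paste0("y", j)]] <- r$pts[j + 1L, 2L]
      for (j in 0:20) out[[paste0("z", j)]] <- r$pts[j + 1L, 3L]
      out
    }))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#version=", STREAM_FORMAT_VERSION), con)
    writeLines(paste0("#fps=", format(stream$fps, digits = 17)), con)
    for (key in names(stream$metadata))
      writeLines(paste0("#", key, "=", stream$metadata[[key]]), con)
    if (is.null(df)) {
      writeLines(paste(c("t", "hand", "side", "conf",
                         paste0("x", 0:20), paste0("y", 0:20), paste0("z", 0:20)),
                       collapse = ","), con)
    } else {
      utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                       con, row.names = FALSE, quote = FALSE)
    }
  }
  invisible(path)
}

# Flatten a stream into per-frame records ordered by timestamp (ties: target
# first), the canonical serialisation order.
stream_as_records <- function(stream) {
  rows <- list()
  for (h in c("target", "pointing")) {
    trk <- stream$hands[[h]]
    if (is.null(trk)) next
    for (i in seq_along(trk$t)) {
      rows[[length(rows) + 1L]] <- list(
        t = trk$t[i], hand = h, side = trk$side,
        pts = matrix(trk$pts[i, , ], 21L, 3L), conf = trk$conf[i])
    }
  }
  if (length(rows) == 0L) return(rows)
  ord <- order(vapply(rows, `[[`, numeric(1), "t"),
               match(vapply(rows, `[[`, character(1), "hand"),
                     c("target", "pointing")))
  rows[ord]
}

#' Uniformly rescale all pixel coordinates of a stream
#'
#' Multiplies every x/y pixel coordinate (and z, which scales with the image)
#' of every frame by `k`, emulating a change of camera distance or zoom with
#' unchanged physical geometry. Hand-size-based calibration makes the
#' centimeter error series invariant under this transformation.
#'
#' @param stream A [frame_stream()].
#' @param k Positive scale factor.
#' @return The rescaled [frame_stream()].
#' @export
rescale_stream <- function(stream, k) {
  if (!is.finite(k) || k <= 0) stop("k must be positive", call. = FALSE)
  for (h in names(stream$hands)) stream$hands[[h]]$pts <- stream$hands[[h]]$pts * k
  stream
}
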