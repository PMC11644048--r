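#' Default hand-skeleton edge set for hand-size measurement
#'
#' Hand size in pixels is defined as the sum of the Euclidean 2D distances
#' along the hand-skeleton connections (the palm edges plus each finger's
#' chain of joints). At reduced pointing levels the finger chains are
#' truncated at the level's terminal landmark, so the `TIP` edge set is a
#' superset of `PIP`, which is a superset of `MCP`.
#'
#' @param level A [landmark_level()] or level name.
#' @return Integer matrix with columns `from`, `to` (0-based landmark
#'   indices).
#' @export
hand_edges <- function(level = "TIP") {
  if (inherits(level, "landmark_level")) level <- level$level
  level <- match.arg(level, c("TIP", "PIP", "MCP"))
  palm <- rbind(c(0L, 1L), c(0L, 5L), c(5L, 9L), c(9L, 13L), c(13L, 17L),
                c(0L, 17L))
  chain <- function(idx) if (length(idx) < 2L) NULL else cbind(idx[-length(idx)], idx[-1L])
  chains <- switch(level,
    TIP = list(1:4, 5:8, 9:12, 13:16, 17:20),
    PIP = list(1:3, 5:6, 9:10, 13:14, 17:18),
    MCP = list(1:2, 5L, 9L, 13L, 17L)
  )
  edges <- do.call(rbind, c(list(palm), lapply(chains, chain)))
  colnames(edges) <- c("from", "to")
  edges
}

#' Hand size in pixels
#'
#' Sums the frontal-plane (2D) pixel distance over an edge set of hand
#' skeleton connections for one frame. Depth is ignored. The result is
#' homogeneous of degree one in the pixel coordinates and invariant to
#' rigid translation/rotation, which is what makes it usable as a
#' per-frame pixel-to-centimeter scale reference.
#'
#' @param frame A [landmark_frame()], or a bare `n x >=2` coordinate matrix
#'   (for toy geometries; edge indices must then address its rows, 0-based).
#' @param level A [landmark_level()] or level name; determines the default
#'   edge set.
#' @param edge_set Optional integer matrix of 0-based `from`,`to` index pairs
#'   overriding the default skeleton edges.
#' @return Hand size in pixels (positive scalar).
#' @export
hand_size_px <- function(frame, level = "TIP", edge_set = NULL) {
  pts <- if (inherits(frame, "landmark_frame")) frame$pts else as.matrix(frame)
  if (is.null(edge_set)) edge_set <- hand_edges(level)
  edge_set <- as.matrix(edge_set)
  if (nrow(edge_set) == 0L) stop("edge set is empty", call. = FALSE)
  if (any(edge_set < 0L) || any(edge_set >= nrow(pts)))
    stop("edge set indexes a landmark outside the frame", call. = FALSE)
  a <- pts[edge_set[, 1L] + 1L, 1:2, drop = FALSE]
  b <- pts[edge_set[, 2L] + 1L, 1:2, drop = FALSE]
  size <- sum(sqrt(rowSums((a - b)^2)))
  if (size <= 0)
    stop("degenerate frame: all edge lengths are zero", call. = FALSE)
  size
}

US_LETTER_PERIMETER_CM <- 2 * (8.5 + 11) * 2.54  # 99.06 cm

#' Pixel density from a reference object of known perimeter
#'
#' Converts the measured pixel perimeter of a flat reference object in a
#' calibration photo (by default a page of US letter paper, perimeter
#' 99.06 cm) into a pixels-per-centimeter scale.
#'
#' @param reference_perimeter_px Measured perimeter in pixels (> 0).
#' @param paper `"us_letter"` or a custom perimeter in cm.
#' @return Scale in px/cm.
#' @export
pixels_per_cm <- function(reference_perimeter_px, paper = "us_letter") {
  if (!is.finite(reference_perimeter_px) || reference_perimeter_px <= 0)
    stop("reference perimeter must be a positive number of pixels",
         call. = FALSE)
  perimeter_cm <- if (identical(paper, "us_letter")) US_LETTER_PERIMETER_CM
                  else as.numeric(paper)
  if (!is.finite(perimeter_cm) || perimeter_cm <= 0)
    stop("paper perimeter must be positive (cm)", call. = FALSE)
  reference_perimeter_px / perimeter_cm
}

#' Hand size in centimeters from a calibration photo
#'
#' Given a landmark frame extracted from a photo of the hand lying flat next
#' to a scale reference (graph paper / letter page), computes the metric hand
#' size as the pixel hand size divided by the photo's pixel density. The
#' result is invariant to the photo's resolution: doubling both the photo
#' pixels and the reference perimeter pixels leaves it unchanged.
#'
#' @param photo_frame A [landmark_frame()] from the calibration photo.
#' @param scale A scale reference created by [scale_reference()].
#' @inheritParams hand_size_px
#' @return Hand size in cm.
#' @export
hand_size_cm_from_photo <- function(photo_frame, scale, level = "TIP",
                                    edge_set = NULL) {
  if (missing(scale) || is.null(scale))
    stop("a scale reference is required", call. = FALSE)
  stopifnot(inherits(scale, "scale_reference"))
  hand_size_px(photo_frame, level = level, edge_set = edge_set) /
    scale$pixels_per_cm
}

#' Scale reference for a calibration photo
#'
#' @param reference_perimeter_px Measured reference perimeter in pixels.
#' @param paper `"us_letter"` or a custom perimeter in cm.
#' @return An object of class `scale_reference` with `pixels_per_cm`.
#' @export
scale_reference <- function(reference_perimeter_px, paper = "us_letter") {
  ppc <- pixels_per_cm(reference_perimeter_px, paper)
  structure(list(reference_perimeter_px = reference_perimeter_px,
                 reference_perimeter_cm = reference_perimeter_px / ppc,
                 pixels_per_cm = ppc),
            class = "scale_reference")
}

# Sex-specific normative hand sizes (cm), measured from calibration photos of
# the post-stroke cohort; used when no per-participant photo is available.
DEFAULT_HAND_SIZE_CM <- c(female = 49.87, male = 54.84)
FAKE_HAND_SIZE_CM <- 60

#' Default hand size by sex
#'
#' Returns the sex-specific average metric hand size used when no calibration
#' photo is available: 49.87 cm for women and 54.84 cm for men. An
#' unspecified sex is an error: measure the hand instead
#' ([hand_size_cm_from_photo()]).
#'
#' @param sex `"female"` or `"male"`.
#' @return Hand size in cm.
#' @export
default_hand_size_cm <- function(sex) {
  if (missing(sex) || length(sex) != 1L || !sex %in% names(DEFAULT_HAND_SIZE_CM))
    stop("sex must be 'female' or 'male'; for other cases use a measured ",
         "calibration photo (hand_size_cm_from_photo)", call. = FALSE)
  unname(DEFAULT_HAND_SIZE_CM[[sex]])
}

#' Convert a pixel error to centimeters using hand size
#'
#' The core calibration identity: `error_cm = handsize_cm / handsize_px *
#' error_px`. Because `handsize_px` is measured in the same frame as the
#' pixel error, any uniform pixel rescaling (camera distance, zoom) cancels
#' and the centimeter error is scale-invariant.
#'
#' @param error_px Pixel error(s), >= 0 (vectorised).
#' @param handsize_cm Metric hand size (cm, > 0).
#' @param handsize_px Pixel hand size in the same frame(s) (> 0, recycled).
#' @return Error(s) in cm.
#' @export
error_px_to_cm <- function(error_px, handsize_cm, handsize_px) {
  if (any(!is.finite(handsize_px)) || any(handsize_px <= 0))
    stop("handsize_px must be positive", call. = FALSE)
  if (!is.finite(handsize_cm) || handsize_cm <= 0)
    stop("handsize_cm must be positive", call. = FALSE)
  (handsize_cm / handsize_px) * error_px
}

#' Calibration profile for one participant's target hand
#'
#' Bundles the metric hand size with its provenance and the landmark level at
#' which it was computed. The same level must be used when measuring
#' `handsize_px` at scoring time, otherwise the ratio in the calibration
#' identity mixes incompatible sums.
#'
#' @param handsize_cm Metric hand size (> 0). For `source = "fake_hand"` this
#'   is fixed at 60 cm (the cardboard hand used in no-proprioception control
#'   conditions) and may be omitted.
#' @param source `"measured_photo"`, `"sex_default"` or `"fake_hand"`.
#' @param sex `"female"`, `"male"` or `"unspecified"`.
#' @param level Landmark level name at which handsize was computed.
#' @param participant_id Optional identifier carried into results.
#' @return An object of class `calibration_profile`.
#' @export
calibration_profile <- function(handsize_cm = NULL,
                                source = c("measured_photo", "sex_default",
                                           "fake_hand"),
                                sex = "unspecified", level = "TIP",
                                participant_id = NA_character_) {
  source <- match.arg(source)
  if (source == "fake_hand") {
    if (!is.null(handsize_cm) && handsize_cm != FAKE_HAND_SIZE_CM)
      stop("the fake hand has a fixed size of ", FAKE_HAND_SIZE_CM, " cm",
           call. = FALSE)
    handsize_cm <- FAKE_HAND_SIZE_CM
  }
  if (source == "sex_default" && is.null(handsize_cm))
    handsize_cm <- default_hand_size_cm(sex)
  if (is.null(handsize_cm) || !is.finite(handsize_cm) || handsize_cm <= 0)
    stop("handsize_cm must be a positive number", call. = FALSE)
  level <- match.arg(level, c("TIP", "PIP", "MCP"))
  structure(list(handsize_cm = handsize_cm, source = source, sex = sex,
                 level = level, participant_id = participant_id),
            class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat(sprintf("<calibration_profile> %.2f cm (%s, level %s)\n",
              x$handsize_cm, x$source, x$level))
  invisible(x)
}

#' Read/write a calibration profile as JSON
#' @param path JSON file path.
#' @return [calibration_profile()] for `read_calibration`; `path`
#'   (invisibly) for `write_calibration`.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("no such calibration file: ", path, call. = FALSE)
  x <- jsonlite::fromJSON(path)
  calibration_profile(handsize_cm = x$handsize_cm, source = x$source,
                      sex = if (is.null(x$sex)) "unspecified" else x$sex,
                      level = x$level,
                      participant_id = if (is.null(x$participant_id))
                        NA_character_ else x$participant_id)
}

#' @rdname read_calibration
#' @param profile A [calibration_profile()].
#' @export
write_calibration <- function(profile, path) {
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
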