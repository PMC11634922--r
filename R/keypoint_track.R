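#' BODY_25 keypoint names
#'
#' Names of the 25 keypoints of the BODY_25 2D skeleton layout emitted by
#' common pose estimators (index 1 in R corresponds to keypoint 0, the nose).
#'
#' @format Character vector of length 25.
#' @export
BODY25_NAMES <- c(
  "nose", "neck", "r_shoulder", "r_elbow", "r_wrist",
  "l_shoulder", "l_elbow", "l_wrist", "mid_hip", "r_hip",
  "r_knee", "r_ankle", "l_hip", "l_knee", "l_ankle",
  "r_eye", "l_eye", "r_ear", "l_ear", "l_big_toe",
  "l_small_toe", "l_heel", "r_big_toe", "r_small_toe", "r_heel"
)

N_KEYPOINTS <- 25L

# 1-based indices of frequently used keypoints
KP_NOSE <- 1L
KP_NECK <- 2L
KP_MIDHIP <- 9L
KP_RWRIST <- 5L
KP_LWRIST <- 8L

#' Construct a keypoint track
#'
#' A keypoint track holds one person's 2D keypoint trajectories over the
#' frames of a recording, together with per-keypoint detection confidences
#' and a missingness mask. Positions are in image pixels with the origin at
#' the top-left corner, so the y coordinate increases downward; an upward
#' head bounce therefore decreases y.
#'
#' @param positions numeric array `frames x 25 x 2`, the (x, y) pixel
#'   coordinates of each keypoint in each frame.
#' @param confidence numeric matrix `frames x 25` of detection confidences
#'   in `[0, 1]`. Pose estimators emit 0 for undetected keypoints.
#' @param fps frame rate in frames per second.
#' @param missing_mask logical matrix `frames x 25`; `TRUE` marks samples
#'   treated as missing. By default, derived from `confidence <
#'   conf_threshold`.
#' @param conf_threshold confidence below which a keypoint sample is treated
#'   as missing. Default 0.1: undetected keypoints are emitted with
#'   confidence 0, and a small positive threshold also absorbs near-zero
#'   jitter detections.
#'
#' @return An object of class `keypoint_track`.
#' @export
keypoint_track <- function(positions, confidence, fps,
                           missing_mask = NULL, conf_threshold = 0.1) {
  positions <- unname(positions)
  confidence <- unname(as.matrix(confidence))
  if (length(dim(positions)) != 3L || dim(positions)[2] != N_KEYPOINTS ||
      dim(positions)[3] != 2L) {
    stopf("positions must be a frames x %d x 2 array", N_KEYPOINTS)
  }
  n <- dim(positions)[1]
  if (!all(dim(confidence) == c(n, N_KEYPOINTS))) {
    stopf("confidence must be a frames x %d matrix", N_KEYPOINTS)
  }
  if (any(confidence < 0 | confidence > 1, na.rm = TRUE)) {
    stopf("confidence values must lie in [0, 1]")
  }
  if (is.null(missing_mask)) {
    missing_mask <- confidence < conf_threshold | is.na(confidence)
  }
  missing_mask <- unname(as.matrix(missing_mask))
  structure(
    list(
      positions = positions,
      confidence = confidence,
      missing_mask = missing_mask,
      fps = fps,
      n_frames = n
    ),
    class = "keypoint_track"
  )
}

#' @export
print.keypoint_track <- function(x, ...) {
  cat(sprintf(
    "<keypoint_track> %d frames @ %g fps, %d keypoints, %.1f%% missing\n",
    x$n_frames, x$fps, N_KEYPOINTS, 100 * mean(x$missing_mask)
  ))
  invisible(x)
}

#' Construct a dyad recording
#'
#' Bundles the two aligned keypoint tracks of an interacting dyad. By
#' convention the child is the first member and the mother the second; the
#' sign convention of relative phase and lead--lag labels follows this
#' ordering.
#'
#' @param child,mother `keypoint_track` objects with identical frame counts
#'   and frame rates.
#' @param dyad_id identifier string.
#'
#' @return An object of class `dyad_recording`.
#' @export
dyad_recording <- function(child, mother, dyad_id = "dyad") {
  stopifnot(inherits(child, "keypoint_track"), inherits(mother, "keypoint_track"))
  if (child$n_frames != mother$n_frames) {
    stopf("child and mother tracks differ in frame count (%d vs %d)",
          child$n_frames, mother$n_frames)
  }
  if (child$fps != mother$fps) {
    stopf("child and mother tracks differ in frame rate")
  }
  structure(
    list(
      child = child,
      mother = mother,
      fps = child$fps,
      n_frames = child$n_frames,
      dyad_id = dyad_id
    ),
    class = "dyad_recording"
  )
}

#' @export
print.dyad_recording <- function(x, ...) {
  cat(sprintf(
    "<dyad_recording> '%s': %d frames @ %g fps (%.1f s)\n",
    x$dyad_id, x$n_frames, x$fps, x$n_frames / x$fps
  ))
  invisible(x)
}

#' Truncate a dyad recording to its first `n` frames
#'
#' Used to harmonize recording lengths before building pseudo-dyads.
#'
#' @param dyad a `dyad_recording`.
#' @param n number of frames to keep.
#' @return A `dyad_recording` with `n` frames.
#' @export
truncate_dyad <- function(dyad, n) {
  if (n > dyad$n_frames) stopf("cannot truncate %d frames to %d", dyad$n_frames, n)
  trim <- function(tr) {
    keypoint_track(
      positions = tr$positions[seq_len(n), , , drop = FALSE],
      confidence = tr$confidence[seq_len(n), , drop = FALSE],
      fps = tr$fps,
      missing_mask = tr$missing_mask[seq_len(n), , drop = FALSE]
    )
  }
  dyad_recording(trim(dyad$child), trim(dyad$mother), dyad$dyad_id)
}
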