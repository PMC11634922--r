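#' Read OpenPose-style per-frame JSON detections
#'
#' Reads a directory of per-frame JSON files in the BODY_25 OpenPose dialect:
#' each file holds a top-level `"people"` list, and each person a flat
#' `"pose_keypoints_2d"` vector of 75 numbers (25 keypoints times x, y,
#' confidence). Frames are ordered by the numeric index embedded in the file
#' name (zero-padded suffix), so enumeration order of the directory does not
#' matter.
#'
#' Frames with zero, one, two, or more than two detected people are kept
#' as-is; identity resolution happens downstream in [assign_identities()].
#'
#' @param path directory containing one JSON file per frame.
#' @return A list with one element per frame; each element is a list of
#'   person detections, each a `25 x 3` numeric matrix (x, y, confidence).
#'   Frame order follows the numeric file-name index.
#' @export
load_openpose_frames <- function(path) {
  if (!dir.exists(path)) stopf("not a directory: %s", path)
  files <- list.files(path, pattern = "\\.json$", full.names = TRUE)
  if (length(files) == 0L) stopf("no JSON frame files found in %s", path)
  # order frames by trailing numeric index in the file name
  idx <- suppressWarnings(as.integer(sub(".*?([0-9]+)[^0-9]*\\.json$", "\\1",
                                         basename(files))))
  if (anyNA(idx)) stopf("frame files must carry a numeric index: %s",
                        basename(files[which(is.na(idx))[1]]))
  files <- files[order(idx)]
  lapply(files, read_openpose_frame)
}

read_openpose_frame <- function(file) {
  obj <- tryCatch(
    jsonlite::fromJSON(file, simplifyVector = TRUE, simplifyDataFrame = FALSE),
    error = function(e) stopf("malformed JSON in %s: %s", basename(file),
                              conditionMessage(e))
  )
  if (is.null(obj$people)) stopf("no 'people' field in %s", basename(file))
  lapply(obj$people, function(p) {
    kp <- p$pose_keypoints_2d
    if (length(kp) != 3L * N_KEYPOINTS) {
      stopf("person in %s has %d keypoint numbers, expected %d",
            basename(file), length(kp), 3L * N_KEYPOINTS)
    }
    matrix(as.numeric(kp), ncol = 3L, byrow = TRUE)
  })
}

#' Resolve person identities across frames
#'
#' Links per-frame detections into two continuous tracks by greedy
#' nearest-centroid matching: each frame's detections are attached to the
#' track whose last known centroid is closest (for two detections, the
#' pairing with the smaller total centroid distance wins). The track with the
#' larger median neck-to-mid-hip pixel distance -- a stature proxy -- is
#' labeled the mother, the other the child. Frames in which a track has no
#' detection contribute all-missing rows.
#'
#' @param frames raw detections from [load_openpose_frames()].
#' @param fps frame rate in frames per second.
#' @param conf_threshold confidence below which a keypoint is missing (see
#'   [keypoint_track()]).
#' @param dyad_id identifier for the resulting recording.
#' @return A [dyad_recording()] with `child` and `mother` tracks.
#' @export
assign_identities <- function(frames, fps, conf_threshold = 0.1,
                              dyad_id = "dyad") {
  n <- length(frames)
  n_det <- vapply(frames, length, integer(1))
  if (!any(n_det >= 2L)) {
    stopf("unusable recording: no frame contains two detections")
  }

  pos <- array(NA_real_, c(n, N_KEYPOINTS, 2L, 2L)) # frame, kp, axis, track
  conf <- array(0, c(n, N_KEYPOINTS, 2L))

  det_centroid <- function(d) {
    ok <- d[, 3] >= conf_threshold
    if (!any(ok)) return(c(NA_real_, NA_real_))
    c(mean(d[ok, 1]), mean(d[ok, 2]))
  }

  first <- which(n_det >= 2L)[1]
  last_cent <- matrix(NA_real_, 2L, 2L) # track x (x, y)

  put <- function(i, track, d) {
    pos[i, , 1, track] <<- d[, 1]
    pos[i, , 2, track] <<- d[, 2]
    conf[i, , track] <<- d[, 3]
    ct <- det_centroid(d)
    if (!anyNA(ct)) last_cent[track, ] <<- ct
  }

  # seed the two tracks from the first two-person frame
  put(first, 1L, frames[[first]][[1]])
  put(first, 2L, frames[[first]][[2]])

  assign_frame <- function(i) {
    dets <- frames[[i]]
    if (length(dets) == 0L) return(invisible())
    cents <- t(vapply(dets, det_centroid, numeric(2)))
    dist2 <- function(a, b) sum((a - b)^2)
    if (length(dets) == 1L) {
      d1 <- dist2(cents[1, ], last_cent[1, ])
      d2 <- dist2(cents[1, ], last_cent[2, ])
      put(i, if (isTRUE(d1 <= d2) || is.na(d2)) 1L else 2L, dets[[1]])
    } else {
      if (length(dets) > 2L) {
        # keep the two detections nearest the current track centroids
        dd <- vapply(seq_along(dets), function(k) {
          min(dist2(cents[k, ], last_cent[1, ]), dist2(cents[k, ], last_cent[2, ]))
        }, numeric(1))
        keep <- order(dd)[1:2]
        dets <- dets[keep]
        cents <- cents[keep, , drop = FALSE]
      }
      straight <- dist2(cents[1, ], last_cent[1, ]) + dist2(cents[2, ], last_cent[2, ])
      crossed <- dist2(cents[1, ], last_cent[2, ]) + dist2(cents[2, ], last_cent[1, ])
      if (is.na(crossed) || isTRUE(straight <= crossed)) {
        put(i, 1L, dets[[1]]); put(i, 2L, dets[[2]])
      } else {
        put(i, 2L, dets[[1]]); put(i, 1L, dets[[2]])
      }
    }
    invisible()
  }

  if (first < n) for (i in (first + 1L):n) assign_frame(i)
  # walk backwards from the seed frame so earlier frames are linked too
  last_cent[1, ] <- det_centroid(frames[[first]][[1]])
  last_cent[2, ] <- det_centroid(frames[[first]][[2]])
  if (first > 1L) for (i in (first - 1L):1L) assign_frame(i)

  make_track <- function(track) {
    p <- pos[, , , track, drop = FALSE]
    dim(p) <- c(n, N_KEYPOINTS, 2L)
    p[is.na(p)] <- 0
    keypoint_track(p, conf[, , track], fps, conf_threshold = conf_threshold)
  }
  t1 <- make_track(1L)
  t2 <- make_track(2L)

  if (stature_px(t2) >= stature_px(t1)) {
    dyad_recording(child = t1, mother = t2, dyad_id = dyad_id)
  } else {
    dyad_recording(child = t2, mother = t1, dyad_id = dyad_id)
  }
}

# Median neck-to-mid-hip pixel distance over frames where both are detected.
stature_px <- function(track) {
  ok <- !track$missing_mask[, KP_NECK] & !track$missing_mask[, KP_MIDHIP]
  if (!any(ok)) return(0)
  d <- sqrt((track$positions[ok, KP_NECK, 1] - track$positions[ok, KP_MIDHIP, 1])^2 +
            (track$positions[ok, KP_NECK, 2] - track$positions[ok, KP_MIDHIP, 2])^2)
  stats::median(d)
}

#' Fill missing keypoint samples by interpolation
#'
#' Interior gaps in each keypoint coordinate series are filled by
#' piecewise-linear interpolation on the frame index (the default behavior
#' of MATLAB-style `interp1`); leading and trailing runs of missing frames
#' are filled by holding the nearest valid value. The missingness mask of
#' filled keypoints is cleared. A keypoint series with fewer than two valid
#' samples cannot be interpolated: it is flagged unusable (recorded in the
#' `unusable` attribute) and its mask is left set; an error is raised only
#' when such a keypoint is actually requested downstream.
#'
#' Interpolation is idempotent: applying it twice gives the same track.
#'
#' @param track a [keypoint_track()].
#' @return The track with gaps filled.
#' @export
interpolate_missing <- function(track) {
  n <- track$n_frames
  unusable <- logical(N_KEYPOINTS)
  for (k in seq_len(N_KEYPOINTS)) {
    miss <- track$missing_mask[, k]
    if (!any(miss)) next
    valid <- which(!miss)
    if (length(valid) < 2L) {
      unusable[k] <- TRUE
      next
    }
    for (ax in 1:2) {
      track$positions[, k, ax] <- stats::approx(
        x = valid, y = track$positions[valid, k, ax],
        xout = seq_len(n), method = "linear", rule = 2
      )$y
    }
    track$missing_mask[, k] <- FALSE
  }
  attr(track, "unusable") <- unusable
  track
}

#' Is a keypoint usable in a track?
#'
#' A keypoint is usable when it has at least two valid (non-missing) samples,
#' so that interpolation can produce a finite series.
#'
#' @param track a [keypoint_track()].
#' @param kp 1-based keypoint index.
#' @return Logical scalar.
#' @export
keypoint_usable <- function(track, kp) {
  sum(!track$missing_mask[, kp]) >= 2L
}

csv_columns <- function() {
  cols <- character(0)
  for (role in c("child", "mother")) {
    for (k in seq_len(N_KEYPOINTS)) {
      cols <- c(cols, paste(role, BODY25_NAMES[k], c("x", "y", "c"), sep = "_"))
    }
  }
  c("frame", cols)
}

#' Write a dyad recording to a flattened CSV
#'
#' One row per frame; columns `frame` then `<role>_<keypoint>_{x,y,c}` for
#' both roles (child first) and all 25 BODY_25 keypoints. Positions are
#' written as stored, including the zero coordinates of undetected
#' keypoints, so a write/read round trip reproduces the recording exactly.
#'
#' @param dyad a [dyad_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dyad_csv <- function(dyad, path) {
  n <- dyad$n_frames
  flat <- function(tr) {
    m <- matrix(0, n, 3L * N_KEYPOINTS)
    for (k in seq_len(N_KEYPOINTS)) {
      m[, 3 * k - 2] <- tr$positions[, k, 1]
      m[, 3 * k - 1] <- tr$positions[, k, 2]
      m[, 3 * k] <- tr$confidence[, k]
    }
    m
  }
  df <- data.frame(frame = seq_len(n) - 1L, flat(dyad$child), flat(dyad$mother))
  names(df) <- csv_columns()
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a dyad recording from a flattened CSV
#'
#' Inverse of [write_dyad_csv()]. The frame rate is not stored in the CSV
#' and must be supplied.
#'
#' @param path CSV path written by [write_dyad_csv()] (or equivalent).
#' @param fps frame rate in frames per second.
#' @param conf_threshold confidence threshold for the missingness mask.
#' @param dyad_id identifier for the recording.
#' @return A [dyad_recording()].
#' @export
read_dyad_csv <- function(path, fps, conf_threshold = 0.1, dyad_id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  expected <- csv_columns()
  if (!all(expected %in% names(df))) {
    stopf("CSV %s lacks expected dyad columns (found %d of %d)",
          path, sum(expected %in% names(df)), length(expected))
  }
  n <- nrow(df)
  unflat <- function(role) {
    p <- array(0, c(n, N_KEYPOINTS, 2L))
    conf <- matrix(0, n, N_KEYPOINTS)
    for (k in seq_len(N_KEYPOINTS)) {
      base <- paste(role, BODY25_NAMES[k], sep = "_")
      p[, k, 1] <- df[[paste0(base, "_x")]]
      p[, k, 2] <- df[[paste0(base, "_y")]]
      conf[, k] <- df[[paste0(base, "_c")]]
    }
    keypoint_track(p, conf, fps, conf_threshold = conf_threshold)
  }
  dyad_recording(unflat("child"), unflat("mother"),
                 dyad_id = dyad_id %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a dyad recording as per-frame OpenPose-style JSON
#'
#' Fixture factory emitting the same JSON dialect that
#' [load_openpose_frames()] consumes: one file per frame named
#' `frame_NNNNNN_keypoints.json`, each with a `"people"` list of persons
#' carrying 75-number `"pose_keypoints_2d"` vectors. The child is written
#' first in each frame's people list; person order is irrelevant to
#' [assign_identities()].
#'
#' @param dyad a [dyad_recording()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_openpose_json <- function(dyad, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  person_vec <- function(tr, i) {
    v <- rbind(tr$positions[i, , 1], tr$positions[i, , 2], tr$confidence[i, ])
    as.numeric(v)
  }
  for (i in seq_len(dyad$n_frames)) {
    people <- list(
      list(pose_keypoints_2d = person_vec(dyad$child, i)),
      list(pose_keypoints_2d = person_vec(dyad$mother, i))
    )
    # drop persons entirely absent in this frame
    people <- people[c(any(dyad$child$confidence[i, ] > 0),
                       any(dyad$mother$confidence[i, ] > 0))]
    jsonlite::write_json(
      list(version = 1.3, people = people),
      file.path(dir, sprintf("frame_%06d_keypoints.json", i - 1L)),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
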