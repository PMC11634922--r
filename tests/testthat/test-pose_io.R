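# Reading OpenPose-style JSON, identity assignment, interpolation, CSV IO.

test_that("JSON round trip preserves detections and resolves identities", {
  dyad <- tiny_dyad(kappa = 2, duration_s = 3, seed = 7, missing_rate = 0.1)
  dir <- withr::local_tempdir()
  write_openpose_json(dyad, dir)

  frames <- load_openpose_frames(dir)
  expect_length(frames, dyad$n_frames)
  expect_true(all(vapply(frames, length, integer(1)) <= 2))

  rec <- assign_identities(frames, fps = dyad$fps)
  expect_s3_class(rec, "dyad_recording")
  expect_identical(rec$n_frames, dyad$n_frames)
  # mother is rendered taller, so stature labeling must recover the roles;
  # detected samples must survive the round trip exactly
  keep <- !dyad$mother$missing_mask
  expect_equal(rec$mother$positions[, , 1][keep],
               dyad$mother$positions[, , 1][keep])
  keep_c <- !dyad$child$missing_mask
  expect_equal(rec$child$positions[, , 2][keep_c],
               dyad$child$positions[, , 2][keep_c])
  # dropped samples carry missing_mask
  expect_true(all(rec$mother$missing_mask[dyad$mother$missing_mask]))
})

test_that("frames with no people and malformed persons are handled", {
  dir <- withr::local_tempdir()
  jsonlite::write_json(list(version = 1.3, people = list()),
                       file.path(dir, "frame_000000_keypoints.json"),
                       auto_unbox = TRUE)
  frames <- load_openpose_frames(dir)
  expect_length(frames[[1]], 0L)

  # 74 numbers instead of 75 is a format error naming the file
  jsonlite::write_json(
    list(people = list(list(pose_keypoints_2d = as.numeric(1:74)))),
    file.path(dir, "frame_000001_keypoints.json"), auto_unbox = TRUE
  )
  expect_error(load_openpose_frames(dir), "74 keypoint numbers")

  writeLines("{not json", file.path(dir, "frame_000001_keypoints.json"))
  expect_error(load_openpose_frames(dir), "malformed JSON")
})

test_that("frame order follows the numeric index, not enumeration order", {
  dir <- withr::local_tempdir()
  # prefixes chosen so lexicographic enumeration disagrees with the index
  write_person <- function(file, x) {
    sk <- fake_skeleton(x, 100)
    jsonlite::write_json(
      list(people = list(list(pose_keypoints_2d = as.numeric(t(sk))),
                         list(pose_keypoints_2d = as.numeric(t(fake_skeleton(400, 100, 140)))))),
      file.path(dir, file), auto_unbox = TRUE, digits = NA
    )
  }
  write_person("zz_000000_keypoints.json", 10)
  write_person("aa_000001_keypoints.json", 20)
  write_person("mm_000002_keypoints.json", 30)
  frames <- load_openpose_frames(dir)
  expect_equal(vapply(frames, function(f) f[[1]][2, 1], numeric(1)),
               c(10, 20, 30))
})

test_that("identity assignment survives crossing trajectories", {
  # two skeletons swap sides; per-frame motion is far smaller than their
  # separation, so nearest-centroid continuity must keep labels stable
  n <- 120
  xa <- seq(100, 500, length.out = n) # short person, moving right
  xb <- seq(500, 100, length.out = n) # tall person, moving left
  frames <- lapply(seq_len(n), function(i) {
    dets <- list(fake_skeleton(xa[i], 200, stature = 80),
                 fake_skeleton(xb[i], 150, stature = 140))
    if (i %% 2 == 0) rev(dets) else dets # detection order must not matter
  })
  rec <- assign_identities(frames, fps = 30)
  # child follows xa (neck x), mother follows xb, through the crossing
  expect_equal(rec$child$positions[, 2, 1], xa, tolerance = 1e-12)
  expect_equal(rec$mother$positions[, 2, 1], xb, tolerance = 1e-12)
})

test_that("assignment errors when no frame has two detections", {
  frames <- list(list(fake_skeleton(100, 100)), list())
  expect_error(assign_identities(frames, fps = 30), "unusable recording")
})

test_that("one person absent in some frames yields missing rows", {
  n <- 50
  drop_idx <- seq(5, 50, by = 10)
  frames <- lapply(seq_len(n), function(i) {
    dets <- list(fake_skeleton(100, 200, stature = 80))
    if (!(i %in% drop_idx)) {
      dets <- c(dets, list(fake_skeleton(400, 150, stature = 140)))
    }
    dets
  })
  rec <- assign_identities(frames, fps = 30)
  expect_true(all(rec$mother$missing_mask[drop_idx, ]))
  expect_false(any(rec$mother$missing_mask[-drop_idx, ]))
  expect_false(any(rec$child$missing_mask))
})

test_that("interpolation fills linear gaps exactly and holds the edges", {
  y <- as.numeric(1:30)
  tr <- flat_track(y)
  tr$missing_mask[4:6, 1] <- TRUE   # interior gap on a ramp
  tr$positions[4:6, 1, ] <- 0
  tr$missing_mask[1:3, 2] <- TRUE   # leading gap on the (constant) neck
  out <- interpolate_missing(tr)
  expect_equal(out$positions[4:6, 1, 2], c(4, 5, 6))
  expect_equal(out$positions[1:3, 2, 2], rep(120, 3)) # held nearest value
  expect_false(any(out$missing_mask[, 1:2]))
})

test_that("interpolation is idempotent and identity on complete tracks", {
  dyad <- tiny_dyad(duration_s = 3, seed = 2, missing_rate = 0.15)
  once <- interpolate_missing(dyad$child)
  twice <- interpolate_missing(once)
  expect_equal(twice$positions, once$positions)

  clean <- tiny_dyad(duration_s = 3, seed = 2, missing_rate = 0)$child
  expect_equal(interpolate_missing(clean)$positions, clean$positions)
})

test_that("keypoints with under two valid samples are flagged unusable", {
  tr <- flat_track(sin(1:100))
  tr$missing_mask[, 5] <- TRUE
  tr$missing_mask[1, 5] <- FALSE
  out <- interpolate_missing(tr)
  expect_true(attr(out, "unusable")[5])
  expect_false(keypoint_usable(tr, 5))
  expect_true(keypoint_usable(tr, 1))
})

test_that("CSV round trip is exact to machine precision", {
  dyad <- tiny_dyad(duration_s = 3, seed = 9, missing_rate = 0.05)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dyad_csv(dyad, path)
  back <- read_dyad_csv(path, fps = dyad$fps)
  expect_identical(back$n_frames, dyad$n_frames)
  expect_equal(back$child$positions, dyad$child$positions, tolerance = 1e-12)
  expect_equal(back$mother$positions, dyad$mother$positions, tolerance = 1e-12)
  expect_equal(back$child$confidence, dyad$child$confidence, tolerance = 1e-12)
  expect_equal(back$mother$missing_mask, dyad$mother$missing_mask)
})
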