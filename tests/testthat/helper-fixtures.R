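# Small fixture builders shared across test files.

# A short synthetic dyad; defaults keep unit tests fast.
tiny_dyad <- function(kappa = 3, duration_s = 10, seed = 1, missing_rate = 0,
                      ...) {
  generate_dyad(
    coupling_spec(kappa = kappa, duration_s = duration_s, seed = seed,
                  missing_rate = missing_rate, ...),
    dyad_id = sprintf("tiny_k%g_s%d", kappa, seed)
  )
}

# A bare-bones keypoint track with a single informative keypoint series.
flat_track <- function(y_nose, fps = 30, conf = 0.9) {
  n <- length(y_nose)
  pos <- array(0, c(n, 25, 2))
  pos[, 1, 2] <- y_nose
  pos[, 1, 1] <- 100
  # give neck/mid-hip fixed positions so stature is defined
  pos[, 2, 1] <- 100; pos[, 2, 2] <- 120
  pos[, 9, 1] <- 100; pos[, 9, 2] <- 220
  keypoint_track(pos, matrix(conf, n, 25), fps)
}

# Hand-built frame detections: a skeleton as a 25 x 3 matrix centered at
# (cx, cy) with a given neck-to-hip stature.
fake_skeleton <- function(cx, cy, stature = 100, conf = 0.9) {
  m <- matrix(0, 25, 3)
  m[, 1] <- cx + seq(-12, 12)            # spread x so centroid is cx
  m[, 2] <- cy + seq(-12, 12) * 0.1
  m[2, 1:2] <- c(cx, cy)                 # neck
  m[9, 1:2] <- c(cx, cy + stature)       # mid-hip
  m[, 3] <- conf
  m
}
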