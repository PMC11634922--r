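# Generalized cross-wavelet transform: complex-plane distribution fit,
# reduction to the bivariate cross-spectrum, and its stated invariances.

test_that("complex distribution fit matches hand computations", {
  # {1, -1}: a line along the real axis through the origin -- the fit sees
  # in-phase and anti-phase values as the same axis
  f <- fit_complex_distribution(c(1 + 0i, -1 + 0i))
  expect_equal(f$second_moment, matrix(c(1, 0, 0, 0), 2), tolerance = 1e-12)
  expect_equal(f$magnitude, 1)
  expect_equal(f$eccentricity, 1)
  expect_equal(f$axis_angle, 0)

  # {1, i}: isotropic pair, tie-break angle to 0
  g <- fit_complex_distribution(c(1 + 0i, 0 + 1i))
  expect_equal(g$second_moment, matrix(c(0.5, 0, 0, 0.5), 2), tolerance = 1e-12)
  expect_equal(g$eccentricity, 0)
  expect_equal(g$axis_angle, 0)

  # a line at 45 degrees
  h <- fit_complex_distribution(c(1 + 1i, -1 - 1i) / sqrt(2))
  expect_equal(h$axis_angle, pi / 4, tolerance = 1e-12)

  expect_error(fit_complex_distribution(complex(real = NaN, imaginary = 1)),
               "no finite")
})

test_that("isotropic Gaussian clouds have low eccentricity", {
  set.seed(10)
  z <- complex(real = rnorm(1e4), imaginary = rnorm(1e4))
  expect_lt(fit_complex_distribution(z)$eccentricity, 0.1)
  # mean-centered fit removes an offset the origin fit keeps
  off <- fit_complex_distribution(z + 100, about_origin = FALSE)
  expect_lt(off$eccentricity, 0.1)
  expect_gt(fit_complex_distribution(z + 100)$eccentricity, 0.9)
})

test_that("multivariate CWT yields one spectrum per usable component", {
  dyad <- tiny_dyad(duration_s = 4, seed = 3)
  st <- multivariate_cwt(dyad$child)
  expect_length(st$spectra, 50L)
  expect_identical(nrow(st$components), 50L)

  # single component reduces to the plain CWT of the detrended series
  one <- multivariate_cwt(dyad$child, keypoints = 1, axes = "y")
  tr <- interpolate_missing(dyad$child)
  direct <- morlet_cwt(dyadsync:::detrend_linear(tr$positions[, 1, 2]), dyad$fps)
  expect_equal(one$spectra[[1]], direct$coefficients, tolerance = 1e-9)

  # constant components are dropped with a warning
  flat <- dyad$child
  flat$positions[, 3, 1] <- 5
  flat$positions[, 3, 2] <- 7
  expect_warning(st2 <- multivariate_cwt(flat, keypoints = c(1, 3)),
                 "constant")
  expect_length(st2$spectra, 2L)
  expect_error(suppressWarnings(multivariate_cwt(flat, keypoints = 3)),
               "all components unusable")
})

test_that("pairwise cross values count N x M and are Hermitian in swap", {
  dyad <- tiny_dyad(duration_s = 4, seed = 4)
  sx <- multivariate_cwt(dyad$child, keypoints = c(1, 2), axes = "y")   # N=2
  sy <- multivariate_cwt(dyad$mother, keypoints = c(1, 2, 9), axes = "y") # M=3
  v <- pairwise_cross_values(sx, sy, scale_idx = 10, time_idx = 50)
  expect_identical(dim(v), c(2L, 3L))
  vswap <- pairwise_cross_values(sy, sx, scale_idx = 10, time_idx = 50)
  expect_equal(vswap, Conj(t(v)), tolerance = 1e-12)

  # N = M = 1 without normalization is the raw bivariate cross-spectrum cell
  ax <- multivariate_cwt(dyad$child, keypoints = 1, axes = "y")
  ay <- multivariate_cwt(dyad$mother, keypoints = 1, axes = "y")
  cell <- pairwise_cross_values(ax, ay, 7, 33, normalize = FALSE)[1, 1]
  expect_equal(cell, ax$spectra[[1]][7, 33] * Conj(ay$spectra[[1]][7, 33]),
               tolerance = 1e-12)
})

test_that("whole-map closed form agrees with the per-cell eigen fit", {
  dyad <- tiny_dyad(duration_s = 4, seed = 5)
  sx <- multivariate_cwt(dyad$child, keypoints = c(1, 5, 9), axes = c("x", "y"))
  sy <- multivariate_cwt(dyad$mother, keypoints = c(1, 5, 9), axes = c("x", "y"))
  maps <- gcwt_maps(sx, sy)
  set.seed(6)
  for (k in 1:12) {
    i <- sample(length(maps$scales), 1)
    j <- sample(length(maps$times), 1)
    cell <- fit_complex_distribution(pairwise_cross_values(sx, sy, i, j))
    expect_equal(maps$magnitude[i, j], cell$magnitude, tolerance = 1e-9)
    expect_equal(maps$eccentricity[i, j], cell$eccentricity, tolerance = 1e-6)
    if (cell$eccentricity > 0.05) {
      expect_equal(maps$axis_angle[i, j], cell$axis_angle, tolerance = 1e-6)
    }
  }
  expect_identical(maps$n_pairs, 36L)
  expect_true(all(maps$eccentricity >= 0 & maps$eccentricity <= 1))
  expect_true(all(maps$axis_angle >= 0 & maps$axis_angle < pi))
  expect_true(all(maps$magnitude >= 0))
})

test_that("univariate GCWT reduces to the bivariate cross-spectrum", {
  dyad <- tiny_dyad(duration_s = 4, seed = 7)
  sx <- multivariate_cwt(dyad$child, keypoints = 1, axes = "y")
  sy <- multivariate_cwt(dyad$mother, keypoints = 1, axes = "y")
  maps <- gcwt_maps(sx, sy, normalize = FALSE)
  direct <- Mod(sx$spectra[[1]] * Conj(sy$spectra[[1]]))
  expect_lt(max(abs(maps$magnitude - direct)), 1e-9)
})

test_that("anti-phase indifference and component-order invariance hold", {
  dyad <- tiny_dyad(duration_s = 4, seed = 8)
  kp <- c(1, 5, 8, 9)
  base <- gcwt_dyad(dyad, keypoint_set = kp)

  flipped <- dyad
  flipped$mother$positions <- -flipped$mother$positions
  neg <- gcwt_dyad(flipped, keypoint_set = kp)
  expect_lt(max(abs(base$magnitude - neg$magnitude)), 1e-9)
  expect_equal(base$mean_magnitude, neg$mean_magnitude, tolerance = 1e-12)

  perm <- gcwt_dyad(dyad, keypoint_set = rev(kp))
  expect_lt(max(abs(base$magnitude - perm$magnitude)), 1e-9)
  expect_lt(max(abs(base$axis_angle - perm$axis_angle)), 1e-9)
})

test_that("identical inputs give zero mutual phase angle", {
  dyad <- tiny_dyad(duration_s = 4, seed = 9)
  twin <- dyad_recording(dyad$child, dyad$child, "twin")
  maps <- gcwt_dyad(twin, keypoint_set = c(1, 9))
  sel <- maps$coi_mask & maps$eccentricity > 0.2
  expect_lt(max(maps$axis_angle[sel]), 1e-6)
})

test_that("stronger coupling raises the mean GCWT magnitude (paired)", {
  diffs <- vapply(1:8, function(s) {
    d8 <- generate_dyad(coupling_spec(kappa = 8, duration_s = 60, seed = 300 + s))
    d0 <- generate_dyad(coupling_spec(kappa = 0, duration_s = 60, seed = 300 + s))
    gcwt_dyad(d8, keypoint_set = "reduced")$mean_magnitude -
      gcwt_dyad(d0, keypoint_set = "reduced")$mean_magnitude
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.7)
})
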