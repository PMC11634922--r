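# Morlet CWT and wavelet coherence: analytic identities, scale
# registration, energy conservation, and the independent time-domain oracle.

fs <- 30

test_that("constant signals transform to zero and the CWT is linear", {
  sp <- morlet_cwt(rep(3, 128), fs)
  expect_lt(max(Mod(sp$coefficients)), 1e-9)

  set.seed(1)
  x <- rnorm(128)
  a <- morlet_cwt(x, fs)
  b <- morlet_cwt(2 * x, fs)
  expect_equal(b$coefficients, 2 * a$coefficients, tolerance = 1e-12)
})

test_that("a pure 2 Hz tone peaks at a 0.5 s Fourier period", {
  t <- (0:2047) / fs
  sp <- morlet_cwt(sin(2 * pi * 2 * t), fs)
  peak <- sp$periods[which.max(rowMeans(Mod(sp$coefficients)^2))]
  expect_lt(abs(peak - 0.5) / 0.5, 0.02)
})

test_that("scale grid and cone of influence have the promised shape", {
  sp <- morlet_cwt(rnorm(512), fs)
  expect_true(all(diff(sp$scales) > 0))
  expect_true(all(sp$coi > 0))
  # coi shrinks to the record edges and peaks in the middle
  expect_lt(sp$coi[1], sp$coi[256])
  expect_lt(sp$coi[512], sp$coi[256])
})

test_that("non-finite and too-short inputs are rejected", {
  expect_error(morlet_cwt(c(rnorm(100), NA), fs), "non-finite")
  expect_error(morlet_cwt(rnorm(10), fs), "too short")
  expect_error(wavelet_coherence(rnorm(128), rnorm(127), fs), "lengths differ")
  expect_error(wavelet_coherence(rnorm(128), rep(1, 128), fs), "degenerate")
})

test_that("broadband variance is recovered from the scaleogram", {
  # Parseval-style reconstruction with the Morlet admissibility constant
  # C_delta = 0.776 (Torrence & Compo): var ~ dj*dt/(C_delta*N) sum |W|^2/s
  set.seed(7)
  x <- rnorm(2048)
  sp <- morlet_cwt(x, fs, max_period = 2048 / fs / 2)
  recon <- (1 / 12) * (1 / fs) / (0.776 * length(x)) *
    sum(Mod(sp$coefficients)^2 / sp$scales)
  expect_lt(abs(recon - stats::var(x)) / stats::var(x), 0.1)
})

test_that("self- and anti-phase coherence hit the analytic limits", {
  set.seed(2)
  x <- rnorm(1024)
  self <- wavelet_coherence(x, x, fs)
  expect_lt(max(abs(self$coherence - 1)), 1e-6)
  expect_equal(self$mean_coherence, 1, tolerance = 1e-6)

  anti <- wavelet_coherence(x, -x, fs)
  expect_lt(max(abs(anti$coherence - 1)), 1e-6)
  expect_lt(max(abs(abs(anti$phase) - pi)), 1e-6)
})

test_that("coherence is invariant to affine transforms of either input", {
  set.seed(3)
  x <- rnorm(256)
  y <- as.numeric(stats::filter(rnorm(256), 0.8, "recursive"))
  base <- wavelet_coherence(x, y, fs)
  aff <- wavelet_coherence(3.7 * x + 11, y, fs)
  expect_lt(max(abs(base$coherence - aff$coherence)), 1e-9)
  expect_lt(max(abs(base$phase - aff$phase)), 1e-9)

  neg <- wavelet_coherence(-2 * x, y, fs)
  expect_lt(max(abs(base$coherence - neg$coherence)), 1e-9)
  # phase flips by pi under sign reversal
  dphi <- (neg$phase - base$phase) %% (2 * pi)
  expect_lt(max(abs(dphi - pi)), 1e-6)
})

test_that("coherence matches the independent time-domain oracle", {
  set.seed(11)
  for (i in 1:3) {
    x <- as.numeric(stats::filter(rnorm(2048), 0.7, "recursive"))
    y <- as.numeric(stats::filter(rnorm(2048), 0.7, "recursive"))
    r <- wavelet_coherence(x, y, fs)
    o <- oracle_coherence(x, y, fs, r$scales)
    expect_lt(sqrt(mean((r$coherence - o)^2)), 0.02)
  }
})

test_that("mean coherence averages the requested region", {
  set.seed(4)
  r <- wavelet_coherence(rnorm(256), rnorm(256), fs)
  r$coherence[] <- 1
  expect_equal(mean_coherence(r), 1)
  # half ones / half zeros inside the coi
  half <- r$coherence
  half[, seq(1, ncol(half), by = 2)] <- 0
  sel <- r$coi_mask
  r2 <- r; r2$coherence <- half
  expect_equal(mean_coherence(r2), mean(half[sel]))
  # band restriction picks only matching periods
  inband <- r$periods <= 1
  expected <- mean(r$coherence[inband, , drop = FALSE][r$coi_mask[inband, ]])
  expect_equal(mean_coherence(r, band = c(0, 1)), expected)
  expect_error(mean_coherence(r, band = c(100, 200)), "no cells")
})

test_that("independent noise shows less coherence than a coupled dyad", {
  coupled <- dyad_head_coherence(
    generate_dyad(coupling_spec(kappa = 8, seed = 21))
  )$mean_coherence
  noise_coh <- vapply(1:12, function(s) {
    set.seed(500 + s)
    wavelet_coherence(rnorm(5400), rnorm(5400), fs)$mean_coherence
  }, numeric(1))
  expect_lt(mean(noise_coh), coupled)
  expect_true(all(noise_coh < coupled))
})

test_that("phase classification follows the lead-lag convention", {
  expect_identical(classify_phase(0), "in_phase")
  expect_identical(classify_phase(pi), "anti_phase")
  expect_identical(classify_phase(-pi + 0.01), "anti_phase")
  expect_identical(classify_phase(pi / 2), "first_leads")
  expect_identical(classify_phase(-pi / 2), "second_leads")

  # x = sin(2 pi f t), y lags by pi/2: the first series leads at the tone
  # scale, under the first-minus-second phase convention
  t <- (0:1023) / fs
  f <- 1.5
  x <- sin(2 * pi * f * t) + rnorm(1024, sd = 0.01)
  y <- sin(2 * pi * f * t - pi / 2) + rnorm(1024, sd = 0.01)
  r <- wavelet_coherence(x, y, fs)
  j <- which.min(abs(r$periods - 1 / f))
  labels <- classify_phase(r$phase[j, r$coi_mask[j, ]])
  expect_gt(mean(labels == "first_leads"), 0.9)
})

test_that("head extraction detrends and is offset/drift invariant", {
  dyad <- tiny_dyad(duration_s = 5, seed = 8)
  h <- extract_head_vertical(dyad)
  expect_length(h$child, dyad$n_frames)
  expect_equal(mean(h$child), 0, tolerance = 1e-9)

  shifted <- dyad
  shifted$child$positions[, , 2] <- shifted$child$positions[, , 2] + 50
  h2 <- extract_head_vertical(shifted)
  expect_equal(h2$child, h$child, tolerance = 1e-9)

  drift <- dyad
  drift$child$positions[, 1, 2] <- drift$child$positions[, 1, 2] +
    0.01 * seq_len(dyad$n_frames)
  h3 <- extract_head_vertical(drift)
  expect_equal(h3$child, h$child, tolerance = 1e-6)

  broken <- dyad
  broken$child$missing_mask[, 1] <- TRUE
  expect_error(extract_head_vertical(broken), "child")
})
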