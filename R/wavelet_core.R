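# Morlet continuous wavelet transform, smoothed wavelet coherence, and the
# per-dyad mean-coherence summary.
#
# Conventions follow the widely used Torrence & Compo / Grinsted MATLAB
# toolbox: analytic Morlet with center frequency omega0 = 6, scale grid
# s_j = s0 * 2^(j / voices) with s0 = 2/fs and 12 voices per octave up to a
# maximum Fourier period of a quarter of the record length, transform by
# frequency-domain multiplication after zero-padding to the next power of
# two, and a cone of influence at the wavelet's e-folding time.

OMEGA0 <- 6
# Fourier period of a Morlet wavelet at scale 1
fourier_factor <- function(omega0 = OMEGA0) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

# Plans (filter banks, smoothing kernels, COI, normalization) are cached per
# (n, fs, grid) so repeated transforms of equally sized records are cheap.
.wavelet_cache <- new.env(parent = emptyenv())

wavelet_plan <- function(n, fs, s0 = NULL, voices = 12L, max_period = NULL) {
  s0 <- s0 %||% (2 / fs)
  max_period <- max_period %||% (n / fs / 4)
  key <- sprintf("%d|%g|%g|%d|%g", n, fs, s0, voices, max_period)
  if (!is.null(.wavelet_cache[[key]])) return(.wavelet_cache[[key]])

  dt <- 1 / fs
  ff <- fourier_factor()
  n_scales <- floor(voices * log2(max_period / (s0 * ff))) + 1L
  if (n_scales < 2L) stopf("scale grid is degenerate; record too short")
  scales <- s0 * 2^((seq_len(n_scales) - 1L) / voices)
  periods <- ff * scales

  npad <- next_pow2(n + 1L) # strictly above n so edges never wrap
  omega_k <- 2 * pi * fs * c(0:(npad / 2), -((npad / 2 - 1):1)) / npad
  pos <- omega_k > 0
  # analytic Morlet filter bank, one column per scale (Torrence & Compo norm)
  bank <- matrix(0, npad, n_scales)
  for (j in seq_len(n_scales)) {
    bank[pos, j] <- sqrt(2 * pi * scales[j] / dt) * pi^(-1 / 4) *
      exp(-0.5 * (scales[j] * omega_k[pos] - OMEGA0)^2)
  }

  # cone of influence: maximum reliable Fourier period at each time point
  dist_edge <- pmin(seq_len(n) - 1L, n - seq_len(n)) * dt
  coi <- ff / sqrt(2) * pmax(dist_edge, dt / 2)

  # --- smoothing machinery -------------------------------------------------
  # time: Gaussian with std s/sqrt(2) at scale s, applied in the frequency
  # domain on a padding long enough that circular wrap is negligible;
  # edge truncation is corrected by normalizing with a smoothed unit mask.
  max_std <- scales[n_scales] / sqrt(2) * fs
  npad_s <- next_pow2(n + ceiling(3 * max_std))
  om_s <- 2 * pi * c(0:(npad_s / 2), -((npad_s / 2 - 1):1)) / npad_s
  gauss_gain <- matrix(0, npad_s, n_scales)
  for (j in seq_len(n_scales)) {
    gauss_gain[, j] <- exp(-0.5 * (scales[j] * fs / sqrt(2))^2 * om_s^2)
  }
  ones <- matrix(0, npad_s, n_scales)
  ones[seq_len(n), ] <- 1
  norm_mask <- Re(stats::mvfft(stats::mvfft(ones) * gauss_gain,
                               inverse = TRUE))[seq_len(n), , drop = FALSE] / npad_s
  norm_mask <- t(norm_mask) # scales x times

  # scale: boxcar over 0.6 octaves (0.6 * voices grid steps, fractional
  # end weights), renormalized at the grid edges
  halfwin <- 0.6 * voices / 2
  smat <- matrix(0, n_scales, n_scales)
  for (j in seq_len(n_scales)) {
    for (k in seq_len(n_scales)) {
      overlap <- min(k + 0.5, j + halfwin) - max(k - 0.5, j - halfwin)
      if (overlap > 0) smat[j, k] <- overlap
    }
    smat[j, ] <- smat[j, ] / sum(smat[j, ])
  }

  plan <- list(
    n = n, fs = fs, npad = npad, npad_s = npad_s,
    scales = scales, periods = periods, voices = voices,
    bank = bank, coi = coi, gauss_gain = gauss_gain,
    norm_mask = norm_mask, scale_smoother = smat
  )
  .wavelet_cache[[key]] <- plan
  plan
}

# CWT of a (mean-removed) series under a plan: scales x times complex matrix.
cwt_with_plan <- function(x, plan) {
  xpad <- c(x, numeric(plan$npad - plan$n))
  xhat <- stats::fft(xpad)
  w <- stats::mvfft(plan$bank * xhat, inverse = TRUE) / plan$npad
  t(w[seq_len(plan$n), , drop = FALSE])
}

# Smoothing operator S: Gaussian in time (scale-dependent), boxcar in scale.
# m is a scales x times matrix, real or complex.
smooth_with_plan <- function(m, plan) {
  mp <- matrix(0i, plan$npad_s, length(plan$scales))
  mp[seq_len(plan$n), ] <- t(m)
  sm <- stats::mvfft(stats::mvfft(mp) * plan$gauss_gain,
                     inverse = TRUE)[seq_len(plan$n), , drop = FALSE] / plan$npad_s
  sm <- t(sm) / plan$norm_mask
  if (is.double(m)) sm <- Re(sm)
  plan$scale_smoother %*% sm
}

#' Morlet continuous wavelet transform
#'
#' Transforms a real series with the analytic Morlet wavelet (center
#' frequency 6) by frequency-domain multiplication after zero-padding to the
#' next power of two. The signal mean is removed first, so a constant series
#' transforms to zero. The scale grid runs from `s0` (default two sample
#' intervals) in `voices` steps per octave up to the scale whose equivalent
#' Fourier period is `max_period` (default a quarter of the record length).
#'
#' @param x real numeric series, length at least 64, all finite (gap-fill
#'   first; see [interpolate_missing()]).
#' @param fs sampling rate in Hz.
#' @param s0 smallest scale in seconds.
#' @param voices scales per octave.
#' @param max_period largest equivalent Fourier period in seconds.
#' @return An object of class `wavelet_spectrum`: complex `coefficients`
#'   (scales x times), `scales` and equivalent Fourier `periods` in
#'   seconds, `times` in seconds, the cone-of-influence boundary `coi`
#'   (maximum reliable period per time point, from the wavelet's e-folding
#'   time), and `fs`.
#' @export
morlet_cwt <- function(x, fs, s0 = NULL, voices = 12L, max_period = NULL) {
  x <- as.numeric(x)
  if (length(x) < 64L) stopf("signal too short (%d < 64 samples)", length(x))
  if (!all(is.finite(x))) stopf("signal contains non-finite values; interpolate first")
  plan <- wavelet_plan(length(x), fs, s0, voices, max_period)
  w <- cwt_with_plan(x - mean(x), plan)
  structure(
    list(
      coefficients = w,
      scales = plan$scales,
      periods = plan$periods,
      times = (seq_along(x) - 1L) / fs,
      coi = plan$coi,
      fs = fs
    ),
    class = "wavelet_spectrum"
  )
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  cat(sprintf("<wavelet_spectrum> %d scales x %d times, periods %.3g-%.3g s\n",
              length(x$scales), length(x$times), min(x$periods), max(x$periods)))
  invisible(x)
}

#' Smoothed Morlet wavelet coherence of two series
#'
#' Computes squared wavelet coherence
#' \deqn{R^2 = |S(W_x W_y^* / s)|^2 / (S(|W_x|^2/s)\, S(|W_y|^2/s))}
#' where `S` smooths with a Gaussian in time (standard deviation
#' \eqn{s/\sqrt{2}} at scale s) and a 0.6-octave boxcar in scale. Smoothing
#' is what makes coherence informative: unsmoothed it is identically 1.
#' Coherence lies in `[0, 1]`; the relative phase is the argument of the
#' smoothed cross-spectrum, positive when the first series leads. Both
#' inputs are standardized internally (coherence is invariant to affine
#' transforms of either signal).
#'
#' @param x,y equal-length finite real series (first = child by the package
#'   convention).
#' @param fs sampling rate in Hz.
#' @inheritParams morlet_cwt
#' @return An object of class `coherence_result`: `coherence` and `phase`
#'   maps (scales x times), `periods`, `times`, `coi`, the logical
#'   `coi_mask` (TRUE inside the cone of influence), and the scalar
#'   `mean_coherence` over coi-valid cells.
#' @export
wavelet_coherence <- function(x, y, fs, s0 = NULL, voices = 12L,
                              max_period = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stopf("series lengths differ (%d vs %d)", length(x), length(y))
  }
  if (length(x) < 64L) stopf("signals too short (%d < 64 samples)", length(x))
  if (!all(is.finite(c(x, y)))) stopf("non-finite values in input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("degenerate signal: zero variance")
  }
  plan <- wavelet_plan(length(x), fs, s0, voices, max_period)
  wx <- cwt_with_plan((x - mean(x)) / stats::sd(x), plan)
  wy <- cwt_with_plan((y - mean(y)) / stats::sd(y), plan)

  inv_s <- 1 / plan$scales
  # the smoothing operator is real-linear, so both real power maps ride one
  # complex transform (real part = x power, imaginary part = y power)
  pow <- smooth_with_plan((Mod(wx)^2 + 1i * Mod(wy)^2) * inv_s, plan)
  sxx <- Re(pow)
  syy <- Im(pow)
  sxy <- smooth_with_plan(wx * Conj(wy) * inv_s, plan)

  denom <- sxx * syy
  coh <- Mod(sxy)^2 / denom
  coh[!is.finite(coh)] <- 0 # cells with underflowed power carry no signal
  coh <- pmin(pmax(coh, 0), 1)
  dim(coh) <- dim(denom)

  coi_mask <- outer(plan$periods, plan$coi, FUN = "<")

  res <- structure(
    list(
      coherence = coh,
      phase = Arg(sxy),
      periods = plan$periods,
      scales = plan$scales,
      times = (seq_along(x) - 1L) / fs,
      coi = plan$coi,
      coi_mask = coi_mask,
      fs = fs
    ),
    class = "coherence_result"
  )
  res$mean_coherence <- mean_coherence(res)
  res
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence_result> %d scales x %d times, mean coherence %.3f\n",
              nrow(x$coherence), ncol(x$coherence), x$mean_coherence))
  invisible(x)
}

#' Per-dyad mean coherence
#'
#' Arithmetic mean of the coherence map, by default restricted to cells
#' inside the cone of influence (edge effects inflate coherence), optionally
#' restricted to a band of Fourier periods.
#'
#' @param result a `coherence_result` from [wavelet_coherence()].
#' @param band optional numeric length-2 vector `c(min_period, max_period)`
#'   in seconds.
#' @param use_coi exclude cells outside the cone of influence (default
#'   TRUE). Set FALSE to average the full map.
#' @return Scalar in `[0, 1]`.
#' @export
mean_coherence <- function(result, band = NULL, use_coi = TRUE) {
  stopifnot(inherits(result, "coherence_result"))
  sel <- if (use_coi) result$coi_mask else
    matrix(TRUE, nrow(result$coherence), ncol(result$coherence))
  if (!is.null(band)) {
    inband <- result$periods >= band[1] & result$periods <= band[2]
    sel <- sel & matrix(inband, nrow(sel), ncol(sel))
  }
  if (!any(sel)) stopf("no cells selected (band/COI mask is empty)")
  mean(result$coherence[sel])
}

#' Classify a relative phase into lead--lag categories
#'
#' The phase convention is first-minus-second (child minus mother): phase
#' near 0 is in-phase movement, near \eqn{\pm\pi} anti-phase; otherwise a
#' positive phase means the first series leads and a negative phase means
#' the second leads.
#'
#' @param phase relative phase(s) in radians, in `(-pi, pi]`.
#' @param tolerance half-width in radians of the in-phase and anti-phase
#'   sectors.
#' @return Character vector with levels `in_phase`, `anti_phase`,
#'   `first_leads`, `second_leads`.
#' @export
classify_phase <- function(phase, tolerance = pi / 8) {
  out <- character(length(phase))
  out[abs(phase) <= tolerance] <- "in_phase"
  anti <- pmin(abs(phase - pi), abs(phase + pi)) <= tolerance
  out[anti & out == ""] <- "anti_phase"
  out[out == "" & phase > 0] <- "first_leads"
  out[out == ""] <- "second_leads"
  out
}

# Remove a least-squares straight line from a series.
detrend_linear <- function(v) {
  t <- seq_along(v) - (length(v) + 1) / 2 # centered regressor
  v - mean(v) - t * (sum(t * v) / sum(t * t))
}

#' Extract the detrended vertical head series of both dyad members
#'
#' The head bounce lives on the image y axis (BODY_25 keypoint 0, the
#' nose). The track is gap-filled with [interpolate_missing()] and the
#' vertical nose series is linearly detrended, removing camera or body
#' drift without touching beat-band content.
#'
#' @param dyad a [dyad_recording()].
#' @return List with numeric `child` and `mother` series of length
#'   `n_frames`.
#' @export
extract_head_vertical <- function(dyad) {
  stopifnot(inherits(dyad, "dyad_recording"))
  one <- function(track, who) {
    if (!keypoint_usable(track, KP_NOSE)) {
      stopf("head keypoint unusable for %s (fewer than 2 valid samples)", who)
    }
    track <- interpolate_missing(track)
    detrend_linear(track$positions[, KP_NOSE, 2])
  }
  list(child = one(dyad$child, "child"), mother = one(dyad$mother, "mother"))
}

#' Wavelet head-coherence summary of a dyad
#'
#' Convenience wrapper: extracts both vertical head series with
#' [extract_head_vertical()] and returns their [wavelet_coherence()].
#'
#' @param dyad a [dyad_recording()].
#' @inheritParams mean_coherence
#' @return A `coherence_result`.
#' @export
dyad_head_coherence <- function(dyad) {
  heads <- extract_head_vertical(dyad)
  wavelet_coherence(heads$child, heads$mother, dyad$fps)
}
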