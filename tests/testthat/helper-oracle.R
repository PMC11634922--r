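# Independent wavelet-coherence oracle used only in tests.
#
# Deliberately takes a different computational route from the package: the
# Morlet wavelet is sampled in the TIME domain (truncated at +/- 6 scales)
# and applied by linear (zero-padded, non-circular) convolution, and the
# coherence smoothing uses explicitly constructed truncated kernels with
# edge renormalization. Agreement with the package's analytic
# frequency-domain implementation is therefore a genuine cross-check.

oracle_linear_xcorr <- function(x, g, half) {
  # cross-correlation w[t] = sum_m x[t + m] g[m], m = -half..half
  n <- length(x)
  m_len <- 2L * half + 1L
  nfft <- 2L^ceiling(log2(n + m_len))
  xpad <- c(x, rep(0, nfft - n))
  gpad <- complex(length.out = nfft)
  gpad[1:(half + 1L)] <- g[(half + 1L):m_len]          # m = 0..half
  gpad[(nfft - half + 1L):nfft] <- g[1:half]           # m = -half..-1
  w <- stats::fft(stats::fft(xpad) * Conj(stats::fft(gpad)), inverse = TRUE) / nfft
  w[1:n]
}

oracle_morlet_cwt <- function(x, fs, scales) {
  x <- x - mean(x)
  dt <- 1 / fs
  w <- matrix(0i, length(scales), length(x))
  for (j in seq_along(scales)) {
    s <- scales[j]
    half <- ceiling(6 * s / dt)
    if (s < 8 * dt) {
      # near-Nyquist scales: the naively sampled wavelet aliases; sample a
      # band-limited version via sinc interpolation from a fine grid
      fine <- 16L
      half_f <- half * fine
      tau <- (-half_f:half_f) * (dt / fine)
      eta_f <- tau / s
      psi_f <- pi^(-1 / 4) * exp(1i * 6 * eta_f) * exp(-eta_f^2 / 2)
      m_t <- (-half:half) * dt
      psi <- vapply(m_t, function(t0) {
        arg <- (t0 - tau) / dt
        sum(psi_f * ifelse(arg == 0, 1, sin(pi * arg) / (pi * arg))) / fine
      }, complex(1)) * sqrt(dt / s)
    } else {
      eta <- (-half:half) * dt / s
      psi <- pi^(-1 / 4) * exp(1i * 6 * eta) * exp(-eta^2 / 2) * sqrt(dt / s)
    }
    w[j, ] <- oracle_linear_xcorr(x, psi, half)
  }
  w
}

oracle_smooth <- function(m, fs, scales, voices) {
  n <- ncol(m)
  out <- m
  # time: truncated Gaussian with std s/sqrt(2), renormalized at the edges
  for (j in seq_along(scales)) {
    sd_samp <- scales[j] * fs / sqrt(2)
    half <- max(1L, ceiling(4 * sd_samp))
    g <- exp(-0.5 * ((-half:half) / sd_samp)^2)
    g <- g / sum(g)
    num <- oracle_linear_xcorr(m[j, ], as.complex(g), half)
    den <- Re(oracle_linear_xcorr(rep(1 + 0i, n), as.complex(g), half))
    out[j, ] <- num / den
  }
  # scale: boxcar over 0.6 octaves with fractional end weights
  halfwin <- 0.6 * voices / 2
  res <- out
  for (j in seq_along(scales)) {
    wts <- pmax(0, pmin(seq_along(scales) + 0.5, j + halfwin) -
                     pmax(seq_along(scales) - 0.5, j - halfwin))
    res[j, ] <- colSums(out * (wts / sum(wts)))
  }
  res
}

oracle_coherence <- function(x, y, fs, scales, voices = 12) {
  x <- (x - mean(x)) / stats::sd(x)
  y <- (y - mean(y)) / stats::sd(y)
  wx <- oracle_morlet_cwt(x, fs, scales)
  wy <- oracle_morlet_cwt(y, fs, scales)
  inv_s <- 1 / scales
  sxx <- Re(oracle_smooth(Mod(wx)^2 * inv_s + 0i, fs, scales, voices))
  syy <- Re(oracle_smooth(Mod(wy)^2 * inv_s + 0i, fs, scales, voices))
  sxy <- oracle_smooth(wx * Conj(wy) * inv_s, fs, scales, voices)
  pmin(pmax(Mod(sxy)^2 / (sxx * syy), 0), 1)
}
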