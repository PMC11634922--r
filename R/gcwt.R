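# Generalized cross-wavelet transform (GCWT) of two multivariate keypoint
# series. All N x M pairwise cross-wavelet values at a time-frequency cell
# form a cloud in the complex plane; the cloud is summarized by a bivariate
# normal fit whose major-axis length measures synchrony, whose eccentricity
# measures phase concentration, and whose major-axis angle (mod pi) measures
# the mutual phase. Because the fit is quadratic in the cross values, the
# GCWT does not distinguish in-phase from anti-phase movement.
#
# The second moment is taken about the ORIGIN by default: coherent cross
# values cluster away from the origin along a shared direction, which is
# exactly what makes the major axis large. A mean-centered fit (available
# via `about_origin = FALSE` for sensitivity analysis) would assign zero
# spread to perfectly coherent data.

#' Continuous wavelet transforms of a set of keypoint components
#'
#' Applies [morlet_cwt()] to each selected (keypoint, axis) coordinate
#' series of a track, after gap-filling and linear detrending. All spectra
#' share one scale grid and cone of influence. Components that are unusable
#' (fewer than two valid samples) or constant are dropped with a warning;
#' if every component is dropped, an error is raised.
#'
#' @param track a [keypoint_track()].
#' @param keypoints 1-based keypoint indices to include (default all 25).
#' @param axes subset of `c("x", "y")`.
#' @inheritParams morlet_cwt
#' @return An object of class `cwt_stack`: `spectra` (list of complex
#'   scales x times matrices), `components` (data frame of keypoint and
#'   axis), plus the shared `scales`, `periods`, `times`, `coi`, and `fs`.
#' @export
multivariate_cwt <- function(track, keypoints = seq_len(N_KEYPOINTS),
                             axes = c("x", "y"), s0 = NULL, voices = 12L,
                             max_period = NULL) {
  comp <- track_component_series(track, keypoints, axes)
  plan <- wavelet_plan(track$n_frames, track$fps, s0, voices, max_period)
  spectra <- lapply(comp$series, function(v) cwt_with_plan(v, plan))
  structure(
    list(
      spectra = spectra,
      components = comp$components,
      scales = plan$scales,
      periods = plan$periods,
      times = (seq_len(track$n_frames) - 1L) / track$fps,
      coi = plan$coi,
      fs = track$fps,
      grid = list(s0 = plan$scales[1], voices = voices,
                  max_period = max_period %||% (track$n_frames / track$fps / 4)),
      plan_key = c(plan$n, plan$fs, length(plan$scales))
    ),
    class = "cwt_stack"
  )
}

#' @export
print.cwt_stack <- function(x, ...) {
  cat(sprintf("<cwt_stack> %d components, %d scales x %d times\n",
              length(x$spectra), length(x$scales), length(x$times)))
  invisible(x)
}

# Extract per-(keypoint, axis) series from a track: gap-fill, drop unusable
# or constant components (with a warning), linearly detrend the rest.
track_component_series <- function(track, keypoints, axes) {
  stopifnot(inherits(track, "keypoint_track"))
  axes <- match.arg(axes, c("x", "y"), several.ok = TRUE)
  ax_idx <- c(x = 1L, y = 2L)[axes]
  track <- interpolate_missing(track)
  unusable <- attr(track, "unusable") %||% logical(N_KEYPOINTS)
  series <- list()
  comp <- data.frame(keypoint = integer(0), axis = character(0))
  dropped <- character(0)
  for (k in keypoints) {
    for (a in seq_along(ax_idx)) {
      label <- paste0(BODY25_NAMES[k], "_", axes[a])
      if (unusable[k]) {
        dropped <- c(dropped, label)
        next
      }
      v <- track$positions[, k, ax_idx[a]]
      if (stats::sd(v) == 0) {
        dropped <- c(dropped, label)
        next
      }
      series[[label]] <- detrend_linear(v)
      comp <- rbind(comp, data.frame(keypoint = k, axis = axes[a]))
    }
  }
  if (length(dropped) > 0) {
    warnf("dropping unusable/constant components: %s",
          paste(dropped, collapse = ", "))
  }
  if (length(series) == 0L) stopf("all components unusable")
  list(series = series, components = comp)
}

# Per-scale time-averaged power of a spectrum, used for normalization.
scale_power <- function(w) rowMeans(Mod(w)^2)

# Normalize a spectrum so no single high-amplitude component dominates the
# cross values: divide each scale row by the sqrt of its mean power.
normalize_spectrum <- function(w) w / sqrt(pmax(scale_power(w), .Machine$double.xmin))

#' Pairwise cross-wavelet values at one time-frequency cell
#'
#' The N x M cross-wavelet values `W_xi * Conj(W_yj)` between every
#' component of stack X and every component of stack Y at one (scale, time)
#' cell. With `normalize = TRUE` (default) each value is divided by the
#' square root of the product of the two components' time-averaged power at
#' that scale, so high-amplitude keypoints do not dominate; with
#' `normalize = FALSE` the raw (pixel-scale) cross values are returned.
#'
#' @param stack_x,stack_y `cwt_stack` objects on identical grids.
#' @param scale_idx,time_idx 1-based cell indices.
#' @param normalize divide by component power (see above).
#' @return An N x M complex matrix.
#' @export
pairwise_cross_values <- function(stack_x, stack_y, scale_idx, time_idx,
                                  normalize = TRUE) {
  check_shared_grid(stack_x, stack_y)
  getv <- function(stack) {
    vapply(stack$spectra, function(w) {
      v <- w[scale_idx, time_idx]
      if (normalize) v <- v / sqrt(max(scale_power(w)[scale_idx],
                                       .Machine$double.xmin))
      v
    }, complex(1))
  }
  a <- getv(stack_x)
  b <- getv(stack_y)
  outer(a, b, function(p, q) p * Conj(q))
}

check_shared_grid <- function(stack_x, stack_y) {
  if (!isTRUE(all.equal(stack_x$plan_key, stack_y$plan_key)) ||
      length(stack_x$scales) != length(stack_y$scales)) {
    stopf("stacks are not on a shared scale/time grid")
  }
  invisible(TRUE)
}

#' Bivariate-normal summary of a cloud of complex cross values
#'
#' Fits the second-moment matrix of the values' real and imaginary parts
#' (about the origin by default) and eigendecomposes it. The major-axis
#' length `magnitude` is the square root of the leading eigenvalue;
#' `eccentricity = sqrt(1 - lambda2/lambda1)` (0 for an isotropic cloud, 1
#' for a degenerate line); `axis_angle` is the orientation of the leading
#' eigenvector folded into `[0, pi)`, set to 0 when the eigenvalues tie
#' (isotropic cell, no preferred axis).
#'
#' @param values complex vector or matrix of cross values (non-finite
#'   entries are dropped).
#' @param about_origin moments about the origin (default) or about the
#'   sample mean.
#' @return List with `second_moment` (2 x 2), `eigenvalues` (decreasing),
#'   `magnitude`, `eccentricity`, and `axis_angle`.
#' @export
fit_complex_distribution <- function(values, about_origin = TRUE) {
  z <- as.complex(values)
  z <- z[is.finite(Re(z)) & is.finite(Im(z))]
  if (length(z) == 0L) stopf("no finite cross values to fit")
  if (!about_origin) z <- z - mean(z)
  xy <- cbind(Re(z), Im(z))
  s <- crossprod(xy) / length(z)
  e <- eigen(s, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  if (lam[1] <= 0) {
    angle <- 0
    ecc <- 0
  } else if ((lam[1] - lam[2]) <= 1e-12 * lam[1]) {
    angle <- 0 # isotropic tie-break
    ecc <- sqrt(max(0, 1 - lam[2] / lam[1]))
  } else {
    v <- e$vectors[, 1]
    angle <- atan2(v[2], v[1]) %% pi
    ecc <- sqrt(1 - lam[2] / lam[1])
  }
  list(
    second_moment = s,
    eigenvalues = lam,
    magnitude = sqrt(lam[1]),
    eccentricity = ecc,
    axis_angle = angle
  )
}

# Closed form used for whole-map fitting. For moments about the origin the
# 2x2 second-moment matrix of {Re z, Im z} has trace B = mean |z|^2 and the
# anisotropic part is carried by A = mean z^2:
#   lambda_{1,2} = (B +/- |A|)/2,  axis angle = Arg(A)/2  (mod pi).
# Both A and B factorize over the pairwise products z_ij = a_i Conj(b_j),
# so whole maps are computed from per-stack sums without forming N x M
# clouds. A test cross-checks this against fit_complex_distribution().
gcwt_finish <- function(accx, accy, plan, about_origin = TRUE) {
  n <- accx$n_comp
  m <- accy$n_comp
  a2 <- (accx$s2 / n) * Conj(accy$s2 / m)
  b2 <- (accx$sabs / n) * (accy$sabs / m)
  if (!about_origin) {
    m1 <- (accx$s1 / n) * Conj(accy$s1 / m)
    a2 <- a2 - m1^2
    b2 <- b2 - Mod(m1)^2
  }
  lam1 <- (b2 + Mod(a2)) / 2
  lam2 <- pmax((b2 - Mod(a2)) / 2, 0)
  lam1 <- pmax(lam1, 0)
  magnitude <- sqrt(lam1)
  ecc <- ifelse(lam1 > 0, sqrt(pmax(0, 1 - lam2 / lam1)), 0)
  tie <- (lam1 - lam2) <= 1e-12 * lam1
  angle <- (Arg(a2) / 2) %% pi
  angle[tie | lam1 == 0] <- 0
  dims <- c(length(plan$scales), plan$n)
  dim(magnitude) <- dims; dim(ecc) <- dims; dim(angle) <- dims
  coi_mask <- outer(plan$periods, plan$coi, FUN = "<")
  structure(
    list(
      magnitude = magnitude,
      eccentricity = ecc,
      axis_angle = angle,
      periods = plan$periods,
      scales = plan$scales,
      times = (seq_len(plan$n) - 1L) * (1 / plan$fs),
      coi = plan$coi,
      coi_mask = coi_mask,
      mean_magnitude = mean(magnitude[coi_mask]),
      n_pairs = n * m,
      fs = plan$fs
    ),
    class = "gcwt_result"
  )
}

# Accumulate per-stack sums Sa, Sa^2, S|a|^2 over components, streaming one
# CWT at a time so full multivariate stacks never sit in memory.
gcwt_accumulate_series <- function(series_list, plan, normalize) {
  dims <- c(length(plan$scales), plan$n)
  s1 <- matrix(0i, dims[1], dims[2])
  s2 <- matrix(0i, dims[1], dims[2])
  sabs <- matrix(0, dims[1], dims[2])
  for (v in series_list) {
    w <- cwt_with_plan(v - mean(v), plan)
    if (normalize) w <- normalize_spectrum(w)
    s1 <- s1 + w
    s2 <- s2 + w * w
    sabs <- sabs + Mod(w)^2
  }
  list(s1 = s1, s2 = s2, sabs = sabs, n_comp = length(series_list))
}

gcwt_accumulate_stack <- function(stack, normalize) {
  dims <- c(length(stack$scales), length(stack$times))
  s1 <- matrix(0i, dims[1], dims[2])
  s2 <- matrix(0i, dims[1], dims[2])
  sabs <- matrix(0, dims[1], dims[2])
  for (w in stack$spectra) {
    if (normalize) w <- normalize_spectrum(w)
    s1 <- s1 + w
    s2 <- s2 + w * w
    sabs <- sabs + Mod(w)^2
  }
  list(s1 = s1, s2 = s2, sabs = sabs, n_comp = length(stack$spectra))
}

#' GCWT maps from two component stacks
#'
#' Fits the complex-plane distribution of all N x M pairwise cross-wavelet
#' values at every (scale, time) cell, yielding magnitude, eccentricity, and
#' axis-angle maps, plus the per-dyad `mean_magnitude` averaged over
#' coi-valid cells.
#'
#' @inheritParams pairwise_cross_values
#' @inheritParams fit_complex_distribution
#' @return An object of class `gcwt_result` with `magnitude` (>= 0),
#'   `eccentricity` (in `[0, 1]`), and `axis_angle` (in `[0, pi)`) maps
#'   (scales x times), the shared grid and COI, `mean_magnitude`, and
#'   `n_pairs = N * M`.
#' @export
gcwt_maps <- function(stack_x, stack_y, normalize = TRUE, about_origin = TRUE) {
  check_shared_grid(stack_x, stack_y)
  plan <- wavelet_plan(length(stack_x$times), stack_x$fs,
                       s0 = stack_x$grid$s0, voices = stack_x$grid$voices,
                       max_period = stack_x$grid$max_period)
  accx <- gcwt_accumulate_stack(stack_x, normalize)
  accy <- gcwt_accumulate_stack(stack_y, normalize)
  gcwt_finish(accx, accy, plan, about_origin)
}

#' @export
print.gcwt_result <- function(x, ...) {
  cat(sprintf(
    "<gcwt_result> %d scales x %d times, %d pairs, mean magnitude %.4g\n",
    nrow(x$magnitude), ncol(x$magnitude), x$n_pairs, x$mean_magnitude
  ))
  invisible(x)
}

#' GCWT of a dyad recording
#'
#' Computes the generalized cross-wavelet transform between the child's and
#' the mother's multivariate keypoint series, streaming one component
#' transform at a time (full stacks of 50 spectra are never held in
#' memory). The default component set is all 25 keypoints on both axes; a
#' reduced `c("head", "midhip", "hands")` set is available via
#' `keypoint_set = "reduced"`.
#'
#' @param dyad a [dyad_recording()].
#' @param keypoint_set `"all"` (25 keypoints) or `"reduced"` (nose,
#'   mid-hip, both wrists), or a numeric vector of 1-based keypoint
#'   indices.
#' @param axes subset of `c("x", "y")`.
#' @inheritParams pairwise_cross_values
#' @inheritParams fit_complex_distribution
#' @return A `gcwt_result` (see [gcwt_maps()]).
#' @export
gcwt_dyad <- function(dyad, keypoint_set = "all", axes = c("x", "y"),
                      normalize = TRUE, about_origin = TRUE) {
  stopifnot(inherits(dyad, "dyad_recording"))
  kps <- resolve_keypoint_set(keypoint_set)
  compx <- track_component_series(dyad$child, kps, axes)
  compy <- track_component_series(dyad$mother, kps, axes)
  plan <- wavelet_plan(dyad$n_frames, dyad$fps)
  accx <- gcwt_accumulate_series(compx$series, plan, normalize)
  accy <- gcwt_accumulate_series(compy$series, plan, normalize)
  gcwt_finish(accx, accy, plan, about_origin)
}

resolve_keypoint_set <- function(keypoint_set) {
  if (is.numeric(keypoint_set)) return(as.integer(keypoint_set))
  switch(match.arg(keypoint_set, c("all", "reduced")),
    all = seq_len(N_KEYPOINTS),
    reduced = c(KP_NOSE, KP_MIDHIP, KP_RWRIST, KP_LWRIST)
  )
}

#' Mean GCWT magnitude over the cone of influence
#'
#' @param result a `gcwt_result`.
#' @param band optional period band in seconds, `c(min, max)`.
#' @param use_coi exclude cells outside the cone of influence.
#' @return Scalar mean magnitude (>= 0).
#' @export
mean_magnitude <- function(result, band = NULL, use_coi = TRUE) {
  stopifnot(inherits(result, "gcwt_result"))
  sel <- if (use_coi) result$coi_mask else
    matrix(TRUE, nrow(result$magnitude), ncol(result$magnitude))
  if (!is.null(band)) {
    inband <- result$periods >= band[1] & result$periods <= band[2]
    sel <- sel & matrix(inband, nrow(sel), ncol(sel))
  }
  if (!any(sel)) stopf("no cells selected (band/COI mask is empty)")
  mean(result$magnitude[sel])
}
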