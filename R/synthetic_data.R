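#' Names of the seven interaction-quality subscales
#'
#' Interaction quality is scored on seven subscales (two maternal, two
#' child, three dyadic), each rated from 1 (minimum) to 5 (maximum).
#'
#' @format Character vector of length 7.
#' @export
CIB_SUBSCALES <- c(
  "acknowledging", "elaborating", "child_initiation", "joint_attention",
  "adaptation_regulation", "fluency", "reciprocity"
)

#' Specify a synthetic coupled dyad
#'
#' Parameters of the coupled-oscillator dyad simulator. The two dancers are
#' modeled as stochastic Kuramoto phase oscillators sharing a musical beat
#' frequency and mutually coupled with strength `kappa`:
#' \deqn{d\phi_c = (2\pi f + \kappa \sin(\phi_m - \phi_c))\,dt + \sigma\,dW_c}
#' and symmetrically for the mother. `kappa = 0` gives independently
#' drifting dancers; large `kappa` phase-locks them.
#'
#' Defaults mirror a 3-minute recording at 30 frames per second of a dyad
#' bouncing to music at 120 beats per minute (a 2 Hz beat).
#'
#' @param kappa phase-coupling strength in rad/s; 0 means uncoupled.
#' @param beat_freq beat frequency in Hz.
#' @param duration_s recording duration in seconds.
#' @param fps frame rate in frames per second; `fps * duration_s` must be a
#'   whole number of frames.
#' @param amp_child,amp_mother vertical bounce amplitude in pixels.
#' @param phase_noise_sd phase diffusion intensity in rad per square-root
#'   second; governs how fast uncoupled dancers drift apart.
#' @param obs_noise_sd pixel-level observation noise added to every
#'   keypoint coordinate, emulating pose-estimator jitter.
#' @param missing_rate probability in `[0, 1)` that any single keypoint
#'   sample is dropped (emitted with zero confidence), emulating detector
#'   dropout.
#' @param seed integer seed; fixing it makes the dyad reproducible.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(kappa = 3, beat_freq = 2, duration_s = 180,
                          fps = 30, amp_child = 30, amp_mother = 40,
                          phase_noise_sd = 1.5, obs_noise_sd = 2,
                          missing_rate = 0.02, seed = NULL) {
  if (kappa < 0) stopf("kappa must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must lie in [0, 1)")
  n <- fps * duration_s
  if (abs(n - round(n)) > 1e-9) stopf("fps * duration_s must be integral")
  structure(
    list(
      kappa = kappa, beat_freq = beat_freq, duration_s = duration_s,
      fps = fps, amp_child = amp_child, amp_mother = amp_mother,
      phase_noise_sd = phase_noise_sd, obs_noise_sd = obs_noise_sd,
      missing_rate = missing_rate, seed = seed
    ),
    class = "coupling_spec"
  )
}

# BODY_25 template: keypoint offsets in units of neck-to-mid-hip length,
# x rightward, y downward from the neck. A plausible standing figure.
body25_template <- function() {
  t <- matrix(0, N_KEYPOINTS, 2L)
  rownames(t) <- BODY25_NAMES
  t["nose", ] <- c(0, -0.35)
  t["neck", ] <- c(0, 0)
  t["r_shoulder", ] <- c(-0.35, 0.05); t["l_shoulder", ] <- c(0.35, 0.05)
  t["r_elbow", ] <- c(-0.45, 0.55);    t["l_elbow", ] <- c(0.45, 0.55)
  t["r_wrist", ] <- c(-0.50, 1.00);    t["l_wrist", ] <- c(0.50, 1.00)
  t["mid_hip", ] <- c(0, 1.00)
  t["r_hip", ] <- c(-0.20, 1.00);      t["l_hip", ] <- c(0.20, 1.00)
  t["r_knee", ] <- c(-0.22, 1.75);     t["l_knee", ] <- c(0.22, 1.75)
  t["r_ankle", ] <- c(-0.24, 2.45);    t["l_ankle", ] <- c(0.24, 2.45)
  t["r_eye", ] <- c(-0.08, -0.42);     t["l_eye", ] <- c(0.08, -0.42)
  t["r_ear", ] <- c(-0.15, -0.38);     t["l_ear", ] <- c(0.15, -0.38)
  t["r_big_toe", ] <- c(-0.28, 2.60);  t["l_big_toe", ] <- c(0.28, 2.60)
  t["r_small_toe", ] <- c(-0.34, 2.58); t["l_small_toe", ] <- c(0.34, 2.58)
  t["r_heel", ] <- c(-0.22, 2.52);     t["l_heel", ] <- c(0.22, 2.52)
  t
}

# Limb keypoints that carry their own slow oscillation on top of the bounce.
LIMB_KPS <- c(3:8, 10:15, 20:25) # shoulders..wrists, hips..ankles, feet

#' Simulate one coupled dyad recording
#'
#' Integrates the stochastic Kuramoto phase pair of [coupling_spec()] by
#' Euler--Maruyama at the frame rate, then renders both dancers as BODY_25
#' skeletons. The vertical head movement is an asymmetric bounce,
#' \eqn{y(t) = y_0 - A\,(1 + 0.5\sin\phi)\sin\phi + \epsilon}, so an upward
#' bounce decreases the image y coordinate and the waveform carries a
#' second harmonic, as real bouncing does. All 25 keypoints ride a rigid
#' skeleton template translated by the bounce; limb keypoints additionally
#' carry independent low-frequency (0.2--0.6 Hz) oscillations unrelated to
#' the coupling. Keypoint samples are dropped i.i.d. at `missing_rate`
#' (position and confidence zeroed); dropped samples do not perturb the
#' retained ones, which are bit-identical to a dropout-free run under the
#' same seed.
#'
#' The latent phase series are attached as attribute `"phases"` (list with
#' `child` and `mother`) for ground-truth checks.
#'
#' @param spec a [coupling_spec()].
#' @param dyad_id identifier for the recording.
#' @return A [dyad_recording()].
#' @export
generate_dyad <- function(spec, dyad_id = "synthetic_dyad") {
  stopifnot(inherits(spec, "coupling_spec"))
  with_seed(spec$seed, generate_dyad_impl(spec, dyad_id))
}

generate_dyad_impl <- function(spec, dyad_id) {
  n <- as.integer(round(spec$fps * spec$duration_s))
  dt <- 1 / spec$fps
  omega <- 2 * pi * spec$beat_freq

  # --- latent phases: Euler-Maruyama at the frame rate
  phi <- matrix(0, n, 2L)
  phi[1, ] <- stats::runif(2, 0, 2 * pi)
  noise <- matrix(stats::rnorm(2L * (n - 1L), sd = spec$phase_noise_sd * sqrt(dt)),
                  n - 1L, 2L)
  for (i in seq_len(n - 1L)) {
    d12 <- sin(phi[i, 2] - phi[i, 1])
    phi[i + 1L, 1] <- phi[i, 1] + (omega + spec$kappa * d12) * dt + noise[i, 1]
    phi[i + 1L, 2] <- phi[i, 2] + (omega - spec$kappa * d12) * dt + noise[i, 2]
  }

  tmpl <- body25_template()
  render_person <- function(phase, amp, stature_px, base_x, base_y) {
    bounce <- -amp * (1 + 0.5 * sin(phase)) * sin(phase) # y up = negative
    pos <- array(0, c(n, N_KEYPOINTS, 2L))
    for (k in seq_len(N_KEYPOINTS)) {
      pos[, k, 1] <- base_x + stature_px * tmpl[k, 1]
      pos[, k, 2] <- base_y + stature_px * tmpl[k, 2] + bounce
    }
    # independent slow limb oscillators, unrelated to the coupling
    for (k in LIMB_KPS) {
      f <- stats::runif(1, 0.2, 0.6)
      ph0 <- stats::runif(2, 0, 2 * pi)
      a <- 0.08 * stature_px
      tt <- (seq_len(n) - 1L) * dt
      pos[, k, 1] <- pos[, k, 1] + a * sin(2 * pi * f * tt + ph0[1])
      pos[, k, 2] <- pos[, k, 2] + a * sin(2 * pi * f * tt + ph0[2])
    }
    pos + array(stats::rnorm(n * N_KEYPOINTS * 2L, sd = spec$obs_noise_sd),
                c(n, N_KEYPOINTS, 2L))
  }

  # child shorter and to the left of the mother
  pos_c <- render_person(phi[, 1], spec$amp_child, 110, 220, 300)
  pos_m <- render_person(phi[, 2], spec$amp_mother, 160, 460, 260)

  conf_c <- matrix(0.9, n, N_KEYPOINTS)
  conf_m <- matrix(0.9, n, N_KEYPOINTS)

  # dropout last in the RNG stream: retained samples are unaffected by it
  if (spec$missing_rate > 0) {
    drop_c <- matrix(stats::runif(n * N_KEYPOINTS) < spec$missing_rate, n, N_KEYPOINTS)
    drop_m <- matrix(stats::runif(n * N_KEYPOINTS) < spec$missing_rate, n, N_KEYPOINTS)
    for (ax in 1:2) {
      pos_c[, , ax][drop_c] <- 0
      pos_m[, , ax][drop_m] <- 0
    }
    conf_c[drop_c] <- 0
    conf_m[drop_m] <- 0
  }

  dyad <- dyad_recording(
    child = keypoint_track(pos_c, conf_c, spec$fps),
    mother = keypoint_track(pos_m, conf_m, spec$fps),
    dyad_id = dyad_id
  )
  attr(dyad, "phases") <- list(child = phi[, 1], mother = phi[, 2])
  dyad
}

#' Default link from coupling strength to expected quality score
#'
#' Monotone map from the simulator's coupling strength `kappa` to an
#' expected subscale score: affine in `log(1 + kappa)`, reaching 1.5 at
#' `kappa = 0` and 4.8 at `kappa = kappa_max`, so expected scores stay away
#' from the 1--5 clipping limits.
#'
#' @param kappa coupling strength(s).
#' @param kappa_max coupling mapped to the top expected score.
#' @return Expected score(s) in `[1.5, 4.8]`.
#' @export
default_score_link <- function(kappa, kappa_max = 8) {
  1.5 + (4.8 - 1.5) * log1p(kappa) / log1p(kappa_max)
}

#' Simulate a cohort of dyads with linked quality scores
#'
#' Draws a coupling strength for each dyad from `kappa_grid`, simulates the
#' recording with [generate_dyad()], and assigns seven interaction-quality
#' subscale scores as `clip(score_link(kappa) + noise, 1, 5)`. With
#' `noise_sd = 0` and a strictly increasing `score_link`, every subscale is
#' a monotone function of the true coupling.
#'
#' @param n_dyads number of dyads (at least 3).
#' @param kappa_grid coupling strengths sampled (uniformly, with
#'   replacement) across dyads.
#' @param score_link monotone function mapping kappa to an expected score.
#' @param noise_sd standard deviation of the score noise, in score units.
#' @param seed integer seed for the whole cohort.
#' @param base_spec a [coupling_spec()] whose non-coupling parameters
#'   (duration, fps, amplitudes, noise, dropout) apply to every dyad.
#' @return An object of class `synthetic_cohort`: a list with `dyads` (list
#'   of [dyad_recording()]), `true_coupling` (numeric), and
#'   `quality_scores` (data frame with `dyad_id` and the seven
#'   [CIB_SUBSCALES] columns).
#' @export
generate_cohort <- function(n_dyads, kappa_grid = c(0, 1, 3, 8),
                            score_link = default_score_link,
                            noise_sd = 0.5, seed = NULL,
                            base_spec = coupling_spec()) {
  if (n_dyads < 3L) stopf("n_dyads must be >= 3")
  if (length(kappa_grid) == 0L) stopf("kappa_grid must be non-empty")
  with_seed(seed, {
    kappas <- sample(kappa_grid, n_dyads, replace = TRUE)
    dyad_seeds <- sample.int(.Machine$integer.max - 1L, n_dyads)
    scores <- matrix(0, n_dyads, length(CIB_SUBSCALES))
    for (j in seq_along(CIB_SUBSCALES)) {
      scores[, j] <- pmin(pmax(score_link(kappas) +
                                 stats::rnorm(n_dyads, sd = noise_sd), 1), 5)
    }
    dyads <- vector("list", n_dyads)
    for (i in seq_len(n_dyads)) {
      sp <- base_spec
      sp$kappa <- kappas[i]
      sp$seed <- dyad_seeds[i]
      dyads[[i]] <- generate_dyad(sp, dyad_id = sprintf("dyad_%03d", i))
    }
    qs <- data.frame(dyad_id = vapply(dyads, function(d) d$dyad_id, character(1)),
                     scores)
    names(qs) <- c("dyad_id", CIB_SUBSCALES)
    structure(
      list(dyads = dyads, true_coupling = kappas, quality_scores = qs),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d dyads, kappa in [%g, %g]\n",
              length(x$dyads), min(x$true_coupling), max(x$true_coupling)))
  invisible(x)
}
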