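# dyadsync

Quantifies **interpersonal movement synchrony** — how tightly two
interacting people move together — from 2D pose-estimation keypoint time
series, such as a mother and her preschool child dancing to music. Intended
for researchers in developmental psychology, movement science, and social
signal processing who record dyadic interactions on plain video, run a pose
estimator (OpenPose-style BODY_25 output), and want validated per-dyad
synchrony summaries they can relate to behavioral measures.

## What it computes

Two complementary synchrony measures over the time–frequency plane:

* **Cross-wavelet coherence (CWT)** of the partners' vertical head movement.
  Using the analytic Morlet wavelet (ω₀ = 6, Grinsted/Torrence–Compo
  conventions), the smoothed squared coherence

  R²(s,t) = |S(WₓW*_y/s)|² / ( S(|Wₓ|²/s) · S(|W_y|²/s) ) ∈ [0, 1]

  is averaged inside the cone of influence to one scalar per dyad. Relative
  phase gives lead–lag labels (positive phase = the child leads, by the
  first-minus-second convention).

* **Generalized cross-wavelet transform (GCWT)** over multivariate keypoint
  sets: all N×M pairwise cross-wavelet values at each cell form a cloud in
  the complex plane; the square root of the leading eigenvalue of its
  second-moment matrix (about the origin) is the synchrony magnitude,
  with eccentricity and major-axis angle as phase-structure maps. The fit is
  quadratic, so in-phase and anti-phase movement are deliberately
  indistinguishable.

Around these sit: OpenPose-dialect JSON/CSV readers with greedy
nearest-centroid identity tracking and stature-based mother/child labeling,
linear gap interpolation, **pseudo-dyad surrogate validation** (derangement
re-pairing plus a paired t-test against chance-level synchrony), Spearman
correlations with seven 1–5 interaction-quality subscales, and a
**coupled-oscillator simulator** (stochastic Kuramoto pair driving bouncing
BODY_25 skeletons) providing ground-truth coupling for every stage.

## Worked example

```r
library(dyadsync)

# simulate a small cohort of coupled dyads (30 s recordings to keep it quick)
cohort <- generate_cohort(
  n_dyads = 6, kappa_grid = c(0, 3, 8), noise_sd = 0.3, seed = 11,
  base_spec = coupling_spec(duration_s = 30)
)

# per-dyad mean head coherence
coh <- sapply(cohort$dyads, function(d) dyad_head_coherence(d)$mean_coherence)
round(data.frame(dyad = seq_along(coh), kappa = cohort$true_coupling,
                 mean_coherence = coh), 3)
#>   dyad kappa mean_coherence
#> 1    1     3          0.500
#> 2    2     3          0.492
#> 3    3     0          0.459
#> 4    4     0          0.445
#> 5    5     0          0.412
#> 6    6     3          0.504

# real vs pseudo-dyad validation
surrogate_validation(cohort$dyads, measure = "cwt", seed = 99)
#> <surrogate_comparison> n = 6, mean real 0.4686 vs pseudo 0.4414, t(5) = 1.793, p = 0.133

# coherence vs interaction-quality subscales
head(spearman_with_quality(coh, cohort$quality_scores), 3)
#>   measure         subscale       rho          p n
#> 1 summary    acknowledging 0.7714286 0.10277778 6
#> 2 summary      elaborating 0.7714286 0.10277778 6
#> 3 summary child_initiation 0.9428571 0.01666667 6
```

Coherence rises with the true coupling κ (uncoupled dyads sit near the
chance floor set by the shared 2 Hz beat), real pairs exceed re-paired
pseudo-dyads (a 6-dyad toy run is underpowered — at realistic cohort sizes
the separation is decisive), and rank correlations with the quality
subscales recover the simulated link. For real data, start instead from
`load_openpose_frames()` / `read_dyad_csv()`, or drive everything from the
command line via `inst/cli/dyadsync` (`convert | synth | analyze | validate
| correlate`, YAML config, tidy CSV outputs).

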