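Package: dyadsync
Title: Interpersonal Movement Synchrony from Pose Keypoints via Wavelet
    Coherence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies interpersonal movement synchrony in dyadic
    interactions (for example a mother and child dancing together) from 2D
    pose-estimation keypoint time series. Reads OpenPose-style BODY_25
    per-frame JSON or flattened CSV, resolves person identities across
    frames, and gap-fills keypoint trajectories. Computes Morlet
    cross-wavelet coherence of vertical head movement and a generalized
    cross-wavelet transform (GCWT) over multiple keypoints, validates
    observed synchrony against shuffled pseudo-dyads with a paired t-test,
    and correlates per-dyad synchrony summaries with interaction-quality
    subscale scores. A coupled-oscillator simulator generates synthetic
    dyad recordings with known phase-coupling strength so the whole
    pipeline can be exercised and validated without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
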