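Package: kneemocap
Title: Knee Joint Kinematics from Optical Motion Capture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A batch-oriented toolkit for computing tibiofemoral (knee)
    kinematics from optical motion-capture marker trajectories. Provides
    repair of occluded and spiking marker samples (rigid-body completion of
    single-marker dropouts, natural cubic-spline interpolation of short
    gaps, a discard rule for unrecoverable frames), stylus-probe calibration
    of bony landmarks as cluster-local virtual markers, least-squares rigid
    registration (Kabsch/SVD), construction of anatomical femur and tibia
    coordinate systems from seven landmarks, and extraction of
    flexion/extension, adduction/abduction and internal/external rotation
    via an X-Y-Z Euler decomposition. A synthetic capture-session generator
    with prescribed ground-truth joint angles makes every pipeline stage
    verifiable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    broom,
    yaml,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
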