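Package: wearval
Title: Agreement Validation Pipeline for Paired Wearable EMG and IMU Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for method-comparison studies of wearable biosignal devices
    against laboratory gold standards. Implements a surface-EMG amplitude chain
    (offset correction, full-wave rectification, moving-average envelope,
    fixed-length cycle resampling with mirror padding, per-cycle 0-1
    normalization, RMS of the mean cycle) and a shoulder-kinematics chain
    (Euler/rotation-matrix conversion, orthogonal-Procrustes rigid alignment of
    an IMU to an optical reference on SO(3), referencing to an initial pose,
    angle unwrapping, zero-phase Butterworth smoothing, per-cycle range of
    motion), together with the full agreement battery: Bland-Altman bias and
    95% limits of agreement, Pearson correlation, ICC(2,1) two-way
    random-effects absolute-agreement intraclass correlation, and coefficients
    of variation across task repetitions. A seeded synthetic paired-sensor
    generator with known ground truth (shared latent muscle activation observed
    by two EMG systems; a segment-orientation trajectory observed by an IMU
    through a fixed mounting misalignment and by a camera directly) makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
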