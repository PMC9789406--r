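Package: polygait
Title: Kinematic, Electromyographic and Circular-Statistical Analysis of
    Amphibious Fish Locomotion Across Water Depths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for quantifying how an elongate amphibious
    fish shifts from swimming to walking as water depth falls. Provides body
    midline extraction from binarized top-view masks and arc-length
    resampling, trial-level body kinematics (locomotion speed, curvature
    coefficient, swing distance, body-wave frequency, nose elevation),
    pectoral-fin stroke segmentation with fin angle, frequency, range of
    motion and left-fin phase, EMG conditioning and burst metrics (duty
    factor, rectified integrated area normalized to a per-electrode
    theoretical maximum, onset/offset phase, contralateral co-activation),
    a circular-statistics decision procedure (Hermans-Rasson, von Mises
    goodness of fit, Rayleigh, Watson-Williams, angular-dispersion
    comparisons), and a synthetic-trial generator with recorded ground truth
    so every stage is verifiable without raw video or EMG recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    zoo,
    jsonlite,
    yaml,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
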