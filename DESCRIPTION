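Package: videobp
Title: Non-Contact Blood Pressure Estimation from Face-and-Hand Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates systolic and diastolic blood pressure from a single
    RGB video showing a subject's face and open palm. Two remote
    photoplethysmography (rPPG) signals are extracted from forehead and palm
    regions of interest with chrominance-based (CHROM) projection and
    zero-phase Butterworth band-pass filtering; systolic and diastolic pulse
    transit times are measured by peak-peak and valley-valley event pairing;
    subject-specific vessel parameters (arterial diameter, wall thickness,
    vessel length difference) are derived from demographics and a full-length
    standing image via anthropometric pixel-to-cm scaling; and blood pressure
    is obtained by inverting a modified Moens-Korteweg pulse-wave-velocity
    relation. Includes seeded synthetic generators (pulse pairs, pulsating
    skin videos, pose fixtures, demographic cohorts) and agreement statistics
    (MAE, intraclass correlation, Bland-Altman limits, two-sample
    Kolmogorov-Smirnov tests) for evaluating estimator variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
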