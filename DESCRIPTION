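Package: neuract
Title: Functional Activity Readouts for Neuronal Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies functional activity of neuronal cultures from three
    complementary readouts: calcium-fluorescence time-lapse imaging (ROI
    detection, background subtraction, moving-average smoothing, dF/F0
    normalization with a lowest-fraction baseline, linear detrending and
    prominence-based transient detection), extracellular microelectrode-array
    recordings (spike detection with a stationary wavelet transform combined
    with the Teager energy operator, electrode quality control and firing-rate
    summaries), and a multiparametric pharmacological fingerprint (serial
    glutamatergic-stimulation percent-change features, mean-padding imputation,
    standardization, principal component analysis and a convex-hull overlap
    percentage between groups). Ships seeded synthetic-data generators for all
    three modalities so every stage can be validated against ground truth, plus
    the nonparametric tests and delta-delta-Ct quantification used in such
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    grDevices,
    tiff,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    readr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
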