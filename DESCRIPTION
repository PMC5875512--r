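Package: cbctdose
Title: Kilovoltage Cone-Beam CT Dosimetry with Point Doses and Dose Line Integrals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for characterising the radiation dose delivered by
    linac-mounted kilovoltage cone-beam CT (CBCT) imaging systems using
    standard radiotherapy dosimetry equipment. Implements TG-61 absolute
    point dose to water from ion-chamber readings (including temperature,
    pressure, polarity and recombination corrections, air-kerma calibration
    factor interpolation by half-value layer), processing of linear
    diode-array beam profiles (per-detector calibration, tube-output
    correction via a reference diode, stitching of shifted scans,
    central-axis normalisation), integration of absolute longitudinal dose
    profiles into dose line integrals (DLI), the radially weighted DLP_CBCT
    metric, and per-100-mAs scaling of summary dose tables to predict doses
    for arbitrary CBCT protocols and treatment courses. A synthetic
    instrument simulator with a closed-form beam model provides ground truth
    for end-to-end validation without measurement hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
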