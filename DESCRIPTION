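Package: radbio
Title: Radiobiological Comparison of SBRT Dose Schedules from Dose-Volume Histograms
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing stereotactic body radiotherapy (SBRT)
    fractionation schedules on radiobiological grounds. Reads, resamples and
    transforms cumulative and differential dose-volume histograms (DVHs),
    converts dose to the equivalent dose in 2 Gy fractions (EQD2) under the
    linear-quadratic model, and evaluates tumor control probability (TCP)
    with five published model families (logistic dose-response, covariate
    logistic, Poisson Webb-Nahum with population-averaged radiosensitivity,
    SF2-based equivalent uniform dose, and an SBRT-fitted logistic), lung
    normal tissue complication probability (NTCP) with EUD-based
    Lyman-Kutcher-Burman and logistic mean-dose models, and chest-wall
    toxicity via a dose-weighted modified EUD over the hottest subvolume.
    Includes a seeded synthetic DVH cohort generator and an end-to-end
    two-schedule comparison pipeline with paired statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
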