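Package: phesensor
Title: Hybrid PLSR-UKF Soft Sensor for Fed-Batch L-Phenylalanine Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: State estimation for fed-batch L-phenylalanine fermentations
    from routine online signals. A coarse-grained proteome-allocation
    process model provides the state-transition function of a constrained
    unscented Kalman filter, while phase-wise partial least-squares
    regression (SIMPLS) maps eight online channels (stirrer, aeration,
    pO2, temperature, pH, off-gas CO2, feed mass flow, cumulative base)
    to concentration measurements of biomass, glycerol, L-phenylalanine,
    acetate and L-tyrosine. Includes measurement-noise construction from
    regression errors, process-noise calibration by pattern search, and a
    synthetic three-phase process generator so the full pipeline can be
    exercised end to end without plant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
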