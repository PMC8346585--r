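Package: diazosip
Title: Stable-Isotope-Probing Rate Calculations for Stratified Water Columns
Version: 0.1.0
Authors@R: person("diazosip", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Quantitative workflow for dual stable-isotope-probing (15N2 and
    13C-DIC) studies of nitrogen and carbon fixation in stratified water
    columns such as meromictic lake chemoclines. Provides CTD upcast/downcast
    depth alignment by physicochemical profile matching, bulk fixation rates
    from endpoint isotope incorporation with detection-limit censoring,
    steady-state Fick's-law diffusive ammonium flux and nitrogen-source
    budgets, nanoSIMS single-cell rate calculation with Poisson counting-error
    quality control, scaling of single-cell activity to population rates with
    propagated errors, and a seeded synthetic-data generator with known ground
    truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
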