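Package: teleconsult
Title: Economic Evaluation and Discrete-Event Simulation of Hospital
    Teleconsultations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Combined economic and organisational evaluation of hospital
    teleconsultations against in-person specialist consultations. Provides a
    per-patient cost model (consultation fees, medical and non-medical
    transport tariffs, amortised telehealth equipment), propensity-score
    matched incremental-cost analysis with non-parametric bootstrap
    confidence intervals and tornado deterministic sensitivity analysis, a
    discrete-event simulation of three consultation pathways (physical
    consultation, video teleconsultation, telehealth station) with daily
    station capacity and nurse sick-leave, scenario sweeps over pathway
    probabilities, average-cost curves and break-even amortisation levels,
    and a synthetic patient-population generator with covariate-driven
    selection into the teleconsultation group for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
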