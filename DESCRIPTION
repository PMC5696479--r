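Package: ameispl
Title: Equivalent Sound Pressure Output of Active Middle Ear Implants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the output of active-middle-ear-implant actuators as
    equivalent free-field sound pressure level from laser-Doppler stapes
    vibration, from the intracochlear pressure difference between scala
    vestibuli and scala tympani measured in cadaveric temporal bones, and from
    paired clinical bone-conduction and direct thresholds.  Includes complex
    spectrum handling with adjacent-bin signal-to-noise estimation and coherent
    averaging, middle-ear transfer-function acceptance gating, nonparametric
    cohort comparisons, and a synthetic temporal-bone and clinical-cohort
    generator with known ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
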