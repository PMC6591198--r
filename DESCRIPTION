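Package: qlqscreen
Title: Item Screening for Quality-of-Life Questionnaire Module Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Phase-III item analysis for patient-reported outcome instrument
    development in the EORTC tradition, built around the field test of the
    QLQ-AA/PNH module for aplastic anaemia and paroxysmal nocturnal
    haemoglobinuria. Computes per-item descriptive statistics for 1-4 Likert
    items with missing responses, evaluates an eight-criterion retention
    screen with a formal keep rule, screens debriefing interviews for issues
    missing from the questionnaire, estimates Cronbach's alpha for
    hypothesised scales, and reconciles the screening verdicts with recorded
    expert-panel decisions. A latent-factor cohort simulator generates
    ordinal response matrices and debriefing records with known structure so
    the whole pipeline can be exercised and checked without patient data.
    The published per-item reference table of the QLQ-AA/PNH field test
    (48 patients, 69 items) is packaged as a plain-text fixture.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
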