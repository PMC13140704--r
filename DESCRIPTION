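Package: spo2delta
Title: Directional Parenclitic Deviation Analysis of Oxygen Saturation Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying the irregularity of 1 Hz pulse-oximetry
    (SpO2) recordings with sample entropy and multiscale entropy, normalising
    entropy against a healthy hypoxia-response reference regression via signed
    (directional) parenclitic deviation, and evaluating that deviation as a
    prognostic marker with Cox proportional-hazards models, ROC discrimination
    and Bland-Altman agreement analysis. Includes a synthetic-data subsystem
    that emulates graded-hypoxia reference populations and ICU-style patient
    cohorts with planted deviation structure, so the full pipeline can be
    exercised and tested without access to restricted waveform databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
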