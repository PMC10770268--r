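Package: surgflow
Title: Execution, Control and Situation Recognition for Surgical Process Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parse, validate, execute and control surgical process models
    expressed in a restricted subset of BPMN 2.0 and CMMN 1.1, including
    hybrid combinations of both notations. A token engine (BPMN) and a
    plan-item lifecycle engine (CMMN) drive the modeled intervention, while a
    recognition layer fuses simulated sensor observations with model-derived
    process knowledge (next possible steps, completable activity instances,
    remaining surgery duration) to track and control the intraoperative
    situation. Ships synthetic model families for a robot-assisted minimally
    invasive esophagectomy and a cochlea implantation, deterministic sensor
    stream simulation with controlled distortions, and a brute-force trace
    oracle for verifying engine semantics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
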