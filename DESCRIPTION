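Package: textpheno
Title: Digital Phenotyping of Therapy Message Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines timestamped patient-therapist message transcripts for
    signals of a population-level stressor. Provides seed-keyword screening
    of pandemic mentions with monthly incidence tables and a daily
    mention-proportion signal, GAD-7/PHQ-9 intake scoring with rolling
    averages and bootstrap estimation of pre/post shifts in mean intake
    severity, TF-IDF term-trajectory correlation screening with
    Benjamini-Hochberg false discovery rate control, lexicon-based topic
    categorization of the selected vocabulary, and mapping of selected terms
    onto ICD-10 symptom descriptors. A synthetic-corpus generator with
    planted ground truth supports end-to-end recovery testing of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
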