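Package: proxqap
Title: Face-to-Face Proximity Networks and Multi-Group Dyadic Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and analysis of face-to-face interaction networks
    recorded with wearable proximity sensors (RFID badges), together with
    survey-based actor attributes. Provides contact-event merging and
    aggregation into weighted interaction matrices, per-hour normalization,
    decomposition of interaction time into dyadic and group components,
    construction of dyadic covariate matrices (means, similarities, category
    dummies, friendship ties), multi-group MRQAP regression with
    Y-permutation inference, node-level permutation correlation tests,
    CES-D and Big Five scoring with Cronbach's alpha, model-implied
    selection tables, and a synthetic-data generator that emulates a
    two-cohort weekend field study so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
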