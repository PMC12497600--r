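Package: pttsleep
Title: Pulse Transit Time and Oximetry Analysis for Paediatric Sleep-Disordered Breathing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-channel sleep studies in children with
    suspected sleep-disordered breathing. Computes beat-wise pulse transit
    time (PTT) from ECG R-peaks and the photoplethysmograph, the smoothed
    PTT2 channel and PTT arousal index, the 1-Hz respiratory PTT channel and
    its respiratory swing (PTTrs), oxygen desaturation indices (ODI3/ODI4)
    and a four-level oximetry severity score, rule-based diagnostic
    categorisation, and the accompanying statistical layer (multinomial and
    logistic regression with iterated variable selection, decision-tree
    cross-check, ROC/AUC and a full confusion-matrix metric suite). A
    synthetic overnight-recording generator reproduces the statistical
    structure the analysis assumes, so the whole pipeline can be exercised
    and validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    caret,
    pROC,
    e1071,
    knitr
Config/testthat/edition: 3
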