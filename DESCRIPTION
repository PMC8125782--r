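Package: dpnet
Title: Drug Co-Prescription Networks from Patient-Level ATC Records
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds drug prescription networks (DPNs) from patient-level
    prescription records coded with the Anatomical Therapeutic Chemical (ATC)
    classification, at all five ATC levels. Nodes carry the number of patients
    prescribed each drug (Pi) and edges the number of patients co-prescribed
    each drug pair (Cij). Provides the standard structural metric panel
    (density, degree, betweenness, closeness, degree assortativity,
    giant-component criteria), phi binary-correlation edge thresholding with
    logistic retention-curve fits and the phi-max gap statistic, and
    demographically stratified layer comparison via Euclidean distance
    matrices with ward.D2 clustering. Includes a synthetic prescription-record
    generator emulating the demographic and popularity structure of
    administrative dispensation data, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    minpack.lm,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
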