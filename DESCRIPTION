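Package: eelsonar
Title: Detection, Tracking and Counting of Anguilliform Fish in Acoustic-Camera Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic detection, identification and counting of anguilliform
    fish (eels) in imaging-sonar ("acoustic camera") video. Frames of interest
    are screened with singular-value-ratio echograms, moving objects are
    segmented with an adaptive Gaussian-mixture background model, candidate
    shapes are measured by ellipse fitting, skeleton reconstruction and k-means
    body sectioning, candidates are tracked across frames with neighborhood and
    orientation gates, and tracks are classified by rule sets tuned per eel
    length class. Includes a ground-truthed synthetic sonar-scene generator,
    detection-evaluation statistics (recall, precision, F1, identification
    precision, stratified metrics, bootstrap count regression) and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
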