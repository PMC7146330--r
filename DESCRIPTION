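Package: jellyquant
Title: Detection Post-Processing, Evaluation and Windowed Quantification
    for Video-Based Jellyfish Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detector-agnostic toolkit for video-based monitoring of
    jellyfish (and other slow-moving animals) from per-frame object
    detections. Provides non-maxima suppression and confidence filtering,
    PASCAL-VOC-style evaluation (IoU matching, precision/recall/F1,
    per-class AP and mAP, optimal-confidence-threshold sweeps), a
    real-time windowed-mode quantification algorithm that reduces noisy
    per-frame species counts to stable resulting information points with
    a Similarity score against manual counts, readers and writers for
    LabelImg PASCAL VOC XML annotations, JSON-lines detection streams and
    count-timeline CSVs, and a seeded simulator of scenes and imperfect
    detector output for end-to-end testing without a trained network.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    xml2,
    jsonlite,
    yaml,
    optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cli.R'
    'detections-io.R'
    'evaluation.R'
    'geometry.R'
    'jellyquant-package.R'
    'nms.R'
    'quantification.R'
    'synthetic.R'
    'timeline-io.R'
    'voc-io.R'
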