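Package: exergauge
Title: Engagement Analytics for Camera-Tracked Home Exercise Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing engagement with camera-tracked,
    gamified home exercise programs. Detects attempted and high-quality
    exercise repetitions from 19-joint 3D skeleton streams using
    configurable per-exercise movement-acceptability rules, converts
    detections into adherence, fidelity and star-rating outcomes,
    generates and analyses restricted-randomization alternating-treatments
    single-case designs (percentage of non-overlapping data, single-case
    randomization tests, Fisher-Pitman and Wilcoxon-Pratt permutation
    tests, JZS Bayes factors), and quantifies manual-versus-system and
    inter-rater agreement (weighted mean relative error, ICC(2,1),
    Bland-Altman limits of agreement). Includes a synthetic-data
    generator for skeleton streams, session series and rater count
    tables so the full pipeline can be exercised without participant
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
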