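Package: ascvs
Title: Automated System-Cognitive Analysis for Virtual Screening of
    Bioassay Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Information-theoretic classification of bioassay activity from
    coded molecular-descriptor tables, in the automated system-cognitive
    (ASC) tradition. Descriptor columns are formalized into scales with
    discrete gradations, objects are coded into a binary incidence matrix,
    and nine knowledge models (two raw-probability models and seven
    information-theoretic criteria built on the Kharkevich measure, the
    chi-square deviation from independence, and the ROI criterion) are
    formed from the gradation-by-class frequency matrix. Objects are
    recognized by signed percent similarity to class profiles; models are
    compared by the crisp Van Rijsbergen F-measure and a fuzzy
    similarity-weighted L1 analogue; low-similarity training artifacts are
    removed and models retrained. Interpretive outputs include information
    portraits, feature-significance Pareto curves, and signed
    gradation-to-class contribution graphs. A synthetic bioassay generator
    reproduces the statistical shape of highly imbalanced screening sets
    (about 1.4 percent actives) with planted ground truth for parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Matrix, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'analysis_outputs.R'
    'artifact_removal.R'
    'data_io.R'
    'model_formation.R'
    'recognition.R'
    'reliability.R'
    'show-methods.R'
    'synthetic_data.R'
    'utils.R'
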