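Package: speechmark
Title: Interpretable Speech and Language Markers for Dementia Detection
Version: 0.1.0
Authors@R: person("Speechmark", "Developers", role = c("aut", "cre"),
    email = "maintainers@speechmark.dev")
Description: Extraction of interpretable speech-timing and lexico-semantic
    markers from picture-description recordings and time-aligned transcripts,
    for the detection of Alzheimer's dementia and the prediction of global
    cognition (MMSE). Implements energy-based voice activity detection,
    pause/timing feature extraction with six-moment summaries, word-class
    ratios, WordNet-style hypernym-depth semantic granularity,
    embedding-distance semantic variability, a decision-tree-guided sparse
    multilayer perceptron classifier/regressor with connection-count feature
    importance, DeLong AUC comparisons, and a leakage-audited within- and
    between-language (zero-shot transfer) evaluation harness. A synthetic
    two-group, two-language cohort generator stands in for access-restricted
    clinical corpora so that every pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
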