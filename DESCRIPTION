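Package: radspatial
Title: Weakly Supervised Spatial Relation Extraction from Radiology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-programming pipeline for extracting spatial triggers and
    nine spatial frame elements (Figure, Ground, Hedge, Diagnosis, Position
    status, Relative position, Distance, Reason, Associated process) from
    radiology report sentences without manually labeled training data.
    Provides category-typed lexicon construction and expansion, dictionary and
    regular-expression candidate generation, a registry of 19 deterministic
    labeling functions that vote frame-element labels for {spatial trigger,
    radiological entity} pairs, an EM-fitted one-coin generative label model
    that aggregates the noisy votes into probabilistic labels, trigger-level
    instance filtering, BIO sequence construction with trigger masking, an
    averaged-perceptron baseline sequence tagger, a trigger-conditioned
    evaluation protocol with false-positive/false-negative trigger accounting,
    and a synthetic radiology-sentence generator with gold frames for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
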