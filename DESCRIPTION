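Package: tavicbr
Title: Case-Based Reasoning Engine for Transcatheter Aortic Valve
    Implantation Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Retrieve/reuse case-based reasoning (CBR) engine for clinical
    decision support in transcatheter aortic valve implantation (TAVI)
    planning. Implements a hierarchical weighted heterogeneous similarity
    measure driven by clinical decision trees (attribute selection, level
    weighting and progressive case filtering), the heterogeneous
    Euclidean-overlap metric (HEOM) and a generalised weighted
    heterogeneous similarity measure (GWHSM) with genetic-algorithm weight
    learning as baselines, a distance- and rank-weighted voting reuse
    rule, leave-one-out and holdout evaluation with per-solution
    sensitivity and specificity, and label-preserving data augmentation
    plus a fully synthetic case-base generator.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
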