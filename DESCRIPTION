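Package: domap
Title: Mining Domain-Gene Ontology Associations from Co-Annotation and
    Predicting Protein Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mines statistically reliable associations between protein domains
    and Gene Ontology (GO) terms from co-annotation patterns on a shared
    protein set. Candidate domain-term pairs are scored with a Dice-type
    co-occurrence similarity, separated from a column-shuffled randomized null
    by Kolmogorov-Smirnov threshold selection, refined into association
    probabilities by expectation maximization over co-annotation triplets, and
    weighed with a leave-one-out likelihood-ratio evidence score. Accepted
    associations are propagated to proteins as scored function predictions and
    evaluated with the CAFA protein-centric protocol (Fmax, Smin, coverage,
    full and partial modes). Includes OBO and GAF readers, a synthetic
    benchmark generator with planted associations, and a pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
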