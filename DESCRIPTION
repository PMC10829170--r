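Package: contrastDDI
Title: Contrastive SMILES Representations for Drug-Drug Interaction
    Side-Effect Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised contrastive pre-training of a 1D-convolutional
    molecular encoder on enumerated SMILES views (InfoNCE objective over
    canonical/randomized pairs), transfer of the frozen representation to
    multiclass drug-drug interaction (DDI) side-effect classification under
    random, one-unseen and both-unseen cold-start evaluation schemes, and
    scaffold-level dataset analyses: Bemis-Murcko scaffold extraction,
    FP-Growth frequent-pattern mining with association rules, binary
    interaction/side-effect profile matrices with Jaccard clustering, and a
    five-metric binary similarity suite. Includes an offline synthetic-data
    generator producing scaffold-structured molecule libraries and DDI pair
    tables so the full pipeline runs without external chemical databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
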