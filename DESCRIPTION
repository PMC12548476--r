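Package: fedcog
Title: Simulating Federated Learning for Speech-Based Cognitive Impairment Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation framework for studying how institutional data
    heterogeneity affects federated learning of speech-derived cognitive
    impairment classifiers. Generates synthetic acoustic-feature cohorts with
    controllable class separation, partitions them into virtual institutions
    with quantity or label skew, trains class-weighted multilayer perceptron
    classifiers locally, aggregates them with sample-size-weighted federated
    averaging (FedAvg) or inverse-distance aggregation (IDA), and reports a
    balanced-accuracy/AUC evaluation panel comparing local and federated
    training conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
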