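Package: harclust
Title: Clustering-Guided Hierarchical Activity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies pairwise confusion between human activities from an
    unsupervised partition of labeled wearable-sensor feature tables (the
    activity confusion index), derives per-activity confusing sets at a
    ratio threshold, and trains a two-level activity recognizer that routes
    each top-level prediction through a specialized second-level classifier
    when the predicted activity has known confusers. Includes pluggable
    clustering back ends (k-means, k-medoids, Ward agglomerative) and
    classifier families (naive Bayes, k-nearest-neighbor, linear-kernel
    support vector machine, decision tree), macro-averaged evaluation
    metrics, parameter-sensitivity sweeps, loaders for delimited feature
    tables and the UCI-HAR file layout, and a synthetic benchmark generator
    with planted activity groups of controllable separability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    class,
    e1071,
    rpart,
    data.table,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
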