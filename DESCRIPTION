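Package: dbsdt
Title: Decision-Tree Prognosis Workflows for Pallidal DBS in Childhood
    Dystonia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Interpretable decision-tree prognostic modelling of deep brain
    stimulation (DBS) outcome in childhood dystonia. Provides a clinical
    cohort data model with limb-level neurophysiology coding (central motor
    conduction time, somatosensory evoked potentials), percentage-improvement
    outcomes on the Burke-Fahn-Marsden motor scale with configurable
    binarization, a classification-tree learner with native categorical
    splits, exhaustive feature-subset search under repeated k-fold
    cross-validation benchmarked against a majority-class classifier, a
    Monte Carlo resampling sweep of the severity cutoff yielding
    sensitivity/specificity curves with node-level bounds and ROC points,
    and a synthetic cohort generator so the whole workflow is testable
    without access-restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
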