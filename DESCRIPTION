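Package: qoverlap
Title: Content Overlap of Mental Health Questionnaires via Item Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the content overlap of mental-health questionnaires in
    an observer-independent way. Items from questionnaires of one diagnostic
    domain are grouped by symptom through three arms: expert consensus over
    three independent raters, k-means clustering of sentence embeddings, and
    prompted label assignment through a pluggable backend. Agreement between
    arms is measured with the Adjusted Rand Index against a permuted-embedding
    null distribution, and content overlap between questionnaires is measured
    with the Jaccard index over per-questionnaire symptom sets. A synthetic
    planted-partition generator makes every stage testable without network
    access or copyrighted questionnaire texts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
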