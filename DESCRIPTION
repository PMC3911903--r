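Package: grnsets
Title: Characteristic Interaction Sets and Group-Ensemble Voting for
    Network Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts characteristic interaction sets from collections of
    signed, directed gene regulatory networks predicted by non-deterministic
    reverse-engineering methods.  Interactions are classified by their relative
    frequency across predictions, pairwise co-occurrence (AND) and mutual
    exclusiveness (EX) relations between low-confidence interactions are scored
    with association-rule confidences combined by a min conjunction, AND-related
    pairs are merged into characteristic sets, and networks are grouped by the
    combination of sets they contain.  Signed ensemble voting is applied per
    group, and the resulting group-ensembles are evaluated by binary ensemble
    entropy, area under the precision-recall curve against a reference network,
    characteristic-set precision, and a simulated interaction-validation
    experiment.  A synthetic-ensemble generator with planted co-occurring sets,
    a high-confidence backbone, unspecific variable edges and random noise
    supports end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
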