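Package: edst
Title: Ensembles of Decision-Stump Trees for Imbalanced Drug-Combination Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interpretable multiclass classification with ensembles of
    decision-stump trees (EDST). Base learners are trees whose every internal
    node is a multi-branch decision stump built by sorted-interval merging and
    scored with a size-unweighted Gini impurity; trees are grown per
    one-vs-one class pair and fused by soft voting. The ensemble trains on
    class-balanced bootstrap subsets with cross-subset exchange of
    low-information stumps, retains the best-scoring half of the candidate
    trees, and supports IF-THEN rule extraction with coverage/accuracy
    scoring, rank-based AUC evaluation, stratified k-fold and
    leave-drug-combinations-out cross-validation, and a synthetic
    drug-combination data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
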