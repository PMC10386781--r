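Package: descforest
Title: Descriptive Forests of Least-PTS Decision Trees for Risk Topic Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers the primary risk topics hidden in an integrated
    tabular disease dataset with an association-rule tree grown in
    support-confidence space under a slope-of-interestingness criterion,
    builds one structure-generalized C4.5-style decision tree per topic
    (selected by the least prodigality-for-the-tree-structure, PTS = 2n - m,
    over a minimum-instances-per-leaf sweep), and combines the trees into a
    descriptive forest for per-instance risk voting and explanation.
    Includes supervised MDLP discretization, class-association-rule mining,
    correctness and coverage evaluation, and a synthetic-data generator with
    planted topics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    foreign,
    jsonlite,
    stats,
    utils
Suggests:
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
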