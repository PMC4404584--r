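Package: fkbn
Title: Restricted Bayesian Network Classifiers for Clinical Tabular Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns and evaluates restricted Bayesian network classifiers
    (naive Bayes, tree-augmented naive Bayes, K-dependence Bayesian
    networks, and a flexible K-dependence learner that augments a
    conditional-mutual-information maximum spanning tree with the
    strongest remaining dependencies) on categorical tabular data such as
    cancer-registry extracts. Includes mode/mean imputation, MDL
    entropy-based discretization of numeric attributes, Laplace-smoothed
    conditional probability tables, stratified cross-validated zero-one
    loss, Friedman rank comparison with sign-test ties, export of the
    learned dependency DAG for mining relationships among clinical
    variables, and a generator of synthetic datasets sampled from planted
    K-dependence networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
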