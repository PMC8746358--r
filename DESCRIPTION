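Package: azolopharm
Title: Fragment-Pair Descriptors and Iterative Neural-Network Pharmacophore
    Analysis for Small QSAR Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates QL fragment-pair topological descriptors from molecular
    structures (unordered pairs of electron donor/acceptor fragments connected
    through carbon-only paths), fits populations of narrow-throat multilayer
    perceptron regressors (k-m-1) against activity data, iteratively prunes
    descriptors with low network sensitivity, extracts the surviving
    high-sensitivity descriptor set as a pharmacophore, and counts pharmacophore
    entries in compound structures.  Includes a curated set of
    azolo[1,5-a]pyrimidine anticoagulants with reconstructed thrombin-time
    activity, and a synthetic-data generator with planted descriptor effects for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    nnet,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
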