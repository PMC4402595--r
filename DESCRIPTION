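Package: nbmpath
Title: Network-Based Detection of Overlapping Mutated Driver Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects candidate cancer driver pathways de novo from binary
    somatic mutation matrices (patients by genes), without prior pathway
    or interaction knowledge.  Gene sets are scored by an exclusive degree
    (mutual exclusivity), a coverage degree, and their product, the
    exclusivity-coverage degree.  Gene pairs with near-exclusive mutation
    patterns form a weighted gene network, and overlapping pathway
    candidates are grown from seed pairs by a greedy local search that
    maximizes the exclusivity-coverage degree.  Includes an
    implanted-pathway simulator with ground-truth labels for benchmarking
    recovery, a permutation-based empirical significance estimate, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
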