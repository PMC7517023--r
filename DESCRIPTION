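Package: miweb
Title: Mutual Information as a Measure of Structure in Bipartite Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes Shannon entropy, mutual information and its normalization S
    for bipartite ecological interaction matrices (plant-pollinator webs, host-
    parasite webs and the like), together with the specialization index H2'.
    Provides generators for the classical matrix topologies studied in community
    ecology (uniform, random, nested, modular, compound nested-modular), closed-
    form solutions for S in each family, and degree-preserving checkerboard swap
    experiments that demonstrate the invariance of mutual information to
    topology at fixed size, occupancy and degree distribution. Results are
    returned as tibbles and fitted objects carry tidy() and glance() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
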