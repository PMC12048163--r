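Package: coresym
Title: Reduction of Signed Regulatory Networks to Their Computational Core
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces signed directed gene regulatory networks to a minimal
    computational core in five steps: collapse of fibration-symmetric node
    classes (fibers, found by balanced-coloring refinement), pruning to the
    out-degree k-core, decomposition into strongly connected components with
    controller/connector role assignment, classification of two-node logic
    circuits (toggle switches, negative-feedback and Smolen oscillators,
    lock-on latches) and fiber building blocks by branching ratio, and a
    census of simple directed cycles. Includes degree- and edge-type-
    preserving randomization for empirical Z-score significance, canonical
    building-block fixtures, a planted-structure synthetic network
    generator, and a synchronous Boolean dynamics checker for fiber
    synchronization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
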