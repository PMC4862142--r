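Package: circsc
Title: Circular Sequence Comparison via Blockwise q-Gram Distance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rotation search for circular DNA, RNA and protein sequences
    under the beta-blockwise q-gram distance. Implements a naive solver,
    a block-anchored heuristic, an exact suffix-array sliding-window
    algorithm running in O(beta*m + n) time, and an alignment-based
    refinement stage that polishes the reported rotation using
    dollar-padded end blocks. Also provides EMBOSS-compatible global and
    local alignment baselines, a distance-based phylogeny pipeline
    (neighbour joining and Robinson-Foulds comparison), and a simulator
    of diverged, randomly rotated sequence families for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
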