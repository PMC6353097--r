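Package: nsalign
Title: Non-Sequential Protein Structure Alignment by Conformational Space
    Annealing and Greedy Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pairwise non-sequential alignment of protein C-alpha traces by
    global optimization with conformational space annealing (CSA) and by
    best-first greedy refinement over a move list.  Four alignment scoring
    functions are supported (DALI, SP, SO with a logistic surrogate, and
    TM-score), together with control over the minimum alignment-block size
    and whether reverse (N-to-C versus C-to-N) alignment blocks are
    permitted.  Includes Kabsch superposition with a mirror-image
    diagnostic, generators for synthetic chains and permuted pairs with
    known ground-truth alignments, precision/recall and Pareto comparison
    of alignments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
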