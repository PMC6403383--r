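Package: fisim
Title: Alignment-Free Phylogenetics via Markov Chains and Fuzzy Integral Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Alignment-free comparison of DNA sequences. Each sequence is
    summarised by the transition probability matrix of a first-order Markov
    chain over the nucleotide states (A, T, G, C), raised to a step k by the
    Chapman-Kolmogorov relation. Pairs of k-step matrices are scored with a
    Sugeno fuzzy integral under a lambda-fuzzy measure whose densities are
    the elementwise conservation maxima, yielding a similarity in [0, 1] and
    the distance 1 - similarity. The step k is selected automatically by
    convergence of consecutive distance matrices (root-mean-square
    difference). Distance matrices feed UPGMA or neighbor-joining tree
    construction with Newick and PHYLIP square-matrix interchange, and
    evaluation utilities (Robinson-Foulds distance, ROC/AUC against group
    labels) plus a Markov-chain sequence simulator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    pROC,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
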