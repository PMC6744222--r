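Package: pogdiv
Title: Divergence and Selection Profiles of Single-Copy Ortholog Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide analysis of putatively single-copy
    orthologous genes (POGs) between pairs of allopatric taxa. From two
    transcript sets the package identifies reciprocal-best-hit ortholog
    pairs, extracts coding sequences, builds codon-aware pairwise
    alignments, and estimates synonymous (Ks) and nonsynonymous (Ka)
    substitution rates and their ratio by Nei-Gojobori (NG86) counting
    and by a Yang-Nielsen (YN00) style estimator that accounts for
    transition/transversion and codon-frequency bias. Per-pair summaries
    include the Ks peak-frequency statistic (plain and tie-merged
    variants), six selection-pressure categories of Ka/Ks, a permutation
    scan test for spatially clustered substitutions in candidate
    positive-selection genes, and cross-pair correlation analyses of
    divergence time, peak Ks, and category abundances. A codon-model
    simulator generates gene pairs, cohorts, and multi-pair panels with
    known omega, kappa, and divergence so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
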