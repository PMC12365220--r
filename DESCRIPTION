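Package: abcd
Title: Abundance-Biased Codon Diversification for Recombination-Safe DNA Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs synonymous coding sequences that are maximally diverse at
    the nucleotide level from a reference DNA context while restricting codon
    choice to abundant codons of a target organism and excluding forbidden
    motifs such as restriction sites and viral inverted terminal repeats.
    Provides a thermodynamic repeat-interaction objective for ranking designs,
    exact-repeat diagnostics (longest identical stretch, maximal exact matches,
    dot plots), and an analysis pipeline for profiling recombination
    breakpoints in long reads from viral vector preparations, together with a
    matching chimeric-read simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
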