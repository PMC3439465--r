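Package: motifsel
Title: Bayesian Variable Selection of Regulatory Motifs from Cross-Species
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates candidate transcription-factor binding motifs in the
    promoters of a (possibly newly sequenced) species by regressing gene
    expression measured in one or more phylogenetically close, well-annotated
    species onto position-weight-matrix matching scores computed against an
    order-k Markov background. Motif inclusion is inferred with a spike-and-slab
    g-prior model explored by multi-chain Metropolis search over inclusion
    indicators, with exact enumeration available at small candidate counts. A
    matrix-variate extension couples experiments across species with
    phylogeny-derived variance weights, and a robustness protocol repeats the
    selection over control-gene subsets, leave-one-out experiment folds and a
    sparsity grid. A synthetic-data generator with planted binding sites makes
    the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
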