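Package: promscan
Title: Promoter Extraction, Exact P-Value Motif Scanning and Regulatory
    Over-Representation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene-centered toolkit for regulatory sequence analysis:
    reads JASPAR-style position frequency matrices, turns them into
    log-likelihood-ratio scoring models with exact p-value calibration by
    dynamic-programming convolution of the null score distribution, extracts
    strand-aware promoter windows around transcription or coding start sites
    from genome FASTA plus refGene-style tables, scans promoter sets on both
    strands for binding-site hits below a p-value cutoff, stores promoters
    and hits in a layered annotation store supporting combinatorial and
    cross-genome homology queries, and computes over-representation ratios
    with bootstrap confidence intervals between positive and negative gene
    sets, including co-occurring site pairs with separation constraints.
    A seeded synthetic-data generator (genomes, gene tables, homology maps,
    planted motifs) makes every analysis reproducible without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
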