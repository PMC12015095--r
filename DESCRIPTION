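Package: hrescan
Title: Hormone Response Element Counting and Phylogenetic Models of Sexual Size Dimorphism
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts androgen and estrogen response elements (AREs/EREs) in
    genome assemblies by degenerate IUPAC motif scanning on both strands with
    correct palindrome handling, aggregates hits into merged windows flanking
    transcription start sites, and relates the resulting per-species counts to
    sexual size dimorphism (ln male/female body mass) with phylogenetic
    generalized least squares under maximum-likelihood Pagel's lambda.
    Includes phylogenetic principal component analysis of per-motif counts,
    per-gene effect scans with direction summaries, a genome-quality (contig
    N50) check, and a synthetic-data generator that plants motifs in simulated
    genomes and evolves traits on birth-death trees so every pipeline stage is
    testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    rtracklayer,
    BiocGenerics,
    GenomeInfoDb,
    withr
Config/testthat/edition: 3
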