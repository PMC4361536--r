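Package: psgscan
Title: Whole-Genome Scans for Positively Selected Genes from Ortholog
    Divergence and Two-Population SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to detect protein-coding genes under positive selection
    during the differentiation of two closely related populations or
    subspecies. Implements pairwise Ka/Ks estimation by the Nei-Gojobori
    (1986) counting method with Jukes-Cantor correction and a one-sided
    Fisher exact test, classification of gene pairs with zero synonymous
    substitutions (nonsynonymous substitution genes), sliding-window
    Ka/Ks scans, reciprocal-best-hit orthology with a collinearity
    filter, codon back-translation of protein alignments, SNP functional
    effect annotation within gene models, per-site two-population Fst,
    an Fst-outlier scan against a simulated Balding-Nichols neutral null
    with heterozygosity-conditional confidence envelopes, gene-level
    positive-selection classification, and neighbor-joining phylogenies
    of accessions from simple-matching distances over selected sites.
    A synthetic-data module generates diverged ortholog pairs with known
    substitution counts and two-population SNP matrices with known
    selected loci so that the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
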