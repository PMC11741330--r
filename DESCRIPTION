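Package: organelleMA
Title: Organelle Mutation-Accumulation Analysis for Plant Mitochondrial
    and Plastid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates germline mutation rates in plant organelle genomes
    from mutation-accumulation (MA) line sequencing. Turns per-site allele
    count tables into filtered variant calls (frequency, depth, wild-type
    background, repeat-copy and homology filters), corrects mitochondrial
    allele frequencies for reads derived from nuclear copies of
    mitochondrial DNA (numts), computes frequency-weighted mutation rates
    and Poisson upper bounds, strand-collapsed mutation spectra, a
    permutation test for synonymous-variant enrichment in protein-coding
    sequence, and homopolymer-centric insertion/deletion bias analyses.
    Includes a forward simulator of MA experiments (genomes with planted
    simple repeats, heteroplasmic drift, numt read bleed-through, and
    sequencing noise) so every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
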