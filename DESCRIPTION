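Package: crisprable
Title: CRISPRable Genome Landscape and Heritability Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how much of the genome is editable by
    CRISPR-Cas enzymes and what that editable fraction contributes to
    complex-trait heritability. Scans a genome for IUPAC-degenerate
    protospacer-adjacent motifs (PAMs) per fixed-width segment on both
    strands, ranks segments into Cas-enriched regions, builds binary SNP
    annotations, and estimates per-annotation heritability enrichment by
    stratified LD score regression with block-jackknife standard errors.
    Includes Fisher exact odds-ratio matrices against functional
    annotations, off-target-to-segment matching, and generators for
    synthetic genomes, LD-structured genotype panels and GWAS summary
    statistics so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
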