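Package: promcis
Title: Cis-Regulatory Motif Annotation, Conserved Module Detection and
    Diversity Statistics for Plant Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scans promoter sequences for degenerate (IUPAC) cis-regulatory
    motifs with coordinates anchored at the translation start codon, resolves
    nested hits to the longest motif, and tabulates per-gene motif counts.
    Builds indel-aware consensus annotations across sets of promoter alleles
    or orthologs, detects conserved cis-regulatory modules (CCRMs), and
    merges per-set consensuses into an overall consensus. Computes promoter
    polymorphism and diversity statistics (segregating sites, indels,
    haplotypes, haplotype diversity, nucleotide diversity, Watterson's
    theta, Tajima's D with significance class) from aligned allele sets.
    Includes a synthetic promoter-family generator with planted motif
    modules and a machine-readable truth record, so the whole pipeline is
    testable without external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
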