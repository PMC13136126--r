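Package: ahlqs
Title: Discovery and Characterization of Acyl-Homoserine-Lactone Quorum-Sensing Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining bacterial genomes for N-acyl-homoserine-lactone
    (AHL) quorum-sensing genes. Curates LuxI/LuxR-family reference sets from
    protein collections, builds position-specific scoring profiles with an
    empirically calibrated e-value inclusion cutoff, scans annotated genomes
    for coordinate-anchored homologs, classifies LuxR-family proteins by
    domain architecture (autoinducer-binding domain plus helix-turn-helix
    versus HTH-only), resolves genomic-neighborhood topology (cognate
    luxI/luxR pairs versus solos, signed intergenic distances, orientation,
    flank inventories), supports alignment trimming, distance trees and
    monophyly testing, and matches LC-MRM-MS transitions against an AHL
    standards table using the diagnostic homoserine-lactone fragment at
    m/z 102. A synthetic-data generator provides ground-truthed genomes,
    protein families and peak lists so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
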