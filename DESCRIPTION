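Package: exont
Title: Exon Ontology Annotation and Enrichment for Coding Exons
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Associates coding exons with ontology terms describing the
    protein features they encode (domains, modified residues, localization
    signals, structural states) by projecting protein-coordinate annotations
    through CDS models onto the genome. Computes a per-term coverage score
    (covered nucleotides per kilo-nucleotide of coding sequence) for exons
    and exon sets, and tests term enrichment in a user-supplied exon list
    against size-matched random exon sets drawn from a category-appropriate
    control pool (all coding, first, internal, last, constitutive or
    alternative internal exons), with log-scale Z-scores and
    Benjamini-Hochberg false discovery rates. Includes a regular-expression
    scanner for localization motifs, a PSI-MITAB interaction-partner lookup,
    a ground-truthed synthetic fixture generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
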