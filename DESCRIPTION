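Package: tifseqr
Title: Transcript Isoform Boundary Calling from Paired 5'/3' End Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts aligned paired 5'/3' boundary reads of single RNA
    molecules into deduplicated boundary tags, filtered and clustered
    transcription start site (TSS) and polyadenylation site (PAS) clusters,
    and linked transcript isoform boundary (TIF) calls. Includes UMI-based
    PCR-duplicate removal with directional adjacency, an internal-priming
    artifact filter based on genomic A-content downstream of putative
    poly(A) sites, power-law normalization of boundary tag counts,
    annotation-based isoform classification, overlap typology of tandem
    transcription units, read-through (transcriptional fusion) detection,
    and a deterministic simulator that generates genomes, annotations
    and paired-tag libraries with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
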