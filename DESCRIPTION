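Package: tripkit
Title: Analysis of Barcoded piggyBac Reporter Integrations (TRIP)
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for TRIP (thousands of reporters integrated
    in parallel) experiments with barcoded piggyBac reporter transgenes:
    extraction and error-collapsing of promoter indexes and 18-nt barcodes
    from normalization (gDNA), expression (cDNA) and inverse-PCR mapping
    libraries; k-mer seed-and-extend localization of each barcode's
    DpnII-bounded genomic flank to a TTAA insertion site with reads_r and
    freq1_r confidence statistics; normalized per-barcode transcriptional
    activity and reliability filtering; gene-element and chromatin-type
    annotation with TSS/TTS distances and activity enrichment; and a
    pLogo-style positional binomial motif matrix around insertion sites.
    Includes a synthetic-data generator (toy genome, gene models, chromatin
    segmentation, ground-truth insertions and the three FASTQ libraries)
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
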