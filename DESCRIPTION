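Package: nrgfusion
Title: Targeted Detection and Interpretation of NRG1 Gene Fusions from DNA
    and RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for targeted analysis of NRG1 rearrangements in breast
    cancer sequencing data: splice-anchor text search of raw RNA reads for
    fusion junctions (including cryptic, unannotated exons), parsing and
    somatic filtering of breakend structural-variant calls, integration of
    DNA and RNA evidence into fusion calls with reading-frame and
    domain-retention annotation, read-count copy-number profiling with
    change-point/junction concordance, and derivative-chromosome
    reconstruction from junction segment graphs. Includes a seeded
    synthetic-data generator (toy genome, rearrangement presets emulating
    the MDA-MB-175 double fusion, junction-spanning RNA reads, tumour/normal
    breakend VCFs) so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    SummarizedExperiment,
    VariantAnnotation,
    dplyr,
    jsonlite,
    purrr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
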