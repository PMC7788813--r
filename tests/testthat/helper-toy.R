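# Shared fixtures, built once per session and memoised.

toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_genome(1)
    cache
  }
})

anchor_index_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      toy <- toy_fixture()
      cache <<- build_anchor_index(toy$genes, toy$genome)
    }
    cache
  }
})

# the MDA-MB-175-style cell-line scan (reads written + scanned once)
mda175_scan_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      toy <- toy_fixture()
      reads <- simulate_rna_reads(toy$genome, toy$genes,
                                  mda175_read_composition(toy$genes),
                                  seed = 11)
      fq <- tempfile(fileext = ".fastq")
      write_fastq(reads, fq)
      cache <<- list(reads = reads, fastq = fq,
                     scan = scan_junctions(fq, anchor_index_fixture()))
    }
    cache
  }
})

# independent reverse complement (no Biostrings), for oracle checks
rc_oracle <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# a tiny ad-hoc genome + plus-strand gene for unit tests
tiny_gene <- function(starts, ends, strand = "+", coding = NULL,
                      name = "G1", chrom = "chr1", tags = NULL) {
  coding <- coding %||% rep(TRUE, length(starts))
  n <- length(starts)
  ord <- if (strand == "+") order(starts) else order(-starts)
  gene_model(name, strand,
             exon_table(name, as.character(seq_len(n)), seq_len(n), chrom,
                        starts[ord], ends[ord], strand, coding[ord],
                        tags = tags))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
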