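# Human-readable reporting and pipeline orchestration over the module
# functions. The numbered scripts under analysis/ are thin drivers around
# these helpers.

#' Markdown report for a set of fusion calls
#'
#' @param calls fusion-call tibble (see [annotate_fusion()]).
#' @param junction_summary optional junction summary tibble from
#'   [summarise_junctions()].
#' @param title report title.
#' @return character vector of markdown lines.
#' @export
fusion_report_md <- function(calls, junction_summary = NULL,
                             title = "Fusion report") {
  lines <- c(paste("#", title), "")
  if (is.null(calls) || nrow(calls) == 0) {
    lines <- c(lines, "No fusion candidates.")
  } else {
    lines <- c(lines, "## Fusion candidates", "",
               paste("| case | junction | 5' partner | 3' gene |",
                     "spliced-in exon | status | frame | EGF-like |",
                     "RNA split reads |"),
               "|---|---|---|---|---|---|---|---|---|")
    for (i in seq_len(nrow(calls))) {
      x <- calls[i, ]
      lines <- c(lines, sprintf(
        "| %s | %s | %s | %s | %s | %s | %s | %s | %d |",
        x$case_id, x$junction_id %|na|% "-", x$five_prime %|na|% "-",
        x$three_prime, x$spliced_in_exon %|na|% "-", x$status,
        x$frame_status %|na|% "-", ifelse(x$egf_like, "yes", "no"),
        x$rna_split_reads))
    }
  }
  if (!is.null(junction_summary) && nrow(junction_summary) > 0) {
    lines <- c(lines, "", "## Junction read counts", "",
               "| acceptor | donor | reads | % of acceptor |",
               "|---|---|---|---|")
    for (i in seq_len(nrow(junction_summary))) {
      x <- junction_summary[i, ]
      lines <- c(lines, sprintf("| %s | %s | %d | %d |",
                                x$acceptor, x$donor, x$n, x$percent))
    }
  }
  lines
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Run the cell-line style pipeline end to end on a preset
#'
#' Simulate (derivative + RNA reads + tumour/normal VCF with one
#' excluded-contig decoy), scan the reads, filter the structural variants,
#' predict fusion candidates, integrate DNA and RNA evidence, and classify
#' the case. Used by the analysis scripts and the end-to-end recovery tests.
#'
#' @param preset preset name (see [rearrangement_preset()]).
#' @param toy toy genome (built with `make_toy_genome(seed)` if NULL).
#' @param seed integer seed for all simulation.
#' @param dir optional directory for fastq/vcf artifacts; tempdir by default.
#' @param dedup collapse duplicate reads in the junction summary.
#' @return list(preset, truth, scan, junctions (filtered), record
#'   (classified), calls, summary, outcome_class, expected_class, paths).
#' @export
run_preset_pipeline <- function(preset, toy = NULL, seed = 1L, dir = NULL,
                                dedup = FALSE) {
  toy <- toy %||% make_toy_genome(seed)
  dir <- dir %||% tempfile(paste0("nrgfusion_", preset, "_"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- rearrangement_preset(preset, toy)
  genes <- toy$genes
  nrg <- genes$NRG

  # --- RNA --------------------------------------------------------------
  reads <- preset_rna_reads(preset, toy, seed)
  fastq <- file.path(dir, "rna.fastq")
  write_fastq(reads, fastq)
  index <- build_anchor_index(genes, toy$genome)
  scan <- scan_junctions(fastq, index, dedup = dedup)

  # --- DNA --------------------------------------------------------------
  vcf <- file.path(dir, "tumour_normal.vcf")
  simulate_sv_vcf(truth$junctions, vcf, toy$contigs, decoy_chroms = "chrM")
  parsed <- parse_breakend_vcf(vcf)
  filtered <- filter_somatic(parsed, allowed_chroms = names(toy$contigs))
  record <- breakpoints_in_gene(filtered, nrg, case_id = preset)

  # --- integrate and classify -------------------------------------------
  five_candidates <- list(genes$WRNL, genes$PPX1, genes$TNM)
  candidates <- purrr::map_dfr(seq_len(nrow(filtered)), function(i) {
    res <- predict_fusion_from_junction(filtered[i, ], five_candidates, nrg)
    if (is_fusion_candidate(res)) res else NULL
  })
  record <- integrate_fusion_evidence(record, candidates, scan$summary,
                                      genes, nrg)
  record <- classify_rearrangement(record, nrg)
  list(preset = preset, truth = truth, scan = scan, junctions = filtered,
       record = record, calls = record$calls, summary = scan$summary,
       outcome_class = record$outcome_class,
       expected_class = truth$expected_class,
       paths = list(fastq = fastq, vcf = vcf))
}

# RNA reads planted per preset (empty tibble: no RNA support planted)
preset_rna_reads <- function(preset, toy, seed) {
  genes <- toy$genes
  no_reads <- tibble::tibble(read_id = character(0), seq = character(0))
  if (preset == "mda175") {
    return(simulate_rna_reads(toy$genome, genes,
                              mda175_read_composition(genes), seed = seed))
  }
  if (preset == "simple_del") {
    iso <- c(paste0("WRNL:", 1:4), paste0("NRG:", c(3:6, 9, 11:18)))
    comp <- tibble::tibble(name = "wrnl4_ex3", isoform = list(iso),
                           exonA = "WRNL:4", exonB = "NRG:3", count = 6L)
    return(simulate_rna_reads(toy$genome, genes, comp, seed = seed))
  }
  if (preset == "dup_inv_insert") {
    # spliced from an undocumented partner exon: the donor sequence is
    # genomic sequence upstream of the DNA breakend, absent from the models
    novel_donor <- as.character(Biostrings::subseq(toy$genome[["chrB"]],
                                                   9941L, 10000L))
    three <- isoform_sequence(toy$genome, genes,
                              paste0("NRG:", c(3:6, 9, 11:18)))
    return(plant_junction_reads(paste0(novel_donor, three),
                                nchar(novel_donor), n = 2L,
                                prefix = "novel", seed = seed + 99L))
  }
  no_reads
}
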