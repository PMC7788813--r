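# Synthetic data, part 1: a seeded toy genome with four mini genes emulating
# the topology of a PPP6R3/TENM4/NRG1-style double-fusion locus plus an
# upstream 5' neighbour of the NRG1-like gene:
#
#   chrA (+)  PPX1  — 3 exons, non-coding first exon (the UTR-only 5' partner)
#   chrA (-)  TNM   — 16 exons, minus strand, coding from exon 3; a 78-nt
#                     cryptic exon ("int15") lies antisense (plus strand)
#                     within intron 15
#   chrB (+)  WRNL  — 5 exons, the gene immediately 5' of the NRG1-like gene
#   chrB (+)  NRG   — 18 exons numbered in genome order; exons 1/2/7/8 are
#                     transcription starts, 3/4 Ig-like, 9 EGF-like,
#                     alternative exons {10|11}, beta3 extension of exon 11,
#                     transmembrane exon 12, cytoplasmic tail 13-18
#
# Coding exon lengths of TNM through exon 12 sum to a multiple of three, so
# a TNM->NRG exon-3 fusion is in frame; the cryptic exon is 78 nt (26 codons)
# so its optional insertion preserves frame.

toy_chrom_len <- 200000L

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

#' Generate the toy genome and gene models
#'
#' Seeded and deterministic: identical seeds give byte-identical sequences.
#' All splice anchors of the four genes are verified unique (both strands)
#' at the given `k`.
#'
#' @param seed integer seed.
#' @param k anchor length used for the uniqueness check (default 20).
#' @return list(genome = DNAStringSet, genes = named list of gene_models,
#'   contigs = named lengths).
#' @export
make_toy_genome <- function(seed = 1L, k = 20L) {
  genome <- withr::with_seed(seed, Biostrings::DNAStringSet(c(
    chrA = rand_dna(toy_chrom_len), chrB = rand_dna(toy_chrom_len))))
  genes <- toy_gene_models()
  idx <- build_anchor_index(genes, genome, k = k)  # errors on collisions
  for (i in seq_len(nrow(idx))) {
    hits <- sum(Biostrings::vcountPattern(idx$sequence[i], genome)) +
      sum(Biostrings::vcountPattern(revcomp(idx$sequence[i]), genome))
    if (hits != 1)
      stop("anchor not unique in toy genome: ", idx$gene[i], ":",
           idx$label[i], "/", idx$side[i])
  }
  list(genome = genome, genes = genes,
       contigs = c(chrA = toy_chrom_len, chrB = toy_chrom_len))
}

toy_gene_models <- function() {
  ppx1 <- gene_model(
    "PPX1", "+",
    exon_table("PPX1", c("1", "2", "3"), 1:3, "chrA",
               start = c(10001L, 12001L, 14001L),
               end = c(10180L, 12150L, 14220L),
               strand = "+", coding = c(FALSE, TRUE, TRUE),
               tags = list("transcription_start", character(0), character(0))))

  # TNM: minus strand; transcript order = descending genomic coordinate
  tnm_starts <- c(117801L, 114001L, 110001L,
                  105501L, 101001L, 96501L, 92001L, 87501L, 83001L, 78501L,
                  74001L, 69501L, 65001L, 60501L, 56001L, 51001L)
  tnm_ends <- tnm_starts + c(199L, 99L, 149L, rep(119L, 12), 299L)
  tnm_tags <- c(list("transcription_start", "transcription_start"),
                rep(list(character(0)), 13),
                list(character(0)))
  tnm <- gene_model(
    "TNM", "-",
    exon_table("TNM", as.character(1:16), 1:16, "chrA",
               start = tnm_starts, end = tnm_ends, strand = "-",
               coding = c(FALSE, FALSE, rep(TRUE, 14)), tags = tnm_tags))

  wrnl <- gene_model(
    "WRNL", "+",
    exon_table("WRNL", as.character(1:5), 1:5, "chrB",
               start = c(20001L, 24001L, 28001L, 32001L, 36001L),
               end = c(20150L, 24150L, 28150L, 32150L, 36400L),
               strand = "+", coding = c(FALSE, rep(TRUE, 4)),
               tags = c(list("transcription_start"),
                        rep(list(character(0)), 4))))

  nrg_starts <- c(80001L, 84001L, 90001L, 95001L, 100001L, 105001L,
                  118501L, 124001L, 130001L, 135001L, 138001L, 142001L,
                  146001L, 149001L, 152501L, 155001L, 158001L, 161001L)
  nrg_ends <- nrg_starts + c(159L, 149L, 129L, 139L, 99L, 109L,
                             99L, 99L, 129L, 99L, 89L, 129L,
                             99L, 99L, 99L, 99L, 99L, 699L)
  ts <- "transcription_start"
  nrg_tags <- list(ts, ts, "Ig_like", "Ig_like", character(0), character(0),
                   ts, ts, "EGF_like", character(0), character(0),
                   "transmembrane", "cytoplasmic_tail", "cytoplasmic_tail",
                   "cytoplasmic_tail", "cytoplasmic_tail", "cytoplasmic_tail",
                   "cytoplasmic_tail")
  nrg_coding <- c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                  rep(TRUE, 10))
  int15 <- exon_table("TNM", "int15", NA_integer_, "chrA",
                      start = 53001L, end = 53078L, strand = "+",
                      coding = TRUE, tags = list("cryptic"))
  nrg <- gene_model(
    "NRG", "+",
    exon_table("NRG", as.character(1:18), 1:18, "chrB",
               start = nrg_starts, end = nrg_ends, strand = "+",
               coding = nrg_coding, tags = nrg_tags),
    alt_groups = list(c(10L, 11L)),
    tail_exons = 12:18,
    beta3_extension = list(exon = 11L, ext_end = 138450L),
    cryptic_exons = int15)

  list(PPX1 = ppx1, TNM = tnm, WRNL = wrnl, NRG = nrg)
}

#' Write toy genome, annotation and model overrides to a directory
#'
#' Emits `genome.fa`, `genes.gtf` and `models.yaml`, the three inputs the
#' loaders consume.
#'
#' @param toy list from [make_toy_genome()].
#' @param dir output directory (created if needed).
#' @return invisible named list of paths.
#' @export
write_toy_genome <- function(toy, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(fasta = file.path(dir, "genome.fa"),
                gtf = file.path(dir, "genes.gtf"),
                yaml = file.path(dir, "models.yaml"))
  write_genome_fasta(toy$genome, paths$fasta)
  write_gene_models(toy$genes, paths$gtf, paths$yaml)
  invisible(paths)
}
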