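#!/usr/bin/env Rscript
# 01 — Simulate the study inputs.
#
# Builds the seeded toy genome (two ~200 kb chromosomes carrying the
# PPX1/TNM/WRNL/NRG mini genes), the five rearrangement presets with their
# truth junction tables, the cell-line RNA read set at the fixed split-read
# composition (38 int15 + 122 exon-12 reads at the NRG exon-3 acceptor;
# 144 + 1 at the TNM exon-3 acceptor), and tumour/normal breakend VCFs with
# one mitochondrial decoy junction each plus a small panel of normals.

suppressMessages(library(nrgfusion))
seed <- 1L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

toy <- make_toy_genome(seed)
paths <- write_toy_genome(toy, out)
message("wrote toy genome and gene models to ", out)

presets <- c("mda175", "simple_del", "dup_inv_insert", "inactivating",
             "complex_multi")
for (p in presets) {
  truth <- rearrangement_preset(p, toy)
  if (!is.null(truth$derivative))
    write_genome_fasta(truth$derivative,
                       file.path(out, paste0("derivative_", p, ".fa")))
  utils::write.table(truth$junctions,
                     file.path(out, paste0("truth_junctions_", p, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # germline junction + decoy exercise the somatic filters downstream
  germ <- truth$junctions[1, ]
  germ$id <- "germline_1"
  germ$posA <- germ$posA + 5000L
  simulate_sv_vcf(truth$junctions, file.path(out, paste0(p, ".vcf")),
                  toy$contigs, tumour_support = 10L, germline = germ,
                  decoy_chroms = "chrM")
}

# panel of normals: two artefact junctions seen across normal samples
panel <- tibble::tibble(
  id = c("pon_1", "pon_2"),
  chromA = "chrA", posA = c(150000L, 180000L), sideA = "left",
  chromB = "chrB", posB = c(10000L, 60000L), sideB = "right")
write_panel_bedpe(panel, file.path(out, "panel_of_normals.bedpe"))

# cell-line RNA reads at the fixed composition
reads <- simulate_rna_reads(toy$genome, toy$genes,
                            mda175_read_composition(toy$genes), seed = seed)
write_fastq(reads, file.path(out, "mda175_rna.fastq"))
message("planted ", nrow(reads), " junction-spanning RNA reads")

write_run_manifest(file.path(out, "manifest.json"),
                   list(step = "simulate", presets = presets,
                        read_length = 75, k = 20), seed = seed)
message("done")
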