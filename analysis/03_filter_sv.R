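#!/usr/bin/env Rscript
# 03 — Parse and somatically filter the breakend calls.
#
# Each preset VCF carries the true somatic junctions plus one planted
# germline junction (supporting reads in the matched normal) and one decoy
# junction on the mitochondrial contig. The somatic filters must remove
# exactly the plants: any normal support, panel-of-normals matches (+/-10 bp,
# same orientation), and excluded contigs.

suppressMessages(library(nrgfusion))
sim <- "results/sim"
out <- "results/sv"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genes <- load_gene_models(file.path(sim, "genes.gtf"),
                          file.path(sim, "models.yaml"))
panel <- read_panel_bedpe(file.path(sim, "panel_of_normals.bedpe"))
allowed <- c("chrA", "chrB")

records <- list()
for (p in c("mda175", "simple_del", "dup_inv_insert", "inactivating",
            "complex_multi")) {
  parsed <- parse_breakend_vcf(file.path(sim, paste0(p, ".vcf")))
  kept <- filter_somatic(parsed, panel = panel, allowed_chroms = allowed)
  truth <- utils::read.table(
    file.path(sim, paste0("truth_junctions_", p, ".tsv")),
    header = TRUE, sep = "\t")
  message(sprintf("%-16s parsed %d junctions, %d somatic (truth %d)",
                  p, nrow(parsed), nrow(kept), nrow(truth)))
  stopifnot(setequal(kept$id, truth$id))
  utils::write.table(kept, file.path(out, paste0("somatic_", p, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- breakpoints_in_gene(kept, genes$NRG, case_id = p)
  records[[p]] <- tibble::tibble(case_id = p,
                                 n_breakpoints = rec$n_breakpoints,
                                 multi_breakpoint = rec$multi_breakpoint)
}
per_case <- dplyr::bind_rows(records)
utils::write.table(per_case, file.path(out, "per_case_breakpoints.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(per_case)
message("done")
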