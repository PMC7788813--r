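#!/usr/bin/env Rscript
# 06 — Derivative-chromosome reconstruction.
#
# From the filtered junctions of the double-fusion derivative: build the
# segment graph, enumerate bounded walks from the 5'-gene segment to the
# distal NRG segment, and keep walks that explain all three observed
# transcript junctions (the 5'-gene exon into the partner body, partner exon
# 12 into the inverted cryptic exon, and the cryptic exon into NRG exon 3).
# On the novel-partner preset, recognise the tandem-duplication-with-
# inverted-insertion motif and report its spans (57 kb / 24 kb).

suppressMessages(library(nrgfusion))
out <- "results/reconstruction"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L
toy <- make_toy_genome(seed)
genes <- toy$genes

truth <- rearrangement_preset("mda175", toy)
graph <- build_segment_graph(truth$junctions, toy$contigs)
write_segment_graph_dot(graph, file.path(out, "segment_graph.dot"))
walks <- enumerate_walks(
  graph, list(seg = segment_at(graph, "chrA", 10001), orient = "+"),
  list(seg = segment_at(graph, "chrB", 150000), orient = "+"),
  max_length = 12)
message(length(walks), " candidate walk(s); truncated: ",
        isTRUE(attr(walks, "truncated")))

observed <- list(c("PPX1:1", "TNM:3"), c("TNM:12", "TNM:int15"),
                 c("TNM:int15", "NRG:3"))
explained <- vapply(walks, function(m)
  sum(vapply(observed, function(j)
    explain_transcript(m, graph, genes, j), logical(1))), 1L)
best <- walks[[which.max(explained)]]
message("best walk explains ", max(explained), "/", length(observed),
        " observed junctions:")
print(best$walk)

models_json <- lapply(seq_along(walks), function(i) list(
  walk = paste(paste0(walks[[i]]$walk$seg_id, walks[[i]]$walk$orient),
               collapse = " "),
  junctions_explained = explained[i]))
jsonlite::write_json(models_json, file.path(out, "derivative_models.json"),
                     auto_unbox = TRUE, digits = NA)

dup <- rearrangement_preset("dup_inv_insert", toy)
motif <- detect_dup_with_inverted_insertion(dup$junctions,
                                            gene = genes$NRG)
jsonlite::write_json(motif, file.path(out, "dup_inv_insert_motif.json"),
                     auto_unbox = TRUE, digits = NA)
message(sprintf("dup-with-inverted-insertion motif: %.0f kb duplication, %.0f kb inverted insert",
                motif$dup_span_bp / 1000, motif$insert_span_bp / 1000))
message("done")
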