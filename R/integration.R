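# DNA + RNA evidence integration. DNA junction candidates alone are
# provisional (orientation-consistent geometry only); RNA split reads at the
# 3' gene's acceptors confirm them, and RNA junctions with no geometric DNA
# candidate (e.g. a fusion transcribed through a derivative too complex to
# read from one junction) still become calls when the case carries DNA
# breakpoints in the gene.

#' Integrate DNA candidates with RNA junction calls
#'
#' Builds the fusion-call table of a case record:
#' 1. every DNA candidate from [predict_fusion_from_junction()] is annotated
#'    via [annotate_fusion()], with RNA split-read support counted from the
#'    junction summary (reads at the spliced-in acceptor whose donor is the
#'    candidate partner's donor exon; any novel donor for novel-partner
#'    candidates);
#' 2. RNA junction-summary rows at an acceptor of the 3' gene whose donor is
#'    an exon of another modelled gene, and which match no DNA candidate,
#'    become `rna_junction` calls (frame from the donor gene's coding
#'    contribution) — emitted only when the case has DNA breakpoints in the
#'    gene, keeping DNA+RNA as the confirmation standard;
#' 3. RNA rows whose donor is a cryptic exon become `cryptic_insertion`
#'    calls: a cryptic cassette exon preserves the reading frame established
#'    by the junction it interrupts iff its length is a multiple of three.
#'
#' @param record case_record from [breakpoints_in_gene()].
#' @param candidates tibble of DNA candidates (possibly zero rows), with a
#'   `donor_label` column naming the 5' partner's donor exon where known.
#' @param summary RNA junction summary from [summarise_junctions()] (NULL for
#'   DNA-only).
#' @param genes named list of gene_models.
#' @param three_prime_gene gene_model of the 3' gene.
#' @return the record with `calls` filled.
#' @export
integrate_fusion_evidence <- function(record, candidates, summary, genes,
                                      three_prime_gene) {
  g3 <- three_prime_gene
  calls <- purrr::map_dfr(seq_len(NROW(candidates)), function(i) {
    cand <- candidates[i, ]
    donor <- cand$donor_label
    if (is.null(donor) || is.na(donor)) donor <- NULL
    fg <- if (cand$status == "candidate") genes[[cand$five_prime]] else NULL
    rna <- rna_support_for(summary, g3, cand, donor)
    annotate_fusion(cand, fg, g3, donor_label = donor,
                    rna_split_reads = rna, case_id = record$case_id)
  })

  if (!is.null(summary) && nrow(summary) > 0 && record$n_breakpoints >= 1L) {
    acc_rows <- summary[grepl(paste0("^", g3$name, ":"), summary$acceptor) &
                          !grepl("^novel\\(", summary$donor) &
                          summary$donor != "too_short", ]
    for (i in seq_len(nrow(acc_rows))) {
      row <- acc_rows[i, ]
      spliced <- suppressWarnings(as.integer(sub("^[^:]+:", "",
                                                 row$acceptor)))
      if (is.na(spliced)) next
      donor_gene <- sub(":.*$", "", row$donor)
      donor_label <- sub("^[^:]+:", "", row$donor)
      if (donor_gene == g3$name) next  # normal internal splicing
      already <- nrow(calls) > 0 &&
        any(calls$five_prime == donor_gene &
              calls$donor_label == donor_label &
              calls$spliced_in_exon == spliced, na.rm = TRUE)
      if (already) next
      dg <- genes[[donor_gene]]
      is_cryptic <- is.null(dg) ||
        !donor_label %in% dg$exons$label
      if (is_cryptic) {
        ce <- resolve_exon(genes, row$donor)
        frame <- if (cassette_insertion_frame(ce$end - ce$start + 1L)$in_frame)
          "in_frame" else "out_of_frame"
        contribution <- "coding"
        status <- "cryptic_insertion"
      } else {
        cds <- partner_cds_length(dg, donor_label)
        frame <- frame_status(cds, acceptor_phase(g3, spliced))
        contribution <- if (identical(cds, "utr_only")) "utr_only" else
          "coding"
        status <- "rna_junction"
      }
      iso <- enumerate_fusion_isoforms(row$donor, g3,
                                       spliced_in_exon = spliced)
      flags <- domain_retention(iso[[length(iso)]], g3)
      calls <- dplyr::bind_rows(calls, tibble::tibble(
        case_id = record$case_id, junction_id = NA_character_,
        five_prime = donor_gene, three_prime = g3$name,
        donor_label = donor_label,
        spliced_in_exon = spliced, status = status, frame_status = frame,
        partner_contribution = contribution,
        ig_like = flags[["ig_like"]], egf_like = flags[["egf_like"]],
        transmembrane = flags[["transmembrane"]],
        cytoplasmic_tail = flags[["cytoplasmic_tail"]],
        beta3_terminus = flags[["beta3_terminus"]],
        rna_split_reads = as.integer(row$n)))
    }
  }
  record$calls <- calls
  record
}

# RNA split reads supporting a DNA candidate: reads at the 3' gene's
# spliced-in acceptor whose donor matches the candidate's donor exon, or any
# novel donor for novel-partner candidates.
rna_support_for <- function(summary, three_prime_gene, cand, donor_label) {
  if (is.null(summary) || nrow(summary) == 0) return(0L)
  if (is.na(cand$spliced_in_exon)) return(0L)
  acc <- paste0(three_prime_gene$name, ":", cand$spliced_in_exon)
  rows <- summary[summary$acceptor == acc, ]
  if (nrow(rows) == 0) return(0L)
  if (cand$status == "novel_partner") {
    return(as.integer(sum(rows$n[startsWith(rows$donor, "novel(")])))
  }
  if (is.null(donor_label)) return(0L)
  want <- paste0(cand$five_prime, ":", donor_label)
  as.integer(sum(rows$n[rows$donor == want]))
}
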