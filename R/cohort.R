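# Cohort fixture and per-case record constructor. The fixture mirrors the
# summary counts of a 571-case breast-cancer cohort with whole-genome DNA
# sequencing of the first 250 cases: four RNA-supported fusions across the
# cohort (two within the DNA-sequenced subset), and among the first 250 a
# further 20 cases with breakpoints in the gene but no fusion transcript,
# 13 of them with multiple breakpoints.

#' Construct a per-case rearrangement record
#'
#' @param case_id case identifier.
#' @param n_breakpoints breakends within the gene of interest.
#' @param calls NULL or a fusion-call tibble (see [annotate_fusion()]).
#' @param in_dna_subset was the case in the DNA-sequenced subset.
#' @return a case_record.
#' @export
new_case_record <- function(case_id, n_breakpoints = 0L, calls = NULL,
                            in_dna_subset = TRUE) {
  structure(list(case_id = case_id,
                 junctions = NULL,
                 n_breakpoints = as.integer(n_breakpoints),
                 multi_breakpoint = n_breakpoints >= 2L,
                 calls = calls, in_dna_subset = in_dna_subset),
            class = "case_record")
}

fixture_call <- function(case_id, five_prime, frame, contribution,
                         spliced_in = 3L, egf = TRUE, rna = 1L,
                         status = "candidate") {
  tibble::tibble(
    case_id = case_id, junction_id = paste0(case_id, "_j1"),
    five_prime = five_prime, three_prime = "NRG",
    spliced_in_exon = as.integer(spliced_in), status = status,
    frame_status = frame, partner_contribution = contribution,
    ig_like = TRUE, egf_like = egf, transmembrane = TRUE,
    cytoplasmic_tail = TRUE, beta3_terminus = FALSE,
    rna_split_reads = as.integer(rna))
}

#' Build the synthetic cohort
#'
#' 571 cases: case_014 (in-frame fusion, 5 split reads) and case_101
#' (out-of-frame fusion, 2 split reads) within the first 250; case_317
#' (out-of-frame, 1 split read) and case_402 (novel partner exon, 3' side in
#' frame, 2 split reads) beyond it; 20 breakpoint-only cases among the first
#' 250 (13 multi-breakpoint, with 2-7 breakpoints; 7 single-breakpoint);
#' everything else clean. Deterministic.
#'
#' @param n_total cohort size (default 571).
#' @param n_dna_subset DNA-sequenced subset size (default 250).
#' @return list of case_records of length `n_total`.
#' @export
build_cohort_fixture <- function(n_total = 571L, n_dna_subset = 250L) {
  ids <- sprintf("case_%03d", seq_len(n_total))
  records <- lapply(seq_len(n_total), function(i)
    new_case_record(ids[i], 0L, NULL, in_dna_subset = i <= n_dna_subset))

  set_case <- function(records, i, n_bk, calls) {
    records[[i]] <- new_case_record(ids[i], n_bk, calls,
                                    in_dna_subset = i <= n_dna_subset)
    records
  }
  # RNA-supported fusions (fusion-positive regardless of frame)
  records <- set_case(records, 14L, 1L,
    fixture_call(ids[14], "FAM91A1L", "in_frame", "coding", rna = 5L))
  records <- set_case(records, 101L, 1L,
    fixture_call(ids[101], "WRNL", "out_of_frame", "coding", rna = 2L))
  records <- set_case(records, 317L, 1L,
    fixture_call(ids[317], "ARHGEF39L", "out_of_frame", "coding", rna = 1L))
  records <- set_case(records, 402L, 3L,
    fixture_call(ids[402], "novel", "unknown_partner_exon", "unknown",
                 rna = 2L, status = "novel_partner"))

  # breakpoint-only cases in the DNA subset: 13 multi, 7 single
  bk_idx <- setdiff(seq(5L, 245L, by = 12L), c(14L, 101L))[1:20]
  multi_counts <- c(2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 6L, 6L, 7L, 7L, 2L)
  for (j in seq_along(bk_idx)) {
    n_bk <- if (j <= 13L) multi_counts[j] else 1L
    records <- set_case(records, bk_idx[j], n_bk, NULL)
  }
  records
}
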