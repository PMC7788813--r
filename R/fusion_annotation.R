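# Fusion annotation: reading-frame status, domain retention from exon role
# tags, the activating / likely-inactivating / indeterminate classification
# of per-case rearrangement records, and cohort summaries.
#
# Frame convention: the phase of a coding exon is the number of bases at its
# start completing the codon begun upstream, i.e. cumulative upstream CDS
# length mod 3. A fusion junction into an acceptor exon of phase p is in
# frame iff the 5' partner contributes L coding bases with L mod 3 == p.

#' Reading-frame status of a fusion junction
#'
#' @param partner_cds_len coding bases contributed by the 5' partner up to
#'   the junction donor; or the string "utr_only" when the partner contributes
#'   only untranslated sequence (translation then initiates at the 3' gene's
#'   own start codon, so the fusion is in frame by construction); or
#'   NA/"unknown" for an undocumented partner exon.
#' @param acceptor_phase phase (0/1/2) of the 3' gene's spliced-in exon.
#' @return one of "in_frame", "out_of_frame", "unknown_partner_exon".
#' @export
frame_status <- function(partner_cds_len, acceptor_phase) {
  if (!acceptor_phase %in% 0:2) stop("acceptor_phase must be 0, 1 or 2")
  if (is.character(partner_cds_len)) {
    if (partner_cds_len == "utr_only") return("in_frame")
    if (partner_cds_len == "unknown") return("unknown_partner_exon")
    stop("partner_cds_len must be a length, 'utr_only' or 'unknown'")
  }
  if (is.na(partner_cds_len)) return("unknown_partner_exon")
  if (partner_cds_len < 0) stop("negative partner CDS length")
  if (partner_cds_len %% 3 == acceptor_phase) "in_frame" else "out_of_frame"
}

#' Frame arithmetic of an inserted cassette exon
#'
#' An exon of length l inserted at a junction preserves the downstream
#' reading frame iff l mod 3 == 0, adding l/3 residues — e.g. the 78-nt
#' cryptic exon inserted in some fusion transcripts adds 26 amino acids in
#' frame.
#'
#' @param length_nt cassette exon length in nucleotides.
#' @return list(in_frame, residues) — residues NA when out of frame.
#' @export
cassette_insertion_frame <- function(length_nt) {
  if (length_nt < 0) stop("negative cassette length")
  in_frame <- (length_nt %% 3) == 0
  list(in_frame = in_frame,
       residues = if (in_frame) length_nt %/% 3 else NA_integer_)
}

#' Coding contribution of a 5' partner up to a donor exon
#'
#' Sums coding exon lengths of the partner gene in transcript order through
#' the donor exon. If no coding exon precedes or includes the donor, the
#' partner contributes only untranslated sequence ("utr_only").
#'
#' @param gene gene_model of the 5' partner.
#' @param donor_label label of the partner's donor exon at the junction.
#' @return integer CDS length, or "utr_only".
#' @export
partner_cds_length <- function(gene, donor_label) {
  ex <- gene$exons
  idx <- match(as.character(donor_label), ex$label)
  if (is.na(idx)) stop("donor exon '", donor_label, "' not in gene ",
                       gene$name)
  upto <- ex[seq_len(idx), ]
  coding <- upto[upto$coding, ]
  if (nrow(coding) == 0) return("utr_only")
  sum(coding$end - coding$start + 1L)
}

#' Phase of an acceptor exon
#'
#' @param gene gene_model of the 3' gene.
#' @param exon_number spliced-in exon number.
#' @return integer phase 0/1/2.
#' @export
acceptor_phase <- function(gene, exon_number) {
  row <- gene$exons[gene$exons$number %in% exon_number, ]
  if (nrow(row) != 1) stop("exon ", exon_number, " not found in ", gene$name)
  if (!isTRUE(row$coding)) stop("exon ", exon_number, " is non-coding")
  row$phase
}

#' Domain retention flags of a fusion isoform
#'
#' Flags are set by presence of role-tagged exons of the 3' gene in the
#' isoform: Ig-like, EGF-like (the receptor-binding exon), transmembrane,
#' cytoplasmic tail, and the beta3 terminus (the extended terminal exon,
#' mutually exclusive with transmembrane/tail).
#'
#' @param isoform character vector of qualified exon ids ("GENE:label").
#' @param three_prime_gene gene_model providing the role tags.
#' @return named logical vector: ig_like, egf_like, transmembrane,
#'   cytoplasmic_tail, beta3_terminus.
#' @export
domain_retention <- function(isoform, three_prime_gene) {
  g <- three_prime_gene
  own <- isoform[startsWith(isoform, paste0(g$name, ":"))]
  labels <- sub("^[^:]+:", "", own)
  beta3 <- any(grepl("ext$", labels))
  tag_hit <- function(tag) {
    rows <- g$exons[g$exons$label %in% labels, ]
    any(vapply(rows$tags, function(t) tag %in% t, logical(1)))
  }
  flags <- c(ig_like = tag_hit("Ig_like"),
             egf_like = tag_hit("EGF_like"),
             transmembrane = !beta3 && tag_hit("transmembrane"),
             cytoplasmic_tail = !beta3 && tag_hit("cytoplasmic_tail"),
             beta3_terminus = beta3)
  if (flags[["beta3_terminus"]] &&
      (flags[["transmembrane"]] || flags[["cytoplasmic_tail"]]))
    stop("beta3 terminus and transmembrane/tail are mutually exclusive")
  flags
}

#' Build an annotated fusion call from a DNA candidate
#'
#' Joins a predicted genomic fusion candidate with the gene models and RNA
#' split-read support into a fusion-call row: frame status (from the
#' partner's coding contribution and the acceptor phase), partner
#' contribution class, domain flags of the representative full-tail isoform,
#' and EGF-domain retention.
#'
#' @param candidate one-row candidate tibble from
#'   [predict_fusion_from_junction()].
#' @param five_prime_gene gene_model of the 5' partner (NULL for novel
#'   partners or 5'-end-only candidates).
#' @param three_prime_gene gene_model of the 3' gene.
#' @param donor_label donor exon label of the 5' partner at the junction
#'   (ignored for novel partners).
#' @param rna_split_reads RNA split reads supporting the junction.
#' @param case_id case identifier.
#' @return one-row fusion-call tibble.
#' @export
annotate_fusion <- function(candidate, five_prime_gene, three_prime_gene,
                            donor_label = NULL, rna_split_reads = 0L,
                            case_id = NA_character_) {
  g3 <- three_prime_gene
  status <- candidate$status
  spliced <- candidate$spliced_in_exon
  if (status == "five_prime_end_only") {
    frame <- NA_character_
    contribution <- NA_character_
    flags <- c(ig_like = FALSE, egf_like = FALSE, transmembrane = FALSE,
               cytoplasmic_tail = FALSE, beta3_terminus = FALSE)
  } else {
    cds <- if (status == "novel_partner" || is.null(five_prime_gene))
      "unknown" else partner_cds_length(five_prime_gene, donor_label)
    frame <- frame_status(cds, acceptor_phase(g3, spliced))
    contribution <- if (identical(cds, "utr_only")) "utr_only"
      else if (identical(cds, "unknown")) "unknown" else "coding"
    iso <- enumerate_fusion_isoforms(
      paste0(candidate$five_prime, ":", donor_label %||% "?"),
      g3, include_cryptic = FALSE, spliced_in_exon = spliced)
    full_tail <- iso[[length(iso)]]
    flags <- domain_retention(full_tail, g3)
  }
  tibble::tibble(
    case_id = case_id, junction_id = candidate$junction_id,
    five_prime = candidate$five_prime, three_prime = candidate$three_prime,
    donor_label = if (is.null(donor_label)) NA_character_ else
      as.character(donor_label),
    spliced_in_exon = spliced, status = status, frame_status = frame,
    partner_contribution = contribution,
    ig_like = flags[["ig_like"]], egf_like = flags[["egf_like"]],
    transmembrane = flags[["transmembrane"]],
    cytoplasmic_tail = flags[["cytoplasmic_tail"]],
    beta3_terminus = flags[["beta3_terminus"]],
    rna_split_reads = as.integer(rna_split_reads))
}

#' Classify a per-case rearrangement record
#'
#' Activation classes:
#' * `activating` — some candidate is in frame (including a UTR-only
#'   partner), retains the EGF-like receptor-binding domain, and has RNA
#'   split-read support of at least `min_rna_support`.
#' * `indeterminate` — a candidate has an unknown partner exon with the
#'   3'-side in frame (reported with subclass
#'   "possible_activating_partner_frame_unknown" unless
#'   `promote_unknown_partner` is set), or the case is multi-breakpoint
#'   without RNA support, or an otherwise clean DNA candidate lacks RNA
#'   confirmation.
#' * `likely_inactivating` — every candidate is out of frame, retains only
#'   the gene's 5' end, loses the EGF-like domain, or splices in at/after the
#'   transmembrane exon; or a single-breakpoint case produces no fusion
#'   candidate at all.
#'
#' The cytoplasmic tail never enters the classification: tail loss is
#' reported per isoform but is not treated as the oncogenic mechanism.
#'
#' @param record case_record from [breakpoints_in_gene()], with `calls`
#'   filled by [annotate_fusion()] (possibly a zero-row tibble).
#' @param three_prime_gene gene_model of the 3' gene (for the EGF and
#'   transmembrane exon numbers).
#' @param min_rna_support split reads needed to confirm a candidate
#'   (default 1).
#' @param promote_unknown_partner treat in-frame-3'-side unknown-partner
#'   candidates with RNA support as activating (default FALSE).
#' @return the record with `outcome_class` (and `outcome_subclass`) set.
#' @export
classify_rearrangement <- function(record, three_prime_gene,
                                   min_rna_support = 1L,
                                   promote_unknown_partner = FALSE) {
  calls <- record$calls
  if (is.null(calls)) calls <- tibble::tibble()
  g3 <- three_prime_gene
  tm <- tm_exon_number(g3)
  subclass <- NA_character_

  if (nrow(calls) == 0) {
    cls <- if (isTRUE(record$multi_breakpoint)) "indeterminate"
      else if (record$n_breakpoints >= 1) "likely_inactivating"
      else "indeterminate"
    if (cls == "indeterminate" && isTRUE(record$multi_breakpoint))
      subclass <- "complex_no_rna_support"
  } else {
    egf_ok <- calls$egf_like
    inactivating_type <-
      (!is.na(calls$frame_status) & calls$frame_status == "out_of_frame") |
      calls$status == "five_prime_end_only" |
      !egf_ok |
      (!is.na(calls$spliced_in_exon) & !is.na(tm) &
         calls$spliced_in_exon >= tm)
    activating_ok <- !is.na(calls$frame_status) &
      calls$frame_status == "in_frame" & egf_ok &
      calls$rna_split_reads >= min_rna_support & !inactivating_type
    unknown_partner <- !is.na(calls$frame_status) &
      calls$frame_status == "unknown_partner_exon" & egf_ok &
      !inactivating_type

    if (any(activating_ok)) {
      cls <- "activating"
    } else if (any(unknown_partner)) {
      has_rna <- any(calls$rna_split_reads[unknown_partner] >=
                       min_rna_support)
      if (promote_unknown_partner && has_rna) {
        cls <- "activating"
        subclass <- "promoted_unknown_partner"
      } else {
        cls <- "indeterminate"
        subclass <- "possible_activating_partner_frame_unknown"
      }
    } else if (all(inactivating_type)) {
      cls <- "likely_inactivating"
    } else {
      cls <- "indeterminate"
      subclass <- if (isTRUE(record$multi_breakpoint))
        "complex_no_rna_support" else "dna_candidate_without_rna"
    }
  }
  record$outcome_class <- cls
  record$outcome_subclass <- subclass
  record
}

tm_exon_number <- function(gene) {
  has <- vapply(gene$exons$tags, function(t) "transmembrane" %in% t,
                logical(1))
  if (!any(has)) return(NA_integer_)
  gene$exons$number[which(has)[1]]
}

#' Is a case fusion-positive?
#'
#' A case counts as fusion-positive when it carries a fusion call (any frame)
#' supported by at least one RNA split read — the survey definition under
#' which out-of-frame but RNA-confirmed fusions still count as detected
#' fusions.
#'
#' @param record a case_record.
#' @param min_rna_support minimum split reads (default 1).
#' @return logical.
#' @export
is_fusion_positive <- function(record, min_rna_support = 1L) {
  calls <- record$calls
  !is.null(calls) && nrow(calls) > 0 &&
    any(calls$status %in% c("candidate", "novel_partner") &
          calls$rna_split_reads >= min_rna_support)
}

#' Cohort summary
#'
#' Fusion frequency over the whole cohort and breakpoint-case frequency over
#' the DNA-sequenced subset. Fusion percent is reported to one decimal,
#' breakpoint percent to the nearest integer, both rounded half away from
#' zero. Breakpoint cases are cases in the DNA subset with >= 1 breakpoint in
#' the gene but no RNA-confirmed fusion ("a further N cases ...").
#'
#' @param cases list of classified case_records.
#' @param n_total total cohort size (default: number of records).
#' @param n_dna_subset size of the DNA-sequenced subset (default: records
#'   flagged `in_dna_subset`).
#' @return one-row tibble: n_cases, n_fusion_positive, fusion_percent,
#'   n_breakpoint_cases, breakpoint_percent, n_multi_breakpoint.
#' @export
cohort_summary <- function(cases, n_total = NULL, n_dna_subset = NULL) {
  n_total <- n_total %||% length(cases)
  fus <- vapply(cases, is_fusion_positive, logical(1))
  in_dna <- vapply(cases, function(r) isTRUE(r$in_dna_subset), logical(1))
  n_dna_subset <- n_dna_subset %||% sum(in_dna)
  bk <- in_dna & !fus &
    vapply(cases, function(r) r$n_breakpoints >= 1L, logical(1))
  multi <- bk & vapply(cases, function(r) isTRUE(r$multi_breakpoint),
                       logical(1))
  fusion_percent <- if (n_total > 0)
    round_half_up(100 * sum(fus) / n_total, 1) else 0
  breakpoint_percent <- if (n_dna_subset > 0)
    round_half_up(100 * sum(bk) / n_dna_subset) else 0
  tibble::tibble(
    n_cases = as.integer(n_total), n_fusion_positive = sum(fus),
    fusion_percent = fusion_percent,
    n_breakpoint_cases = sum(bk), breakpoint_percent = breakpoint_percent,
    n_multi_breakpoint = sum(multi))
}
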