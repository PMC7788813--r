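# Brute-force translation oracle: a fixed 3'-gene CDS (in frame 0, no stop
# codons); a fusion contributing L coding bases upstream of the acceptor
# exon starting at CDS offset c preserves the reading frame iff translating
# the concatenated sequence from the partner's start codon reproduces the
# 3' protein tail.
oracle_cds <- local({
  codons <- c("ATG", "GCT", "GAA", "CTG", "AAA", "TTC", "GGC", "CAT",
              "ACA", "GTC")
  paste(rep(codons, 5), collapse = "")  # 150 nt, 50 codons, no stops
})

translate_chr <- function(x) {
  x <- substr(x, 1, 3 * (nchar(x) %/% 3))
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

test_that("frame_status agrees with the translation oracle on all
          phase x length combinations", {
  set.seed(42)
  S <- oracle_cds
  for (phase in 0:2) {
    c_off <- phase + 9L  # CDS bases upstream of the acceptor exon
    acceptor_seq <- substr(S, c_off + 1, nchar(S))
    # protein tail from the first complete codon inside the acceptor exon
    tail_start <- 3L * ceiling(c_off / 3) + 1L
    tail_prot <- translate_chr(substr(S, tail_start, nchar(S)))
    for (L in 3:150) {
      partner <- paste0("ATG", paste(sample(c("A", "C", "G", "T"), L - 3,
                                            replace = TRUE), collapse = ""))
      fused_prot <- translate_chr(paste0(partner, acceptor_seq))
      oracle <- endsWith(fused_prot, tail_prot)
      expect_identical(frame_status(L, phase) == "in_frame", oracle,
                       label = sprintf("L=%d phase=%d", L, phase))
    }
  }
  expect_identical(frame_status(0, 0), "in_frame")
  expect_identical(frame_status(100, 0), "out_of_frame")  # 100 mod 3 = 1
})

test_that("UTR-only and unknown partners get the documented statuses", {
  expect_identical(frame_status("utr_only", 2), "in_frame")
  expect_identical(frame_status("unknown", 0), "unknown_partner_exon")
  expect_identical(frame_status(NA, 1), "unknown_partner_exon")
  expect_error(frame_status(-3, 0), "negative")
  expect_error(frame_status(3, 5))
})

test_that("cassette-exon insertion preserves frame iff length is 0 mod 3", {
  # the cryptic exon spans chr11:78,506,385-78,506,462 in the source locus
  res <- cassette_insertion_frame(78506462 - 78506385 + 1)
  expect_true(res$in_frame)
  expect_equal(res$residues, 26)
  for (l in 0:30) {
    r <- cassette_insertion_frame(l)
    expect_identical(r$in_frame, l %% 3 == 0)
    if (r$in_frame) expect_equal(r$residues, l / 3)
  }
})

test_that("partner coding contribution distinguishes UTR-only donors", {
  toy <- toy_fixture()
  expect_identical(partner_cds_length(toy$genes$PPX1, "1"), "utr_only")
  expect_equal(partner_cds_length(toy$genes$WRNL, "4"), 450L)
  expect_equal(partner_cds_length(toy$genes$TNM, "12"), 1230L)
  expect_equal(acceptor_phase(toy$genes$NRG, 3), 0L)
})

test_that("domain retention follows exon role tags", {
  nrg <- toy_fixture()$genes$NRG
  tail_iso <- paste0("NRG:", c(3:6, 9, 11, 12:18))
  f <- domain_retention(tail_iso, nrg)
  expect_true(f[["ig_like"]] && f[["egf_like"]] && f[["transmembrane"]] &&
                f[["cytoplasmic_tail"]])
  expect_false(f[["beta3_terminus"]])
  b3_iso <- c(paste0("NRG:", c(3:6, 9)), "NRG:11ext")
  f2 <- domain_retention(b3_iso, nrg)
  expect_true(f2[["beta3_terminus"]])
  expect_false(f2[["transmembrane"]] || f2[["cytoplasmic_tail"]])
  f3 <- domain_retention(character(0), nrg)
  expect_false(any(f3))
})

test_that("activation classes follow the interpretation rules", {
  nrg <- toy_fixture()$genes$NRG
  call <- function(frame, rna, spliced = 3L, status = "candidate",
                   egf = TRUE) {
    tibble::tibble(case_id = "c", junction_id = "j", five_prime = "X",
                   three_prime = "NRG", donor_label = "1",
                   spliced_in_exon = spliced, status = status,
                   frame_status = frame, partner_contribution = "coding",
                   ig_like = TRUE, egf_like = egf, transmembrane = TRUE,
                   cytoplasmic_tail = TRUE, beta3_terminus = FALSE,
                   rna_split_reads = as.integer(rna))
  }
  rec <- function(calls, n_bk = 1L) {
    r <- new_case_record("c", n_bk, calls)
    classify_rearrangement(r, nrg)
  }
  expect_identical(rec(call("in_frame", 2))$outcome_class, "activating")
  expect_identical(rec(call("out_of_frame", 2))$outcome_class,
                   "likely_inactivating")
  # splice-in at the transmembrane exon is inactivating even in frame
  expect_identical(rec(call("in_frame", 2, spliced = 12L,
                            egf = FALSE))$outcome_class,
                   "likely_inactivating")
  # unknown partner exon with the 3' side in frame: indeterminate subclass
  r_unk <- rec(call("unknown_partner_exon", 2, status = "novel_partner"))
  expect_identical(r_unk$outcome_class, "indeterminate")
  expect_identical(r_unk$outcome_subclass,
                   "possible_activating_partner_frame_unknown")
  expect_identical(classify_rearrangement(
    new_case_record("c", 1L, call("unknown_partner_exon", 2,
                                  status = "novel_partner")),
    nrg, promote_unknown_partner = TRUE)$outcome_class, "activating")
  # multi-breakpoint case without RNA support is indeterminate
  expect_identical(rec(NULL, n_bk = 7L)$outcome_class, "indeterminate")
  # a clean in-frame DNA candidate without RNA support stays unconfirmed
  expect_identical(rec(call("in_frame", 0))$outcome_class, "indeterminate")
})

test_that("the three classes partition classified records", {
  nrg <- toy_fixture()$genes$NRG
  cases <- build_cohort_fixture()
  classes <- vapply(cases[c(14, 101, 317, 402, 5, 17, 29)], function(r)
    classify_rearrangement(r, nrg)$outcome_class, "")
  expect_true(all(classes %in% c("activating", "likely_inactivating",
                                 "indeterminate")))
  expect_identical(unname(classes[1]), "activating")        # in frame + RNA
  expect_identical(unname(classes[2]), "likely_inactivating")  # out of frame
})

test_that("cohort summary reproduces the printed frequencies", {
  cases <- build_cohort_fixture()
  s <- cohort_summary(cases, n_total = 571, n_dna_subset = 250)
  expect_equal(s$n_fusion_positive, 4)
  expect_equal(s$fusion_percent, 0.7)
  expect_equal(s$n_breakpoint_cases, 20)
  expect_equal(s$breakpoint_percent, 8)
  expect_equal(s$n_multi_breakpoint, 13)
  expect_lte(s$n_multi_breakpoint, s$n_breakpoint_cases)
  # empty cohort: zeros, no division error
  s0 <- cohort_summary(list(), n_total = 0, n_dna_subset = 0)
  expect_equal(s0$fusion_percent, 0)
  expect_equal(s0$breakpoint_percent, 0)
})
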