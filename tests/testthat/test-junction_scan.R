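test_that("a junction-spanning read yields one classified acceptor hit", {
  toy <- toy_fixture()
  idx <- anchor_index_fixture()
  donor_anchor <- idx[idx$gene == "TNM" & idx$label == "12" &
                        idx$side == "donor", ]
  acc_anchor <- idx[idx$gene == "NRG" & idx$label == "3" &
                      idx$side == "acceptor", ]
  # 30 bp of TNM exon-12 donor flank followed by the 20-bp NRG exon-3
  # acceptor anchor
  ex12 <- exon_sequence(toy$genome,
                        toy$genes$TNM$exons[toy$genes$TNM$exons$label == "12", ])
  flank <- substr(ex12, nchar(ex12) - 29, nchar(ex12))
  read <- paste0(flank, acc_anchor$sequence)
  reads <- tibble::tibble(read_id = "r1", seq = read)
  hits <- scan_reads(reads, idx)
  acc_hits <- hits[hits$side == "acceptor", ]
  expect_equal(nrow(acc_hits), 1)
  expect_identical(acc_hits$flank_sequence, flank)
  calls <- classify_flanks(hits, idx)
  call <- calls[calls$side == "acceptor", ]
  expect_identical(call$acceptor, "NRG:3")
  expect_identical(call$donor, "TNM:12")

  # the same read reverse-complemented gives the identical junction call
  rc_reads <- tibble::tibble(read_id = "r1rc", seq = rc_oracle(read))
  rc_calls <- classify_flanks(scan_reads(rc_reads, idx), idx)
  rc_call <- rc_calls[rc_calls$side == "acceptor", ]
  expect_identical(rc_call$read_strand, "revcomp")
  expect_identical(rc_call[c("acceptor", "donor")],
                   call[c("acceptor", "donor")])

  # a read with no anchor substring yields no hits
  none <- scan_reads(tibble::tibble(read_id = "x", seq = strrep("ACGT", 19)),
                     idx)
  expect_equal(nrow(none), 0)
})

test_that("short flanks are too_short and unknown flanks are novel", {
  toy <- toy_fixture()
  idx <- anchor_index_fixture()
  acc <- idx[idx$gene == "NRG" & idx$label == "3" & idx$side == "acceptor", ]
  set.seed(5)
  junk <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                collapse = "")
  reads <- tibble::tibble(
    read_id = c("short", "novel"),
    seq = c(paste0("ACGTGA", acc$sequence),            # 6-bp flank
            paste0(junk, acc$sequence)))               # unmodelled flank
  calls <- classify_flanks(scan_reads(reads, idx), idx, min_flank = 12)
  calls <- calls[calls$side == "acceptor", ]
  expect_identical(calls$category[calls$read_id == "short"], "too_short")
  novel <- calls[calls$read_id == "novel", ]
  expect_identical(novel$category, "novel")
  expect_identical(novel$donor, paste0("novel(", junk, ")"))
})

test_that("anchor collisions at the chosen k are an error", {
  # two exons sharing their terminal 20-mer
  seqA <- paste0(strrep("AC", 30), "GATTACAGATTACAGATTAC")
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste0(strrep("T", 50), seqA, strrep("G", 50), seqA,
                  strrep("T", 50))))
  g <- gene_model("G1", "+",
                  exon_table("G1", c("1", "2"), 1:2, "chr1",
                             c(51L, 181L), c(130L, 260L), "+", TRUE))
  expect_error(build_anchor_index(list(g), genome, k = 20), "collision")
})

test_that("single-mismatch mode recovers mutated anchors; exact mode does not", {
  toy <- toy_fixture()
  idx <- anchor_index_fixture()
  acc <- idx[idx$gene == "NRG" & idx$label == "3" & idx$side == "acceptor", ]
  mut <- acc$sequence
  substr(mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 10, 10))[1]
  ex12 <- exon_sequence(toy$genome,
                        toy$genes$TNM$exons[toy$genes$TNM$exons$label == "12", ])
  read <- paste0(substr(ex12, nchar(ex12) - 19, nchar(ex12)), mut)
  reads <- tibble::tibble(read_id = "m", seq = read)
  expect_equal(nrow(scan_reads(reads, idx, max_mismatches = 0)[
    scan_reads(reads, idx, max_mismatches = 0)$side == "acceptor", ]), 0)
  hits1 <- scan_reads(reads, idx, max_mismatches = 1)
  expect_true(any(hits1$side == "acceptor" & hits1$gene == "NRG" &
                    hits1$label == "3"))
})

test_that("planted junction compositions are recovered exactly", {
  scan <- mda175_scan_fixture()$scan
  s <- scan$summary
  nrg3 <- s[s$acceptor == "NRG:3", ]
  expect_equal(nrg3$n[nrg3$donor == "TNM:int15"], 38)
  expect_equal(nrg3$n[nrg3$donor == "TNM:12"], 122)
  expect_equal(nrg3$percent[nrg3$donor == "TNM:int15"], 24)
  tnm3 <- s[s$acceptor == "TNM:3", ]
  expect_equal(tnm3$n[tnm3$donor == "TNM:2"], 1)
  expect_equal(sum(tnm3$n), 145)
})

test_that("junction summaries are invariant to reverse-complementing reads", {
  fx <- mda175_scan_fixture()
  idx <- anchor_index_fixture()
  flipped <- tibble::tibble(read_id = fx$reads$read_id,
                            seq = rc_oracle(fx$reads$seq))
  s2 <- scan_junctions(flipped, idx)$summary
  expect_equal(as.data.frame(s2), as.data.frame(fx$scan$summary))
})

test_that("reads from normal transcripts give no cross-gene junctions", {
  toy <- toy_fixture()
  idx <- anchor_index_fixture()
  normals <- tibble::tibble(
    name = c("nrg_norm", "tnm_norm"),
    isoform = list(paste0("NRG:", c(2:6, 9, 11:18)), paste0("TNM:", 1:16)),
    exonA = NA_character_, exonB = NA_character_,
    count = c(120L, 120L))
  reads <- simulate_rna_reads(toy$genome, toy$genes, normals, seed = 21)
  calls <- scan_junctions(reads, idx)$calls
  classified <- calls[calls$side == "acceptor" & calls$category == "known", ]
  acc_gene <- sub(":.*", "", classified$acceptor)
  don_gene <- sub(":.*", "", classified$donor)
  expect_true(all(acc_gene == don_gene))
})

test_that("per-acceptor percentages sum to 100 within rounding", {
  s <- mda175_scan_fixture()$scan$summary
  sums <- tapply(s$percent, s$acceptor, sum)
  expect_true(all(abs(sums - 100) <= 1))
})

test_that("duplicate collapsing changes counts only when reads repeat", {
  fx <- mda175_scan_fixture()
  dedup <- summarise_junctions(fx$scan$calls, dedup = TRUE)
  raw <- fx$scan$summary
  nrg3_raw <- sum(raw$n[raw$acceptor == "NRG:3"])
  nrg3_dd <- sum(dedup$n[dedup$acceptor == "NRG:3"])
  expect_lte(nrg3_dd, nrg3_raw)  # 160 reads over <= 36 distinct placements
  expect_gt(nrg3_dd, 0)
})
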