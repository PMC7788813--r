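# Hand-decoded expectations for the four VCF 4.2 bracket cases: for a record
# at (c1, p1) with ALT t[p[ the local breakend retains the left of p1 and the
# mate the right of p2; t]p] -> left/left; ]p]t -> right/left; [p[t ->
# right/right.
bracket_cases <- tibble::tibble(
  alt1 = c("N[chrB:500[", "N]chrB:500]", "]chrB:500]N", "[chrB:500[N"),
  sideA = c("left", "left", "right", "right"),
  sideB = c("right", "left", "left", "right"))

write_test_vcf <- function(records) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chrA,length=10000>",
           "##contig=<ID=chrB,length=10000>",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"m\">",
           "##FORMAT=<ID=SR,Number=1,Type=Integer,Description=\"s\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "TUMOUR", "NORMAL", sep = "\t"))
  writeLines(c(hdr, records), path)
  path
}

mate_alt <- function(alt1) {
  # mirror of bracket_cases rows for the mate record at chrB:500 -> chrA:100
  c("N[chrB:500[" = "]chrA:100]N", "N]chrB:500]" = "N]chrA:100]",
    "]chrB:500]N" = "N[chrA:100[", "[chrB:500[N" = "[chrA:100[N")[[alt1]]
}

test_that("all four breakend bracket orientations decode correctly", {
  for (i in seq_len(nrow(bracket_cases))) {
    b <- bracket_cases[i, ]
    recs <- c(
      paste("chrA", 100, "j_1", "N", b$alt1, ".", "PASS",
            "SVTYPE=BND;MATEID=j_2", "SR", 12, 0, sep = "\t"),
      paste("chrB", 500, "j_2", "N", mate_alt(b$alt1), ".", "PASS",
            "SVTYPE=BND;MATEID=j_1", "SR", 12, 0, sep = "\t"))
    jn <- parse_breakend_vcf(write_test_vcf(recs))
    expect_equal(nrow(jn), 1)
    expect_identical(jn$sideA, b$sideA)
    expect_identical(jn$sideB, b$sideB)
    expect_equal(jn$tumour_support, 12L)
    expect_equal(jn$normal_support, 0L)
  }
})

test_that("non-BND records are skipped and unpaired mates are an error", {
  recs <- paste("chrA", 100, "snv1", "A", "T", ".", "PASS", "SVTYPE=BND",
                "SR", 3, 0, sep = "\t")
  expect_message(jn <- parse_breakend_vcf(write_test_vcf(recs)), "ignored")
  expect_equal(nrow(jn), 0)
  recs2 <- paste("chrA", 100, "j_1", "N", "N[chrB:500[", ".", "PASS",
                 "SVTYPE=BND;MATEID=j_2", "SR", 3, 0, sep = "\t")
  expect_error(parse_breakend_vcf(write_test_vcf(recs2)), "missing")
})

test_that("junction tables round-trip through breakend VCF emission", {
  toy <- toy_fixture()
  truth <- rearrangement_preset("mda175", toy)$junctions
  truth$tumour_support <- 9L
  path <- tempfile(fileext = ".vcf")
  write_breakend_vcf(truth, path, toy$contigs)
  back <- parse_breakend_vcf(path)
  cols <- c("chromA", "posA", "sideA", "chromB", "posB", "sideB",
            "tumour_support", "normal_support")
  expect_equal(as.data.frame(canonical_junctions(back)[cols]),
               as.data.frame(canonical_junctions(truth)[cols]),
               ignore_attr = TRUE)
  # and re-emitting the parsed junctions reproduces the same set
  path2 <- tempfile(fileext = ".vcf")
  write_breakend_vcf(back, path2, toy$contigs)
  back2 <- parse_breakend_vcf(path2)
  expect_equal(as.data.frame(canonical_junctions(back2)[cols]),
               as.data.frame(canonical_junctions(back)[cols]),
               ignore_attr = TRUE)
})

make_jn <- function(id, chromA, posA, sideA, chromB, posB, sideB,
                    tum = 10L, norm = 0L) {
  tibble::tibble(id = id, chromA = chromA, posA = as.integer(posA),
                 sideA = sideA, chromB = chromB, posB = as.integer(posB),
                 sideB = sideB, inserted_sequence = "",
                 tumour_support = as.integer(tum),
                 normal_support = as.integer(norm))
}

test_that("somatic filters drop normal-supported, panel and decoy junctions", {
  jn <- dplyr::bind_rows(
    make_jn("som", "chrA", 1000, "left", "chrB", 2000, "right"),
    make_jn("germ", "chrA", 3000, "left", "chrB", 4000, "right", norm = 1L),
    make_jn("mito", "chrM", 100, "left", "chrA", 5000, "right"),
    make_jn("inpanel", "chrA", 7000, "left", "chrB", 8000, "right"))
  panel <- make_jn("p1", "chrA", 7005, "left", "chrB", 7995, "right")
  kept <- filter_somatic(jn, panel = panel,
                         allowed_chroms = c("chrA", "chrB"))
  expect_identical(kept$id, "som")
  # matching requires the same orientation
  panel_flip <- make_jn("p1", "chrA", 7005, "right", "chrB", 7995, "right")
  kept2 <- filter_somatic(jn, panel = panel_flip,
                          allowed_chroms = c("chrA", "chrB"))
  expect_setequal(kept2$id, c("som", "inpanel"))
  # beyond the +/-10 bp tolerance the junction is retained
  panel_far <- make_jn("p1", "chrA", 7020, "left", "chrB", 7995, "right")
  expect_true("inpanel" %in% filter_somatic(
    jn, panel = panel_far, allowed_chroms = c("chrA", "chrB"))$id)
})

test_that("somatic filtering is idempotent and returns a subset", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(1:12, 1)
    jn <- make_jn(paste0("j", seq_len(n)),
                  sample(c("chrA", "chrB", "chrM"), n, TRUE),
                  sample(1e4, n), sample(c("left", "right"), n, TRUE),
                  sample(c("chrA", "chrB"), n, TRUE),
                  sample(1e4, n), sample(c("left", "right"), n, TRUE),
                  tum = sample(0:20, n, TRUE), norm = sample(0:2, n, TRUE))
    once <- filter_somatic(jn, allowed_chroms = c("chrA", "chrB"))
    twice <- filter_somatic(once, allowed_chroms = c("chrA", "chrB"))
    expect_identical(once, twice)
    expect_true(all(once$id %in% jn$id))
  }
})

test_that("planted germline junctions are removed, somatic survive", {
  toy <- toy_fixture()
  truth <- rearrangement_preset("simple_del", toy)
  germ <- make_jn("g", "chrA", 150000, "left", "chrB", 170000, "right")
  path <- tempfile(fileext = ".vcf")
  written <- simulate_sv_vcf(truth$junctions, path, toy$contigs,
                             tumour_support = 8L, germline = germ,
                             decoy_chroms = "chrM")
  parsed <- parse_breakend_vcf(path)
  expect_equal(nrow(parsed), nrow(written))
  kept <- filter_somatic(parsed, allowed_chroms = names(toy$contigs))
  expect_setequal(kept$id, truth$junctions$id)
})

test_that("breakpoints within the gene are counted and flagged", {
  toy <- toy_fixture()
  nrg <- toy$genes$NRG
  # a 7-breakpoint case (4 junctions, 7 breakends inside the gene span)
  jn <- dplyr::bind_rows(
    make_jn("a", "chrB", 85000, "left", "chrB", 90000, "left"),
    make_jn("b", "chrB", 95000, "right", "chrB", 100000, "right"),
    make_jn("c", "chrB", 110000, "left", "chrB", 120000, "right"),
    make_jn("d", "chrB", 130000, "left", "chrA", 50000, "right"))
  rec <- breakpoints_in_gene(jn, nrg, case_id = "cl")
  expect_equal(rec$n_breakpoints, 7)
  expect_true(rec$multi_breakpoint)
  # none in span
  rec0 <- breakpoints_in_gene(make_jn("x", "chrB", 1000, "left",
                                      "chrA", 2000, "right"), nrg)
  expect_equal(rec0$n_breakpoints, 0)
  # exactly two breakends: boundary of the multi-breakpoint rule
  rec2 <- breakpoints_in_gene(make_jn("y", "chrB", 90000, "left",
                                      "chrB", 120000, "right"), nrg)
  expect_equal(rec2$n_breakpoints, 2)
  expect_true(rec2$multi_breakpoint)
})

test_that("exactly one of the four side combinations yields a sense fusion", {
  toy <- toy_fixture()
  genes <- toy$genes
  sides <- expand.grid(sA = c("left", "right"), sB = c("left", "right"),
                       stringsAsFactors = FALSE)
  hits <- 0
  for (i in seq_len(nrow(sides))) {
    jn <- make_jn("j", "chrB", 33000, sides$sA[i], "chrB", 88000,
                  sides$sB[i])
    res <- predict_fusion_from_junction(jn[1, ], list(genes$WRNL),
                                        genes$NRG)
    if (is_fusion_candidate(res) && res$status == "candidate") {
      hits <- hits + 1
      expect_identical(res$five_prime, "WRNL")
      expect_equal(res$spliced_in_exon, 3L)
      expect_identical(res$donor_label, "4")
    }
  }
  expect_equal(hits, 1)
})

test_that("a breakend retaining only the gene's 5' part is flagged", {
  toy <- toy_fixture()
  # breakend inside NRG downstream of the receptor-binding exon, left
  # retained: only the 5' end of the gene survives
  jn <- make_jn("j", "chrB", 133000, "left", "chrA", 10000, "right")
  res <- predict_fusion_from_junction(jn[1, ], list(toy$genes$WRNL),
                                      toy$genes$NRG)
  expect_identical(res$status, "five_prime_end_only")
})
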