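del_junction <- tibble::tibble(
  id = "D", chromA = "chr1", posA = 3000L, sideA = "left",
  chromB = "chr1", posB = 7000L, sideB = "right",
  inserted_sequence = "", tumour_support = 5L, normal_support = 0L)

empty_junctions_tbl <- function() del_junction[0, ]

test_that("a deletion junction gives 3 segments and a skipping adjacency", {
  g <- build_segment_graph(del_junction, c(chr1 = 10000L))
  expect_equal(nrow(g$segments), 3)
  v <- g$adjacencies[g$adjacencies$type == "variant", ]
  expect_equal(nrow(v), 1)
  expect_identical(c(v$seg1, v$seg2), c("chr1.1", "chr1.3"))
  expect_identical(c(v$end1, v$end2), c("R", "L"))
  # the derivative walk skips the middle segment
  walks <- enumerate_walks(g, list(seg = "chr1.1", orient = "+"),
                           list(seg = "chr1.3", orient = "+"),
                           max_length = 4)
  keys <- vapply(walks, function(m) paste(m$walk$seg_id, collapse = ">"), "")
  expect_true("chr1.1>chr1.3" %in% keys)
})

test_that("an inversion junction joins like ends and flips orientation", {
  inv <- del_junction
  inv$sideB <- "left"  # both retain left: inversion-type join
  g <- build_segment_graph(inv, c(chr1 = 10000L))
  v <- g$adjacencies[g$adjacencies$type == "variant", ]
  expect_identical(c(v$end1, v$end2), c("R", "R"))
  walks <- enumerate_walks(g, list(seg = g$segments$seg_id[1], orient = "+"),
                           list(seg = v$seg2, orient = NULL), max_length = 3)
  through <- Filter(function(m) nrow(m$walk) == 2 &&
                      m$walk$seg_id[2] == v$seg2, walks)
  expect_true(length(through) >= 1)
  expect_identical(through[[1]]$walk$orient[2], "-")
})

test_that("positions outside the chromosome extents are an error", {
  bad <- del_junction
  bad$posB <- 999999L
  expect_error(build_segment_graph(bad, c(chr1 = 10000L)), "outside")
})

test_that("segment count equals breakpoint count + 1 per chromosome", {
  set.seed(23)
  for (rep in 1:15) {
    n <- sample(1:10, 1)
    jn <- tibble::tibble(
      id = paste0("j", seq_len(n)),
      chromA = sample(c("c1", "c2"), n, TRUE),
      posA = sample(100:9900, n), sideA = sample(c("left", "right"), n, TRUE),
      chromB = sample(c("c1", "c2"), n, TRUE),
      posB = sample(100:9900, n), sideB = sample(c("left", "right"), n, TRUE),
      inserted_sequence = "", tumour_support = 1L, normal_support = 0L)
    g <- build_segment_graph(jn, c(c1 = 10000L, c2 = 10000L))
    ends <- rbind(data.frame(chrom = jn$chromA, pos = jn$posA, side = jn$sideA),
                  data.frame(chrom = jn$chromB, pos = jn$posB, side = jn$sideB))
    for (ch in c("c1", "c2")) {
      e <- ends[ends$chrom == ch, ]
      cuts <- unique(ifelse(e$side == "left", e$pos, e$pos - 1L))
      expect_equal(sum(g$segments$chrom == ch), length(cuts) + 1)
    }
    expect_equal(sum(g$adjacencies$type == "variant"), n)
  }
})

test_that("every enumerated walk passes the independent connectivity check", {
  toy <- toy_fixture()
  truth <- rearrangement_preset("mda175", toy)
  g <- build_segment_graph(truth$junctions, toy$contigs)
  walks <- enumerate_walks(g, list(seg = segment_at(g, "chrA", 10001),
                                   orient = "+"),
                           list(seg = segment_at(g, "chrB", 150000),
                                orient = "+"), max_length = 8)
  expect_gt(length(walks), 0)
  for (m in walks) expect_true(walk_is_connected(g, m$walk))
  # a graph with no variant adjacencies only yields the reference walk
  g0 <- build_segment_graph(empty_junctions_tbl(), c(chrX = 5000L))
  w0 <- enumerate_walks(g0, list(seg = "chrX.1", orient = "+"),
                        list(seg = "chrX.1", orient = NULL), 3)
  expect_length(w0, 1)
})

test_that("the derivative walk explains the observed fusion transcripts", {
  toy <- toy_fixture()
  truth <- rearrangement_preset("mda175", toy)
  g <- build_segment_graph(truth$junctions, toy$contigs)
  walks <- enumerate_walks(g, list(seg = segment_at(g, "chrA", 10001),
                                   orient = "+"),
                           list(seg = segment_at(g, "chrB", 150000),
                                orient = "+"), max_length = 8)
  genes <- toy$genes
  junctions <- list(c("PPX1:1", "TNM:3"), c("TNM:12", "TNM:int15"),
                    c("TNM:int15", "NRG:3"))
  ok <- vapply(walks, function(m)
    all(vapply(junctions, function(j)
      explain_transcript(m, g, genes, j), logical(1))), logical(1))
  expect_equal(sum(ok), 1)
  # a walk lacking the cryptic-exon fragment cannot explain the
  # int15 -> exon 3 junction
  no_frag <- structure(list(
    walk = tibble::tibble(seg_id = c(segment_at(g, "chrA", 10001),
                                     segment_at(g, "chrB", 150000)),
                          orient = c("+", "+"))), class = "derivative_model")
  expect_false(explain_transcript(no_frag, g, genes,
                                  c("TNM:int15", "NRG:3")))
  # an empty walk explains nothing
  empty_model <- structure(list(
    walk = tibble::tibble(seg_id = character(0), orient = character(0)),
    multiplicity = table(character(0))), class = "derivative_model")
  expect_false(explain_transcript(empty_model, g, genes,
                                  c("PPX1:1", "TNM:3")))
})

test_that("round trip: simulated derivative junctions recover an explaining
          walk", {
  toy <- toy_fixture()
  for (preset in c("mda175", "simple_del")) {
    truth <- rearrangement_preset(preset, toy)
    g <- build_segment_graph(truth$junctions, toy$contigs)
    start_chrom <- truth$walk$chrom[1]
    walks <- enumerate_walks(
      g, list(seg = segment_at(g, start_chrom, truth$walk$start[1] + 1),
              orient = "+"),
      list(seg = segment_at(g, "chrB", 150000), orient = "+"),
      max_length = 8)
    jn <- if (preset == "mda175") c("TNM:12", "TNM:int15") else
      c("WRNL:4", "NRG:3")
    expect_true(any(vapply(walks, function(m)
      explain_transcript(m, g, toy$genes, jn), logical(1))))
  }
})

test_that("the dup-with-inverted-insertion motif is recognised with spans", {
  toy <- toy_fixture()
  truth <- rearrangement_preset("dup_inv_insert", toy)
  motif <- detect_dup_with_inverted_insertion(truth$junctions,
                                              gene = toy$genes$NRG)
  expect_false(is.null(motif))
  expect_equal(motif$dup_span_bp, 57000)
  expect_equal(motif$insert_span_bp, 24000)
  expect_true(motif$dup_start <= toy$genes$NRG$exons$start[7] &&
                motif$dup_end >= toy$genes$NRG$exons$end[7])
  # a plain tandem duplication (single junction) is not the motif
  plain <- tibble::tibble(
    id = c("t", "x", "y"),
    chromA = "chrB", posA = c(152000L, 1000L, 2000L),
    sideA = c("left", "left", "left"),
    chromB = "chrB", posB = c(95001L, 5000L, 6000L),
    sideB = c("right", "right", "right"),
    inserted_sequence = "", tumour_support = 5L, normal_support = 0L)
  expect_null(detect_dup_with_inverted_insertion(plain))
  # flipping any single retained side destroys the signature
  for (col in c("sideA", "sideB")) for (row in 2:3) {
    flipped <- truth$junctions
    flipped[[col]][row] <- setdiff(c("left", "right"), flipped[[col]][row])
    expect_null(detect_dup_with_inverted_insertion(flipped),
                label = paste("flip", col, "row", row))
  }
})

test_that("walk multiplicities are checked softly against copy number", {
  toy <- toy_fixture()
  truth <- rearrangement_preset("dup_inv_insert", toy)
  g <- build_segment_graph(truth$junctions, toy$contigs)
  walks <- enumerate_walks(g, list(seg = segment_at(g, "chrB", 500),
                                   orient = "+"),
                           list(seg = segment_at(g, "chrB", 190000),
                                orient = "+"), max_length = 8)
  truth_key <- vapply(walks, function(m)
    any(m$multiplicity > 1), logical(1))
  m <- walks[[which(truth_key)[1]]]
  segs <- g$segments[g$segments$chrom == "chrB", ]
  ratios <- tibble::tibble(
    seg_id = segs$seg_id,
    ratio = vapply(segs$seg_id, function(s) {
      mult <- if (s %in% names(m$multiplicity))
        m$multiplicity[[s]] else 0L
      mult + 1L
    }, 1L))
  expect_equal(walk_cn_consistency(m, ratios), 1)
})
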