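# Synthetic data, part 2: derivative chromosomes. A rearrangement is
# specified as a walk of oriented reference segments; the derivative sequence
# is the concatenation of the (possibly reverse-complemented) segments, and
# the truth junction table is derived from each non-reference adjacency of
# consecutive segments, with retained sides following the breakend
# convention (left/right of the breakend position).

#' Assemble a derivative chromosome from a segment walk
#'
#' @param genome DNAStringSet.
#' @param walk tibble(chrom, start, end, orient) of oriented reference
#'   segments, 5'->3' along the derivative.
#' @param name derivative sequence name.
#' @return list(derivative = DNAStringSet(name), junctions = truth junction
#'   tibble with ids "A", "B", ... and zero support columns, walk = walk).
#' @export
apply_rearrangement <- function(genome, walk, name = "der1") {
  seqs <- vapply(seq_len(nrow(walk)), function(i) {
    s <- as.character(Biostrings::subseq(genome[[walk$chrom[i]]],
                                         walk$start[i], walk$end[i]))
    if (walk$orient[i] == "-") revcomp(s) else s
  }, "")
  der <- Biostrings::DNAStringSet(stats::setNames(
    paste(seqs, collapse = ""), name))
  jn <- list()
  for (i in seq_len(nrow(walk) - 1L)) {
    a <- walk[i, ]; b <- walk[i + 1L, ]
    # reference adjacency -> no junction
    if (a$chrom == b$chrom && a$orient == "+" && b$orient == "+" &&
        b$start == a$end + 1L) next
    if (a$chrom == b$chrom && a$orient == "-" && b$orient == "-" &&
        a$start == b$end + 1L) next
    endA <- if (a$orient == "+") list(pos = a$end, side = "left")
            else list(pos = a$start, side = "right")
    endB <- if (b$orient == "+") list(pos = b$start, side = "right")
            else list(pos = b$end, side = "left")
    jn[[length(jn) + 1]] <- tibble::tibble(
      id = LETTERS[length(jn) + 1L],
      chromA = a$chrom, posA = endA$pos, sideA = endA$side,
      chromB = b$chrom, posB = endB$pos, sideB = endB$side,
      inserted_sequence = "", tumour_support = 0L, normal_support = 0L)
  }
  junctions <- if (length(jn)) dplyr::bind_rows(jn) else empty_junctions()
  list(derivative = der, junctions = junctions, walk = walk)
}

#' Rearrangement presets
#'
#' Named derivative-chromosome scenarios over the toy genome:
#' * `mda175` — the double-fusion derivative: the PPX1 region joined by a
#'   large inversion to the (minus-strand) TNM body so that TNM exons 3-12
#'   read in the derivative's forward direction, then an inverted intron-15
#'   fragment carrying the cryptic int15 exon, then a translocated chrB
#'   block starting upstream of NRG exon 3.
#' * `simple_del` — a WRNL->NRG deletion fusion splicing into exon 3
#'   (in frame; the activating pattern).
#' * `dup_inv_insert` — a novel-partner fusion into exon 3 plus a 57-kb
#'   tandem duplication within NRG carrying a 24-kb inverted insertion at
#'   the duplication junction.
#' * `inactivating` — a WRNL->NRG junction splicing in at the transmembrane
#'   exon (exon 12): an EGF-domain-losing, likely inactivating pattern.
#' * `complex_multi` — two incoherently oriented intragenic junctions in
#'   NRG, no expressible fusion.
#'
#' @param name preset name.
#' @param toy toy genome list from [make_toy_genome()].
#' @return list(derivative, junctions, walk, expected_class).
#' @export
rearrangement_preset <- function(name = c("mda175", "simple_del",
                                          "dup_inv_insert", "inactivating",
                                          "complex_multi"),
                                 toy) {
  name <- match.arg(name)
  walk <- switch(name,
    mda175 = tibble::tibble(
      chrom = c("chrA", "chrA", "chrA", "chrB"),
      start = c(1L, 67000L, 52500L, 88000L),
      end = c(20000L, 112000L, 53500L, 200000L),
      orient = c("+", "-", "+", "+")),
    simple_del = tibble::tibble(
      chrom = c("chrB", "chrB"), start = c(1L, 88000L),
      end = c(33000L, 200000L), orient = c("+", "+")),
    dup_inv_insert = tibble::tibble(
      chrom = c("chrB", "chrB", "chrB", "chrB"),
      start = c(1L, 88000L, 55001L, 95001L),
      end = c(10000L, 152000L, 79000L, 200000L),
      orient = c("+", "+", "-", "+")),
    inactivating = tibble::tibble(
      chrom = c("chrB", "chrB"), start = c(1L, 140000L),
      end = c(33000L, 200000L), orient = c("+", "+")),
    complex_multi = NULL)

  expected_class <- c(mda175 = "activating", simple_del = "activating",
                      dup_inv_insert = "indeterminate",
                      inactivating = "likely_inactivating",
                      complex_multi = "indeterminate")[[name]]

  if (name == "complex_multi") {
    junctions <- tibble::tibble(
      id = c("A", "B"),
      chromA = "chrB", posA = c(93000L, 97000L), sideA = "right",
      chromB = "chrB", posB = c(101000L, 110000L), sideB = "right",
      inserted_sequence = "", tumour_support = 8L, normal_support = 0L)
    return(list(derivative = NULL, junctions = junctions, walk = NULL,
                expected_class = expected_class))
  }
  out <- apply_rearrangement(toy$genome, walk, paste0("der_", name))
  out$junctions$tumour_support <- 10L
  out$expected_class <- expected_class
  out
}
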