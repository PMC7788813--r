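# Synthetic data, part 4: breakend VCFs with paired tumour/normal support,
# optional germline junctions and excluded-contig decoys, a panel-of-normals
# BEDPE, and seeded read-position simulation for the copy-number profile.

#' Simulate a tumour/normal breakend VCF (+ optional panel)
#'
#' Writes the truth junctions as BND mate pairs with the given tumour/normal
#' split-read support. Germline junctions (normal support >= 1) and decoy
#' junctions on excluded contigs can be planted to exercise the somatic
#' filters. The emitted file re-parses to the returned truth table.
#'
#' @param junctions truth junction tibble (support columns are overridden by
#'   the arguments when given).
#' @param path output VCF path.
#' @param contigs named integer vector of contig lengths (decoy contigs are
#'   added automatically).
#' @param tumour_support,normal_support per-junction support (recycled).
#' @param germline optional junction tibble to plant with
#'   `germline_normal_support` reads in the normal.
#' @param germline_normal_support normal support of planted germline
#'   junctions (default 2).
#' @param decoy_chroms character vector of excluded-contig names to plant one
#'   decoy junction each (e.g. "chrM"); NULL for none.
#' @return the full truth tibble as written (somatic + germline + decoys).
#' @export
simulate_sv_vcf <- function(junctions, path, contigs,
                            tumour_support = NULL, normal_support = NULL,
                            germline = NULL, germline_normal_support = 2L,
                            decoy_chroms = NULL) {
  jn <- junctions
  if (!is.null(tumour_support))
    jn$tumour_support <- rep_len(as.integer(tumour_support), nrow(jn))
  if (!is.null(normal_support))
    jn$normal_support <- rep_len(as.integer(normal_support), nrow(jn))
  if (!is.null(germline)) {
    germline$tumour_support <- rep_len(germline$tumour_support %||% 6L,
                                       nrow(germline))
    germline$normal_support <- rep_len(as.integer(germline_normal_support),
                                       nrow(germline))
    germline$id <- paste0("G", seq_len(nrow(germline)))
    jn <- dplyr::bind_rows(jn, germline)
  }
  if (!is.null(decoy_chroms)) {
    for (dc in decoy_chroms) {
      if (!dc %in% names(contigs)) contigs[dc] <- 20000L
      jn <- dplyr::bind_rows(jn, tibble::tibble(
        id = paste0("D_", dc), chromA = dc, posA = 5000L, sideA = "left",
        chromB = names(contigs)[1], posB = 50000L, sideB = "right",
        inserted_sequence = "", tumour_support = 5L, normal_support = 0L))
    }
  }
  write_breakend_vcf(jn, path, contigs)
  jn
}

#' Simulate read start positions for a copy-number profile
#'
#' Poisson read counts per window at `depth` reads/window in the reference
#' and `depth * copy_number` in the tumour, with uniform positions within
#' each window. Returns the two position vectors.
#'
#' @param region list(chrom, start, end).
#' @param window_bp window width.
#' @param depth mean reads per window at copy ratio 1.
#' @param copy_number numeric vector of per-window tumour/normal copy ratios
#'   (recycled over windows).
#' @param seed integer seed.
#' @return list(tumour, reference) of integer positions.
#' @export
simulate_cn_reads <- function(region, window_bp, depth, copy_number,
                              seed = 1L) {
  starts <- seq(region$start, region$end, by = window_bp)
  cn <- rep_len(copy_number, length(starts))
  withr::with_seed(seed, {
    tum <- unlist(lapply(seq_along(starts), function(i) {
      n <- stats::rpois(1, depth * cn[i])
      if (n == 0) return(integer(0))
      starts[i] + sample.int(window_bp, n, replace = TRUE) - 1L
    }))
    ref <- unlist(lapply(seq_along(starts), function(i) {
      n <- stats::rpois(1, depth)
      if (n == 0) return(integer(0))
      starts[i] + sample.int(window_bp, n, replace = TRUE) - 1L
    }))
    list(tumour = as.integer(pmin(tum, region$end)),
         reference = as.integer(pmin(ref, region$end)))
  })
}

#' Per-window copy ratio implied by a derivative walk
#'
#' Models a tumour carrying the derivative chromosome plus
#' `background_copies` intact reference homologues against a diploid
#' reference sample: per window, ratio = (walk coverage multiplicity +
#' background_copies) / 2. A heterozygous deletion gives 0.5, neutral 1,
#' a duplicated segment 1.5.
#'
#' @param walk derivative walk tibble(chrom, start, end, orient).
#' @param region list(chrom, start, end).
#' @param window_bp window width.
#' @param background_copies untouched reference copies in the tumour
#'   (default 1).
#' @return numeric vector of per-window ratios (length = windows in region).
#' @export
walk_copy_ratio <- function(walk, region, window_bp, background_copies = 1L) {
  starts <- seq(region$start, region$end, by = window_bp)
  mid <- pmin(starts + window_bp %/% 2L, region$end)
  cover <- vapply(mid, function(p) {
    sum(walk$chrom == region$chrom & walk$start <= p & walk$end >= p)
  }, 1L)
  (cover + background_copies) / 2
}
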