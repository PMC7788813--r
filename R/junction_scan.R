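# Junction scan: exact text search of raw RNA reads for splice-boundary
# anchor k-mers of the genes of interest, classification of the sequence
# adjacent to each anchor hit (the partner side of the junction), and
# per-junction read-count summaries.
#
# This is a targeted fusion detector, not an aligner: every read is scanned
# independently for anchor substrings in both orientations, and whatever lies
# adjacent to the anchor within the read is compared against the
# complementary-side anchors of all modelled exons (including cryptic ones).

#' Build a splice-anchor index
#'
#' Extracts both-side anchors of length `k` for every exon (including cryptic
#' exons) of the given gene models and checks them for collisions: two exon
#' boundaries sharing a k-mer (in either orientation) make hits unattributable
#' and are reported as an error, the remedy being a larger `k`.
#'
#' @param genes list of gene_models.
#' @param genome DNAStringSet.
#' @param k anchor length (default 20).
#' @return tibble(gene, label, side, k, sequence, ambiguous) with attribute
#'   `k`; one row per exon boundary.
#' @export
build_anchor_index <- function(genes, genome, k = 20L) {
  idx <- purrr::map_dfr(genes, function(g) splice_anchors(genome, g, k))
  all_seqs <- c(idx$sequence, revcomp(idx$sequence))
  counts <- table(all_seqs)
  clash <- names(counts)[counts > 1]
  clash <- clash[clash %in% idx$sequence]
  if (length(clash) > 0) {
    bad <- idx[idx$sequence %in% clash, ]
    stop("anchor collisions at k=", k, " (raise k): ",
         paste(sprintf("%s:%s/%s", bad$gene, bad$label, bad$side),
               collapse = ", "))
  }
  attr(idx, "k") <- as.integer(k)
  idx
}

#' Read a FASTQ file as a character tibble
#'
#' @param path FASTQ path (plain or gzipped).
#' @return tibble(read_id, seq).
#' @export
read_fastq <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) stop("malformed FASTQ '", path, "': ",
                             conditionMessage(e)))
  tibble::tibble(read_id = sub("\\s.*$", "", names(x)),
                 seq = as.character(x))
}

# Hamming-tolerant substring positions of `pattern` in `subject`
# (used only when max_mismatches > 0; the 0-mismatch path uses gregexpr).
mismatch_positions <- function(pattern, subject, max_mismatches) {
  k <- nchar(pattern)
  n <- nchar(subject)
  if (n < k) return(integer(0))
  pat <- utf8ToInt(pattern)
  sub <- utf8ToInt(subject)
  out <- integer(0)
  for (p in seq_len(n - k + 1)) {
    if (sum(sub[p:(p + k - 1)] != pat) <= max_mismatches) out <- c(out, p)
  }
  out
}

anchor_positions <- function(anchor, seqs, max_mismatches) {
  if (max_mismatches == 0) {
    m <- gregexpr(anchor, seqs, fixed = TRUE)
    lapply(m, function(x) if (x[1] == -1L) integer(0) else as.integer(x))
  } else {
    lapply(seqs, function(s) mismatch_positions(anchor, s, max_mismatches))
  }
}

#' Scan reads for splice-anchor hits
#'
#' Every occurrence of an indexed anchor — or its reverse complement — in a
#' read yields a hit. Hits found on the reverse complement of a read are
#' reported in transcript orientation (`read_strand = "revcomp"`, offsets and
#' flanks on the reverse-complemented read), so downstream classification is
#' strand-invariant. The flank is the partner-side sequence adjacent to the
#' anchor within the read: everything 5' of an acceptor anchor, everything 3'
#' of a donor anchor. Anchors may match anywhere in the read.
#'
#' @param reads FASTQ path or tibble(read_id, seq) from [read_fastq()].
#' @param index anchor index from [build_anchor_index()].
#' @param max_mismatches allowed mismatches in the anchor match (default 0,
#'   pure text search).
#' @return tibble of hits: read_id, file_order, gene, label, side,
#'   read_strand, offset, flank_sequence, flank_length, read_seq (oriented);
#'   ordered by file order then offset.
#' @export
scan_reads <- function(reads, index, max_mismatches = 0L) {
  if (is.character(reads)) reads <- read_fastq(reads)
  k <- attr(index, "k")
  if (nrow(reads) == 0 || nrow(index) == 0) return(empty_hits())
  oriented <- list(`as-is` = reads$seq, revcomp = revcomp(reads$seq))
  hits <- list()
  for (strand_name in names(oriented)) {
    seqs <- oriented[[strand_name]]
    for (i in seq_len(nrow(index))) {
      pos <- anchor_positions(index$sequence[i], seqs, max_mismatches)
      nhit <- lengths(pos)
      if (sum(nhit) == 0) next
      ridx <- rep.int(seq_along(seqs), nhit)
      p <- unlist(pos, use.names = FALSE)
      seq_at <- seqs[ridx]
      if (index$side[i] == "acceptor") {
        flank <- substr(seq_at, 1L, p - 1L)
      } else {
        flank <- substr(seq_at, p + k, nchar(seq_at))
      }
      hits[[length(hits) + 1]] <- tibble::tibble(
        read_id = reads$read_id[ridx], file_order = ridx,
        gene = index$gene[i], label = index$label[i], side = index$side[i],
        read_strand = strand_name, offset = p,
        flank_sequence = flank, flank_length = nchar(flank),
        read_seq = seq_at)
    }
  }
  if (length(hits) == 0) return(empty_hits())
  out <- dplyr::bind_rows(hits)
  out[order(out$file_order, out$offset, out$read_strand, out$side), ]
}

empty_hits <- function() {
  tibble::tibble(read_id = character(0), file_order = integer(0),
                 gene = character(0), label = character(0),
                 side = character(0), read_strand = character(0),
                 offset = integer(0), flank_sequence = character(0),
                 flank_length = integer(0), read_seq = character(0))
}

#' Classify the partner flank of anchor hits
#'
#' For an acceptor-anchor hit the flank is the donor side of the junction: a
#' flank of length f >= `min_flank` whose last min(f, k) bases exactly match
#' the corresponding suffix of a modelled donor anchor is labelled with that
#' exon; symmetrically, donor-anchor hits are classified against acceptor
#' anchor prefixes. Flanks matching no modelled exon are `novel` and the
#' literal sequence is retained for reporting; flanks shorter than `min_flank`
#' are `too_short` and excluded from fraction denominators downstream.
#'
#' @param hits tibble from [scan_reads()].
#' @param index anchor index (provides the candidate partner anchors).
#' @param min_flank minimum flank length for a definite classification
#'   (default 12).
#' @return hits with columns added: acceptor, donor, category
#'   (known|novel|too_short).
#' @export
classify_flanks <- function(hits, index, min_flank = 12L) {
  k <- attr(index, "k")
  n <- nrow(hits)
  acceptor <- donor <- character(n)
  category <- character(n)
  donors <- index[index$side == "donor", ]
  acceptors <- index[index$side == "acceptor", ]
  for (i in seq_len(n)) {
    own <- paste0(hits$gene[i], ":", hits$label[i])
    f <- hits$flank_length[i]
    flank <- hits$flank_sequence[i]
    if (hits$side[i] == "acceptor") {
      acceptor[i] <- own
      if (f < min_flank) {
        donor[i] <- "too_short"; category[i] <- "too_short"
      } else {
        m <- min(f, k)
        fl_tail <- substr(flank, f - m + 1L, f)
        match <- substr(donors$sequence, k - m + 1L, k) == fl_tail
        if (any(match)) {
          j <- which(match)[1]
          donor[i] <- paste0(donors$gene[j], ":", donors$label[j])
          category[i] <- "known"
        } else {
          donor[i] <- paste0("novel(", flank, ")")
          category[i] <- "novel"
        }
      }
    } else {
      donor[i] <- own
      if (f < min_flank) {
        acceptor[i] <- "too_short"; category[i] <- "too_short"
      } else {
        m <- min(f, k)
        fl_head <- substr(flank, 1L, m)
        match <- substr(acceptors$sequence, 1L, m) == fl_head
        if (any(match)) {
          j <- which(match)[1]
          acceptor[i] <- paste0(acceptors$gene[j], ":", acceptors$label[j])
          category[i] <- "known"
        } else {
          acceptor[i] <- paste0("novel(", flank, ")")
          category[i] <- "novel"
        }
      }
    }
  }
  hits$acceptor <- acceptor
  hits$donor <- donor
  hits$category <- category
  hits
}

#' Summarise junction read counts per acceptor
#'
#' Counts classified split reads per (acceptor, donor) pair, using
#' acceptor-side anchor hits (one per junction-spanning read, avoiding double
#' counting reads that also contain the donor anchor). `too_short` hits are
#' excluded from the denominators. Percentages per acceptor are
#' 100 * count / total, rounded half away from zero.
#'
#' @param calls classified hits from [classify_flanks()].
#' @param dedup if TRUE, identical (oriented) read sequences are collapsed
#'   before counting — the duplicate-removed cell-line mode; FALSE keeps
#'   duplicates, the cohort mode.
#' @return tibble(acceptor, donor, n, percent) sorted by acceptor then
#'   descending count; attribute "too_short" holds the per-acceptor count of
#'   unclassifiable short-flank hits.
#' @export
summarise_junctions <- function(calls, dedup = FALSE) {
  acc <- calls[calls$side == "acceptor", ]
  too_short <- acc[acc$category == "too_short", ]
  acc <- acc[acc$category != "too_short", ]
  if (dedup && nrow(acc) > 0)
    acc <- dplyr::distinct(acc, .data$acceptor, .data$donor, .data$read_seq,
                           .keep_all = TRUE)
  out <- acc |>
    dplyr::count(.data$acceptor, .data$donor, name = "n") |>
    dplyr::group_by(.data$acceptor) |>
    dplyr::mutate(percent = round_half_up(100 * .data$n / sum(.data$n))) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$acceptor, dplyr::desc(.data$n), .data$donor)
  attr(out, "too_short") <-
    if (nrow(too_short)) dplyr::count(too_short, .data$acceptor, name = "n")
    else tibble::tibble(acceptor = character(0), n = integer(0))
  out
}

#' One-call junction scan
#'
#' Convenience wrapper: scan, classify, summarise.
#'
#' @inheritParams scan_reads
#' @inheritParams classify_flanks
#' @inheritParams summarise_junctions
#' @return list(hits, calls, summary).
#' @export
scan_junctions <- function(reads, index, max_mismatches = 0L,
                           min_flank = 12L, dedup = FALSE) {
  hits <- scan_reads(reads, index, max_mismatches)
  calls <- classify_flanks(hits, index, min_flank)
  list(hits = hits, calls = calls,
       summary = summarise_junctions(calls, dedup))
}
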