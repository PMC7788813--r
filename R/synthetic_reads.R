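# Synthetic data, part 3: RNA reads. Junction-spanning reads are planted with
# explicit counts (deterministic compositions); background reads are drawn
# uniformly from spliced transcripts. Every other read is emitted
# reverse-complemented so both orientations are exercised. All sampling is
# seeded; identical configurations give byte-identical FASTQ.

#' Plant junction-spanning reads on a transcript sequence
#'
#' Read start positions are drawn uniformly among those placing at least
#' `min_side` bases on each side of the junction (so every planted read is
#' recoverable by an anchor of length <= `min_side` with a classifiable
#' flank). Reads with even index are reverse-complemented.
#'
#' @param tx_seq transcript (or pseudo-transcript) sequence.
#' @param junction_pos number of bases 5' of the junction in `tx_seq`.
#' @param n number of reads.
#' @param read_length read length (default 75).
#' @param min_side minimum bases on each side of the junction (default 20).
#' @param prefix read-id prefix.
#' @param seed integer seed.
#' @param base_error per-base substitution error rate (default 0).
#' @return tibble(read_id, seq).
#' @export
plant_junction_reads <- function(tx_seq, junction_pos, n, read_length = 75L,
                                 min_side = 20L, prefix = "jread",
                                 seed = 1L, base_error = 0) {
  if (n == 0) return(tibble::tibble(read_id = character(0),
                                    seq = character(0)))
  lo <- max(1L, junction_pos + min_side - read_length + 1L)
  hi <- min(nchar(tx_seq) - read_length + 1L, junction_pos - min_side + 1L)
  if (hi < lo)
    stop("transcript too short to plant reads with min_side = ", min_side)
  withr::with_seed(seed, {
    starts <- sample(lo:hi, n, replace = TRUE)
    seqs <- substr(rep(tx_seq, n), starts, starts + read_length - 1L)
    seqs <- apply_base_errors(seqs, base_error)
    rc <- seq_len(n) %% 2L == 0L
    seqs[rc] <- revcomp(seqs[rc])
    tibble::tibble(read_id = sprintf("%s_%04d", prefix, seq_len(n)),
                   seq = seqs)
  })
}

#' Uniform background reads from a transcript
#'
#' @inheritParams plant_junction_reads
#' @return tibble(read_id, seq).
#' @export
simulate_transcript_reads <- function(tx_seq, n, read_length = 75L,
                                      prefix = "bread", seed = 1L,
                                      base_error = 0) {
  if (n == 0) return(tibble::tibble(read_id = character(0),
                                    seq = character(0)))
  if (nchar(tx_seq) < read_length)
    stop("transcript shorter than the read length")
  withr::with_seed(seed, {
    starts <- sample(seq_len(nchar(tx_seq) - read_length + 1L), n,
                     replace = TRUE)
    seqs <- substr(rep(tx_seq, n), starts, starts + read_length - 1L)
    seqs <- apply_base_errors(seqs, base_error)
    rc <- seq_len(n) %% 2L == 0L
    seqs[rc] <- revcomp(seqs[rc])
    tibble::tibble(read_id = sprintf("%s_%04d", prefix, seq_len(n)),
                   seq = seqs)
  })
}

apply_base_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    b <- strsplit(s, "")[[1]]
    hit <- stats::runif(length(b)) < rate
    if (any(hit)) {
      b[hit] <- vapply(b[hit], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    }
    paste(b, collapse = "")
  }, "", USE.NAMES = FALSE)
}

# transcript-coordinate position of the boundary after exon `exon_id`
junction_offset <- function(genes, isoform, exon_id) {
  i <- match(exon_id, isoform)
  if (is.na(i)) stop("exon ", exon_id, " not in isoform")
  widths <- vapply(isoform[seq_len(i)], function(q) {
    e <- resolve_exon(genes, q)
    e$end - e$start + 1L
  }, 1L)
  sum(widths)
}

#' Simulate an RNA read set from a junction composition
#'
#' Each composition row plants `count` reads across one splice junction of
#' one isoform (or, with `exonA`/`exonB` NA, draws `count` background reads
#' from the whole isoform). Counts are exact, not sampled — the deterministic
#' fixture mode.
#'
#' @param genome DNAStringSet (reference or derivative-augmented).
#' @param genes list of gene_models.
#' @param composition tibble(name, isoform (list-column of qualified exon id
#'   vectors), exonA, exonB, count).
#' @param read_length,min_side,base_error see [plant_junction_reads()].
#' @param seed integer seed; each row uses `seed + row`.
#' @return tibble(read_id, seq).
#' @export
simulate_rna_reads <- function(genome, genes, composition, read_length = 75L,
                               min_side = 20L, seed = 1L, base_error = 0) {
  purrr::map_dfr(seq_len(nrow(composition)), function(i) {
    row <- composition[i, ]
    iso <- row$isoform[[1]]
    tx <- isoform_sequence(genome, genes, iso)
    if (is.na(row$exonA)) {
      simulate_transcript_reads(tx, row$count, read_length,
                                prefix = row$name, seed = seed + i,
                                base_error = base_error)
    } else {
      jpos <- junction_offset(genes, iso, row$exonA)
      nxt <- match(row$exonA, iso) + 1L
      if (iso[nxt] != row$exonB)
        stop("junction ", row$exonA, ">", row$exonB,
             " is not adjacent in the isoform")
      plant_junction_reads(tx, jpos, row$count, read_length, min_side,
                           prefix = row$name, seed = seed + i,
                           base_error = base_error)
    }
  })
}

#' The MDA-MB-175-style read composition
#'
#' The deterministic split-read composition used by the cell-line fixture:
#' at the NRG exon-3 acceptor, 38 reads splice from the cryptic int15 exon
#' and 122 from TNM exon 12 (160 split reads, 24% from int15); at the TNM
#' exon-3 acceptor, 144 reads splice from PPX1 exon 1 and exactly 1 from TNM
#' exon 2 (145 split reads).
#'
#' @param genes toy gene models.
#' @return composition tibble for [simulate_rna_reads()].
#' @export
mda175_read_composition <- function(genes) {
  nrg_body <- paste0("NRG:", c(3:6, 9, 11:18))
  tnm_body <- paste0("TNM:", 3:12)
  iso_beta <- c("PPX1:1", tnm_body, nrg_body)
  iso_int15 <- c("PPX1:1", tnm_body, "TNM:int15", nrg_body)
  iso_tnm_start <- c("TNM:2", paste0("TNM:", 3:16))
  tibble::tibble(
    name = c("int15_ex3", "ex12_ex3", "ppx1_tnm3", "tnm2_tnm3"),
    isoform = list(iso_int15, iso_beta, iso_beta, iso_tnm_start),
    exonA = c("TNM:int15", "TNM:12", "PPX1:1", "TNM:2"),
    exonB = c("NRG:3", "NRG:3", "TNM:3", "TNM:3"),
    count = c(38L, 122L, 144L, 1L))
}

#' Write reads as FASTQ
#'
#' Constant "I" base qualities; `.gz` paths are compressed.
#'
#' @param reads tibble(read_id, seq).
#' @param path output path.
#' @return invisible path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$read_id))
  Biostrings::writeXStringSet(
    x, path, format = "fastq", compress = grepl("\\.gz$", path),
    qualities = Biostrings::BStringSet(strrep("I", Biostrings::width(x))))
  invisible(path)
}
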