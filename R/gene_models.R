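# Gene models: genome container, exon tables, genome-order exon numbering,
# splice-boundary anchors and fusion isoform combinatorics.
#
# Conventions: all coordinates handled and reported 1-based inclusive (GTF/VCF
# style); interval length = end - start + 1. Exon "labels" are short strings
# ("3", "11ext", "int15"); fully qualified exon ids are "GENE:label".

#' Construct a genome assembly
#'
#' Validates a set of named chromosome sequences (A/C/G/T/N, uppercase) and
#' returns them as a [Biostrings::DNAStringSet].
#'
#' @param sequences named character vector or DNAStringSet of chromosome
#'   sequences.
#' @return a DNAStringSet with unique names.
#' @export
genome_assembly <- function(sequences) {
  x <- Biostrings::DNAStringSet(sequences)
  nm <- names(x)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("all chromosomes must be named")
  if (anyDuplicated(nm)) stop("duplicate chromosome names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(Biostrings::width(x) == 0)) stop("empty chromosome sequence")
  freq <- Biostrings::alphabetFrequency(x, baseOnly = FALSE, collapse = TRUE)
  bad <- freq[setdiff(names(freq)[freq > 0], c("A", "C", "G", "T", "N"))]
  if (length(bad) > 0)
    stop("genome alphabet restricted to ACGTN; found: ",
         paste(names(bad), collapse = ", "))
  x
}

#' Read / write a genome FASTA
#'
#' @param path FASTA file path.
#' @return `read_genome_fasta()` returns a validated DNAStringSet.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  # FASTA descriptions may carry comments after the identifier
  names(x) <- sub("\\s.*$", "", names(x))
  genome_assembly(x)
}

#' @rdname read_genome_fasta
#' @param genome DNAStringSet to write.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70)
  invisible(path)
}

#' Build an exon table
#'
#' Helper constructing the exon tibble used inside [gene_model()]. Rows are in
#' transcript order; `number` is the exon number (genome-order for genes using
#' that convention), `label` its string form ("3", "int15", "11ext").
#'
#' @param gene gene name the exon belongs to (cryptic exons may be hosted by a
#'   different gene than the model that lists them).
#' @param label character exon labels.
#' @param number integer exon numbers (NA for cryptic/unnumbered exons).
#' @param chrom,start,end 1-based inclusive genomic coordinates.
#' @param strand "+" or "-" — the strand the exon is *expressed* on (cryptic
#'   antisense exons carry the expressed strand, not the host gene's).
#' @param coding logical; is any part of the exon coding.
#' @param tags list of character vectors of role tags per exon, from
#'   {transcription_start, Ig_like, EGF_like, transmembrane, cytoplasmic_tail,
#'   beta3_extension, cryptic}.
#' @return tibble of exons.
#' @export
exon_table <- function(gene, label, number, chrom, start, end, strand,
                       coding, tags = NULL) {
  n <- length(label)
  tags <- tags %||% rep(list(character(0)), n)
  stopifnot(all(start <= end), all(strand %in% c("+", "-")))
  tibble::tibble(
    gene = rep_len(gene, n), label = as.character(label),
    number = as.integer(number),
    chrom = rep_len(chrom, n), start = as.integer(start), end = as.integer(end),
    strand = rep_len(strand, n), coding = rep_len(coding, n),
    phase = NA_integer_, tags = tags
  )
}

#' Construct a gene model
#'
#' A gene model is the exon table (transcript order) plus the splicing
#' combinatorics needed for fusion-isoform enumeration: mutually exclusive
#' alternative exon groups (e.g. the NRG1 alpha/beta exons 10|11), the
#' cytoplasmic-tail exon set, an optional 3' extension block of the last
#' pre-tail exon (the beta3 terminus, modelled as an extension of exon 11
#' rather than a separate exon), and cryptic exons (unannotated, possibly
#' antisense within another gene's intron). Coding phases are computed from
#' cumulative coding length in transcript order: the phase of a coding exon is
#' the number of bases at its start that complete the previous codon.
#'
#' @param name gene name.
#' @param strand gene strand ("+"/"-").
#' @param exons exon tibble from [exon_table()], transcript order.
#' @param alt_groups list of integer vectors of mutually exclusive exon
#'   numbers (each group has >= 2 members).
#' @param tail_exons integer vector of cytoplasmic-tail exon numbers.
#' @param beta3_extension NULL or list(exon = <number>, ext_end = <coordinate>)
#'   defining the extended terminal exon of beta3-type isoforms.
#' @param cryptic_exons NULL or exon tibble of cryptic exons (tagged
#'   "cryptic").
#' @return a `gene_model` list.
#' @export
gene_model <- function(name, strand, exons, alt_groups = list(),
                       tail_exons = integer(0), beta3_extension = NULL,
                       cryptic_exons = NULL) {
  stopifnot(nrow(exons) >= 1, strand %in% c("+", "-"))
  for (g in alt_groups)
    if (length(g) < 2) stop("alternative exon groups need >= 2 members")
  if (!is.null(cryptic_exons)) {
    ok <- vapply(cryptic_exons$tags, function(t) "cryptic" %in% t, logical(1))
    if (!all(ok)) stop("cryptic exons must carry the 'cryptic' role tag")
  }
  # beta3 terminus and transmembrane are mutually exclusive exon roles
  bad <- vapply(exons$tags, function(t)
    all(c("beta3_extension", "transmembrane") %in% t), logical(1))
  if (any(bad)) stop("an exon cannot be both beta3_extension and transmembrane")
  model <- structure(
    list(name = name, strand = strand, exons = exons,
         alt_groups = alt_groups, tail_exons = as.integer(tail_exons),
         beta3_extension = beta3_extension, cryptic_exons = cryptic_exons),
    class = "gene_model")
  model$exons <- compute_phases(model)
  model
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s), %d exons", x$name, x$strand,
              nrow(x$exons)))
  if (length(x$alt_groups))
    cat(", alt groups:", paste(vapply(x$alt_groups, paste, "",
                                      collapse = "|"), collapse = " "))
  if (!is.null(x$cryptic_exons))
    cat(",", nrow(x$cryptic_exons), "cryptic exon(s)")
  cat("\n")
  invisible(x)
}

compute_phases <- function(gene) {
  ex <- gene$exons
  cum <- 0L
  ex$phase <- NA_integer_
  for (i in seq_len(nrow(ex))) {
    if (isTRUE(ex$coding[i])) {
      ex$phase[i] <- cum %% 3L
      cum <- cum + (ex$end[i] - ex$start[i] + 1L)
    }
  }
  ex
}

#' Gene genomic span
#'
#' @param gene a gene_model.
#' @return list(chrom, start, end) covering all (non-cryptic) exons.
#' @export
gene_span <- function(gene) {
  list(chrom = gene$exons$chrom[1],
       start = min(gene$exons$start), end = max(gene$exons$end))
}

#' Number exons by genome order
#'
#' Assigns exon numbers 1..n by ascending genomic start coordinate,
#' irrespective of transcript usage or strand — the numbering convention used
#' for NRG1, under which the first exon of many normal transcripts is exon 3.
#' Overlapping exons are an annotation error unless they belong to the same
#' annotated alternative group.
#'
#' @param gene a gene_model.
#' @return the gene_model with `number` (and numeric `label`s) reassigned;
#'   attribute "mapping" holds the old-label -> new-number map.
#' @export
number_exons_by_genome_order <- function(gene) {
  ex <- gene$exons
  if (nrow(ex) < 1) stop("gene has no exons")
  ord <- order(ex$start, ex$end)
  sorted <- ex[ord, ]
  # overlap check among non-alternative exons
  if (nrow(sorted) > 1) {
    for (i in seq_len(nrow(sorted) - 1)) {
      if (sorted$start[i + 1] <= sorted$end[i] &&
          sorted$chrom[i + 1] == sorted$chrom[i]) {
        same_group <- any(vapply(gene$alt_groups, function(g)
          all(c(sorted$number[i], sorted$number[i + 1]) %in% g), logical(1)))
        if (!same_group)
          stop(sprintf("overlapping non-alternative exons %s and %s in %s",
                       sorted$label[i], sorted$label[i + 1], gene$name))
      }
    }
  }
  new_number <- integer(nrow(ex))
  new_number[ord] <- seq_len(nrow(ex))
  mapping <- stats::setNames(new_number, ex$label)
  renum <- gene
  renum$exons$number <- new_number
  renum$exons$label <- as.character(new_number)
  renum$exons <- compute_phases(renum)
  attr(renum, "mapping") <- mapping
  renum
}

# Look up one exon row by label within a model (regular, cryptic, or the
# extended beta3 terminal exon "NNext").
find_exon <- function(gene, label) {
  label <- as.character(label)
  hit <- gene$exons[gene$exons$label == label, ]
  if (nrow(hit) == 1) return(hit)
  if (!is.null(gene$cryptic_exons)) {
    hit <- gene$cryptic_exons[gene$cryptic_exons$label == label, ]
    if (nrow(hit) == 1) return(hit)
  }
  b3 <- gene$beta3_extension
  if (!is.null(b3) && label == paste0(b3$exon, "ext")) {
    base <- gene$exons[gene$exons$number == b3$exon, ]
    if (nrow(base) == 1) {
      if (base$strand == "+") {
        base$end <- as.integer(b3$ext_end)
      } else {
        base$start <- as.integer(b3$ext_end)
      }
      base$label <- label
      base$tags <- list(union(base$tags[[1]], "beta3_extension"))
      return(base)
    }
  }
  stop(sprintf("exon '%s' not found in gene %s", label, gene$name))
}

# Resolve "GENE:label" against a list of gene models; exon rows carry their
# own `gene` column, so cryptic exons hosted in another gene's intron resolve
# through the model that lists them.
resolve_exon <- function(genes, qualified) {
  parts <- strsplit(qualified, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("exon ids must be 'GENE:label', got ", qualified)
  for (g in genes) {
    hit <- tryCatch(find_exon(g, parts[2]), error = function(e) NULL)
    if (!is.null(hit) && hit$gene[1] == parts[1]) return(hit)
  }
  stop("exon ", qualified, " not found in supplied gene models")
}

#' Genomic sequence of an exon (transcript strand)
#'
#' @param genome DNAStringSet.
#' @param exon one-row exon tibble.
#' @return character sequence, 5'->3' on the expressed strand.
#' @export
exon_sequence <- function(genome, exon) {
  s <- as.character(Biostrings::subseq(genome[[exon$chrom]],
                                       exon$start, exon$end))
  if (exon$strand == "-") s <- revcomp(s) else s
}

#' Extract a splice anchor
#'
#' The acceptor anchor is the first `k` transcribed bases of an exon, the
#' donor anchor the last `k`, both read 5'->3' on the mRNA (so for minus-strand
#' exons the reverse complement is taken from the opposite genomic end). No
#' padding into the intron: `k` longer than the exon is an error. Anchors
#' containing N are flagged ambiguous with a warning.
#'
#' @param genome DNAStringSet.
#' @param exon one-row exon tibble.
#' @param side "acceptor" or "donor".
#' @param k anchor length in bases (>= 8).
#' @return one-row tibble: gene, label, side, k, sequence, ambiguous.
#' @export
extract_splice_anchor <- function(genome, exon, side = c("acceptor", "donor"),
                                  k = 20L) {
  side <- match.arg(side)
  k <- as.integer(k)
  if (k < 8L) stop("anchor length k must be >= 8")
  len <- exon$end - exon$start + 1L
  if (k > len)
    stop(sprintf("k=%d exceeds exon %s:%s length %d (no padding into intron)",
                 k, exon$gene, exon$label, len))
  txseq <- exon_sequence(genome, exon)
  seq <- if (side == "acceptor") substr(txseq, 1L, k) else
    substr(txseq, nchar(txseq) - k + 1L, nchar(txseq))
  ambiguous <- grepl("N", seq, fixed = TRUE)
  if (ambiguous)
    warning(sprintf("anchor %s:%s %s contains N; flagged ambiguous",
                    exon$gene, exon$label, side))
  tibble::tibble(gene = exon$gene, label = exon$label, side = side,
                 k = k, sequence = seq, ambiguous = ambiguous)
}

#' All splice anchors of a gene model
#'
#' Both-side anchors for every exon, including cryptic exons. The beta3
#' extension block is not a spliced boundary and contributes no anchors.
#'
#' @inheritParams extract_splice_anchor
#' @param gene a gene_model.
#' @return tibble of anchors.
#' @export
splice_anchors <- function(genome, gene, k = 20L) {
  ex <- gene$exons
  if (!is.null(gene$cryptic_exons)) ex <- dplyr::bind_rows(ex, gene$cryptic_exons)
  purrr::map_dfr(seq_len(nrow(ex)), function(i) {
    dplyr::bind_rows(
      extract_splice_anchor(genome, ex[i, ], "acceptor", k),
      extract_splice_anchor(genome, ex[i, ], "donor", k))
  })
}

#' Enumerate fusion isoforms
#'
#' Cartesian expansion of a fusion transcript's 3'-gene splicing choices:
#' one member per mutually exclusive alternative group, terminal choice
#' (beta3 extended exon vs the cytoplasmic-tail exons), and optional
#' inclusion of each cryptic exon (inserted at the fusion junction, i.e.
#' between the 5'-partner exons and the first 3'-gene exon). Exons tagged
#' `transcription_start` never participate in fusion transcripts and are
#' skipped.
#'
#' @param five_prime_exons character vector of qualified exon ids
#'   ("GENE:label") contributed by the 5' partner, 5'->3'.
#' @param three_prime_gene gene_model of the 3' gene (alt groups and tail
#'   defined).
#' @param include_cryptic if TRUE, each cryptic exon of the 3' gene model is
#'   optionally included (doubling the isoform count per cryptic exon).
#' @param spliced_in_exon first retained exon number of the 3' gene
#'   (default 3).
#' @return list of isoforms, each a character vector of qualified exon ids,
#'   in deterministic (lexicographic) order.
#' @export
enumerate_fusion_isoforms <- function(five_prime_exons, three_prime_gene,
                                      include_cryptic = FALSE,
                                      spliced_in_exon = 3L) {
  if (length(five_prime_exons) == 0) stop("empty 5' exon list")
  g <- three_prime_gene
  ex <- g$exons
  is_ts <- vapply(ex$tags, function(t) "transcription_start" %in% t, logical(1))
  body <- ex[!is_ts & ex$number >= spliced_in_exon, ]
  if (nrow(body) == 0) stop("no 3' exons at or after the spliced-in exon")
  alt_members <- unlist(g$alt_groups)
  common <- body$number[!(body$number %in% c(alt_members, g$tail_exons))]

  alt_choices <- if (length(g$alt_groups)) expand.grid(g$alt_groups) else
    data.frame(row.names = 1)
  terminal_choices <- if (!is.null(g$beta3_extension) && length(g$tail_exons))
    c("beta3", "tail") else "tail"
  cryptics <- if (include_cryptic && !is.null(g$cryptic_exons))
    g$cryptic_exons else NULL
  cryptic_sets <- list(character(0))
  if (!is.null(cryptics)) {
    for (i in seq_len(nrow(cryptics))) {
      qual <- paste0(cryptics$gene[i], ":", cryptics$label[i])
      cryptic_sets <- c(cryptic_sets,
                        lapply(cryptic_sets, function(s) c(s, qual)))
    }
  }

  isoforms <- list()
  for (ai in seq_len(max(1, nrow(alt_choices)))) {
    alt_sel <- if (ncol(alt_choices)) as.integer(unlist(alt_choices[ai, ])) else integer(0)
    for (term in terminal_choices) {
      nums <- sort(c(common, alt_sel))
      if (term == "beta3") {
        b3 <- g$beta3_extension
        labels <- as.character(nums)
        if (b3$exon %in% nums) {
          labels[nums == b3$exon] <- paste0(b3$exon, "ext")
        } else {
          labels <- c(labels, paste0(b3$exon, "ext"))
        }
      } else {
        nums <- sort(c(nums, g$tail_exons))
        labels <- as.character(nums)
      }
      three <- paste0(g$name, ":", labels)
      for (cs in cryptic_sets) {
        isoforms <- c(isoforms, list(c(five_prime_exons, cs, three)))
      }
    }
  }
  isoforms <- unique(isoforms)
  keys <- vapply(isoforms, paste, "", collapse = "|")
  isoforms[order(keys)]
}

#' Spliced sequence of an isoform
#'
#' @param genome DNAStringSet.
#' @param genes list of gene_models (for exon resolution).
#' @param isoform character vector of qualified exon ids, 5'->3'.
#' @return character transcript sequence.
#' @export
isoform_sequence <- function(genome, genes, isoform) {
  paste(vapply(isoform, function(q)
    exon_sequence(genome, resolve_exon(genes, q)), ""), collapse = "")
}
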