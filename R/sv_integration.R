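# Structural-variant integration: breakend (BND) VCF parsing with bracket
# decoding, somatic filtering (matched normal, panel of normals, excluded
# contigs), per-gene breakpoint accounting, and orientation-consistent
# genomic fusion prediction.
#
# A junction is an oriented adjacency between two breakends. Each breakend is
# (chrom, pos, retained side), retained side "left" meaning reference sequence
# left of (and including) pos is retained in the derivative, "right" meaning
# sequence to the right is retained — the convention used to letter junctions
# in capture-sequencing breakpoint maps.

# --- VCF 4.2 breakend bracket decoding -------------------------------------
# ALT forms, with t the REF base plus any inserted sequence, p the mate locus:
#   t[p[  local retains left,  mate retains right
#   t]p]  local retains left,  mate retains left
#   ]p]t  local retains right, mate retains left
#   [p[t  local retains right, mate retains right
decode_breakend_alt <- function(alt, ref) {
  m <- regmatches(alt, regexec(
    "^([ACGTN]*)([\\[\\]])([^:\\[\\]]+):([0-9]+)([\\[\\]])([ACGTN]*)$", alt,
    perl = TRUE))[[1]]
  if (length(m) == 0 || m[3] != m[6])
    stop("cannot decode breakend ALT: ", alt)
  t_before <- m[2]; t_after <- m[7]
  if (nchar(t_before) > 0 && nchar(t_after) > 0)
    stop("cannot decode breakend ALT: ", alt)
  local_side <- if (nchar(t_before) > 0) "left" else "right"
  mate_side <- if (m[3] == "[") "right" else "left"
  t <- paste0(t_before, t_after)
  insert <- if (local_side == "left") substr(t, nchar(ref) + 1L, nchar(t))
            else substr(t, 1L, nchar(t) - nchar(ref))
  list(mate_chrom = m[4], mate_pos = as.integer(m[5]),
       local_side = local_side, mate_side = mate_side, insert = insert)
}

encode_breakend_alt <- function(ref, local_side, mate_chrom, mate_pos,
                                mate_side, insert = "") {
  bracket <- if (mate_side == "right") "[" else "]"
  p <- paste0(bracket, mate_chrom, ":", mate_pos, bracket)
  if (local_side == "left") paste0(ref, insert, p) else paste0(p, insert, ref)
}

#' Parse a breakend VCF into junctions
#'
#' Reads BND-style records (bracket ALT notation, mate pairing via the MATEID
#' INFO field) and collapses each mate pair into a single junction with both
#' breakends' retained sides decoded. Split-read support is taken from the
#' `SR` FORMAT field of the tumour and matched-normal sample columns.
#' Non-BND records are ignored with a message; an unpaired mate is an error.
#'
#' @param path VCF path.
#' @param tumour_sample,normal_sample sample column names or indices
#'   (defaults: columns 1 and 2).
#' @return junction tibble: id, chromA, posA, sideA, chromB, posB, sideB,
#'   inserted_sequence, tumour_support, normal_support.
#' @export
parse_breakend_vcf <- function(path, tumour_sample = 1L, normal_sample = 2L) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  ref <- as.character(VariantAnnotation::ref(vcf))
  ids <- names(rr)
  is_bnd <- grepl("\\[|\\]", alt)
  n_skipped <- sum(!is_bnd)
  if (n_skipped > 0)
    message(n_skipped, " non-breakend record(s) ignored")
  mateid <- VariantAnnotation::info(vcf)$MATEID
  mateid <- vapply(seq_along(ids), function(i) {
    m <- mateid[[i]]
    if (length(m) == 0) NA_character_ else as.character(m)[1]
  }, "")
  sr <- VariantAnnotation::geno(vcf)$SR
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)

  keep <- which(is_bnd)
  seen <- character(0)
  rows <- list()
  for (i in keep) {
    if (is.na(mateid[i]))
      stop("breakend record ", ids[i], " has no MATEID")
    j <- match(mateid[i], ids)
    if (is.na(j))
      stop("mate record ", mateid[i], " of ", ids[i], " is missing")
    if (ids[i] %in% seen) next
    seen <- c(seen, ids[i], ids[j])
    dec <- decode_breakend_alt(alt[i], ref[i])
    if (dec$mate_chrom != chrom[j] || dec$mate_pos != pos[j])
      stop("breakend ", ids[i], " ALT disagrees with its mate record position")
    dec_mate <- decode_breakend_alt(alt[j], ref[j])
    if (dec_mate$local_side != dec$mate_side ||
        dec_mate$mate_side != dec$local_side)
      warning("inconsistent retained sides between mates ", ids[i], "/",
              ids[j])
    rows[[length(rows) + 1]] <- tibble::tibble(
      id = sub("_[12]$", "", ids[i]),
      chromA = chrom[i], posA = pos[i], sideA = dec$local_side,
      chromB = chrom[j], posB = pos[j], sideB = dec$mate_side,
      inserted_sequence = dec$insert,
      tumour_support = as.integer(sr[i, tumour_sample]),
      normal_support = as.integer(sr[i, normal_sample]))
  }
  if (length(rows) == 0) return(empty_junctions())
  dplyr::bind_rows(rows)
}

empty_junctions <- function() {
  tibble::tibble(id = character(0), chromA = character(0), posA = integer(0),
                 sideA = character(0), chromB = character(0),
                 posB = integer(0), sideB = character(0),
                 inserted_sequence = character(0),
                 tumour_support = integer(0), normal_support = integer(0))
}

#' Write junctions as a breakend VCF
#'
#' Emits each junction as a BND mate pair (ids `<id>_1`/`<id>_2`) with bracket
#' ALTs encoding both retained sides, SVTYPE=BND, MATEID, and an `SR` FORMAT
#' field for TUMOUR and NORMAL sample columns. Round-trips through
#' [parse_breakend_vcf()].
#'
#' @param junctions junction tibble (see [parse_breakend_vcf()]).
#' @param path output VCF path.
#' @param contigs named integer vector of contig lengths for the header.
#' @return invisible path.
#' @export
write_breakend_vcf <- function(junctions, path, contigs) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of mate breakend\">",
    "##FORMAT=<ID=SR,Number=1,Type=Integer,Description=\"Split read support\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TUMOUR", "NORMAL", sep = "\t"))
  recs <- character(0)
  for (i in seq_len(nrow(junctions))) {
    jn <- junctions[i, ]
    ins <- jn$inserted_sequence %||% ""
    if (is.na(ins)) ins <- ""
    alt1 <- encode_breakend_alt("N", jn$sideA, jn$chromB, jn$posB, jn$sideB,
                                ins)
    alt2 <- encode_breakend_alt("N", jn$sideB, jn$chromA, jn$posA, jn$sideA,
                                if (nzchar(ins)) revcomp_if_antisense(ins, jn) else "")
    id1 <- paste0(jn$id, "_1"); id2 <- paste0(jn$id, "_2")
    recs <- c(recs,
      paste(jn$chromA, jn$posA, id1, "N", alt1, ".", "PASS",
            paste0("SVTYPE=BND;MATEID=", id2), "SR",
            jn$tumour_support, jn$normal_support, sep = "\t"),
      paste(jn$chromB, jn$posB, id2, "N", alt2, ".", "PASS",
            paste0("SVTYPE=BND;MATEID=", id1), "SR",
            jn$tumour_support, jn$normal_support, sep = "\t"))
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

# Inserted sequence is recorded on the A record 5'->3' on the derivative as
# entered from side A; the mate record reads the join from the other side, so
# the insertion appears reverse-complemented iff the two retained sides make
# the join strand-flipping (left/left or right/right joins).
revcomp_if_antisense <- function(ins, jn) {
  if (jn$sideA == jn$sideB) revcomp(ins) else ins
}

#' Canonical form of a junction table
#'
#' Orders the two breakends of each junction (by chrom, pos, side) and sorts
#' rows, for set-style comparisons and round-trip tests.
#'
#' @param junctions junction tibble.
#' @return canonically ordered tibble.
#' @export
canonical_junctions <- function(junctions) {
  if (nrow(junctions) == 0) return(junctions)
  swap <- with(junctions, chromB < chromA |
                 (chromB == chromA & (posB < posA |
                                        (posB == posA & sideB < sideA))))
  out <- junctions
  out[swap, c("chromA", "posA", "sideA", "chromB", "posB", "sideB")] <-
    junctions[swap, c("chromB", "posB", "sideB", "chromA", "posA", "sideA")]
  out[order(out$chromA, out$posA, out$sideA, out$chromB, out$posB, out$sideB), ]
}

#' Somatic filtering of junctions
#'
#' Applies the three somatic filters: drop junctions with any supporting
#' reads in the matched normal; drop junctions matching a panel-of-normals
#' junction (same retained-side orientation, both breakends within
#' `panel_tol` bp); drop junctions with either breakend on a chromosome
#' outside `allowed_chroms` (mitochondrial and unassembled contigs).
#' Order-preserving and idempotent.
#'
#' @param junctions junction tibble.
#' @param panel NULL or a junction-like tibble (chromA, posA, sideA, chromB,
#'   posB, sideB) of panel-of-normals junctions.
#' @param allowed_chroms character vector of chromosomes to keep.
#' @param panel_tol matching tolerance in bp for the panel filter
#'   (default 10).
#' @return filtered junction tibble.
#' @export
filter_somatic <- function(junctions, panel = NULL,
                           allowed_chroms = NULL, panel_tol = 10L) {
  out <- junctions
  if (nrow(out) == 0) return(out)
  out <- out[out$normal_support < 1L, ]
  if (!is.null(allowed_chroms))
    out <- out[out$chromA %in% allowed_chroms &
                 out$chromB %in% allowed_chroms, ]
  if (!is.null(panel) && nrow(panel) > 0 && nrow(out) > 0) {
    in_panel <- vapply(seq_len(nrow(out)), function(i) {
      j <- out[i, ]
      direct <- panel$chromA == j$chromA & panel$chromB == j$chromB &
        panel$sideA == j$sideA & panel$sideB == j$sideB &
        abs(panel$posA - j$posA) <= panel_tol &
        abs(panel$posB - j$posB) <= panel_tol
      flipped <- panel$chromA == j$chromB & panel$chromB == j$chromA &
        panel$sideA == j$sideB & panel$sideB == j$sideA &
        abs(panel$posA - j$posB) <= panel_tol &
        abs(panel$posB - j$posA) <= panel_tol
      any(direct | flipped)
    }, logical(1))
    out <- out[!in_panel, ]
  }
  out
}

#' Read / write a panel of normals as BEDPE
#'
#' BEDPE with 0-based half-open intervals one breakend each; strand columns
#' encode retained sides ("+" = left retained, "-" = right retained).
#'
#' @param path BEDPE path.
#' @return `read_panel_bedpe()`: junction-like tibble.
#' @export
read_panel_bedpe <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom1", "start1", "end1", "chrom2",
                                       "start2", "end2", "name", "score",
                                       "strand1", "strand2"),
                         colClasses = c("character", "integer", "integer",
                                        "character", "integer", "integer",
                                        "character", "character", "character",
                                        "character"))
  tibble::tibble(id = x$name,
                 chromA = x$chrom1, posA = x$end1,
                 sideA = ifelse(x$strand1 == "+", "left", "right"),
                 chromB = x$chrom2, posB = x$end2,
                 sideB = ifelse(x$strand2 == "+", "left", "right"))
}

#' @rdname read_panel_bedpe
#' @param junctions junction-like tibble to write.
#' @export
write_panel_bedpe <- function(junctions, path) {
  lines <- vapply(seq_len(nrow(junctions)), function(i) {
    j <- junctions[i, ]
    paste(j$chromA, j$posA - 1L, j$posA, j$chromB, j$posB - 1L, j$posB,
          j$id %||% paste0("pon_", i), ".",
          ifelse(j$sideA == "left", "+", "-"),
          ifelse(j$sideB == "left", "+", "-"), sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Breakpoints within a gene
#'
#' Counts junction breakends falling inside the gene span (optionally widened
#' by `flank_bp`) and builds the per-case rearrangement record used by the
#' cohort summary and activation classification. A case with >= 2 breakpoints
#' in the gene is flagged multi-breakpoint.
#'
#' @param junctions (filtered) junction tibble.
#' @param gene gene_model of the gene of interest.
#' @param flank_bp span widening in bp (default 0: strictly within the
#'   annotated gene span).
#' @param case_id case identifier.
#' @return a `case_record` list: case_id, junctions (those with a breakend in
#'   span), n_breakpoints, multi_breakpoint, calls (empty; filled by
#'   annotation), in_dna_subset flag.
#' @export
breakpoints_in_gene <- function(junctions, gene, flank_bp = 0L,
                                case_id = NA_character_) {
  sp <- gene_span(gene)
  lo <- sp$start - flank_bp
  hi <- sp$end + flank_bp
  inA <- junctions$chromA == sp$chrom & junctions$posA >= lo &
    junctions$posA <= hi
  inB <- junctions$chromB == sp$chrom & junctions$posB >= lo &
    junctions$posB <= hi
  n <- sum(inA) + sum(inB)
  structure(list(case_id = case_id,
                 junctions = junctions[inA | inB, ],
                 n_breakpoints = as.integer(n),
                 multi_breakpoint = n >= 2L,
                 calls = NULL, in_dna_subset = TRUE),
            class = "case_record")
}

# 5'-most coordinate test helpers
gene_contains <- function(gene, chrom, pos, flank_bp = 0L) {
  sp <- gene_span(gene)
  chrom == sp$chrom & pos >= sp$start - flank_bp & pos <= sp$end + flank_bp
}

#' Predict a genomic fusion from one junction
#'
#' A fusion candidate is emitted iff (a) one breakend lies inside a 5'
#' candidate gene (span + `flank_bp`) with the retained side covering that
#' gene's promoter-proximal end on its coding strand, and (b) the other
#' breakend lies upstream of the 3' gene's first retained exon with the
#' retained side reading into the gene on its coding strand. The predicted
#' spliced-in exon is the first (lowest-numbered) acceptor exon downstream of
#' the breakend, excluding transcription-start exons. A breakend inside the
#' 3' gene that retains only the gene's 5' portion yields a candidate flagged
#' `five_prime_end_only` (an inactivating pattern). If no modelled 5' gene
#' contains the partner breakend but the 3'-side geometry is fusion-consistent,
#' a `novel` 5' partner is reported (frame then unknown).
#'
#' @param junction one-row junction tibble.
#' @param five_prime_candidates list of gene_models considered as 5' partners.
#' @param three_prime_gene gene_model of the 3' gene.
#' @param flank_bp span widening for the 5' gene test.
#' @param allow_novel_partner emit novel-partner candidates (default TRUE).
#' @return one-row tibble (junction_id, five_prime, three_prime,
#'   spliced_in_exon, donor_label, status), or a `no_fusion` object whose
#'   "reason" attribute logs why (test with [is_fusion_candidate()]).
#' @export
predict_fusion_from_junction <- function(junction, five_prime_candidates,
                                         three_prime_gene, flank_bp = 0L,
                                         allow_novel_partner = TRUE) {
  g3 <- three_prime_gene
  ends <- list(
    list(chrom = junction$chromA, pos = junction$posA, side = junction$sideA),
    list(chrom = junction$chromB, pos = junction$posB, side = junction$sideB))

  ex <- g3$exons
  is_ts <- vapply(ex$tags, function(t) "transcription_start" %in% t, logical(1))
  acceptors <- ex[!is_ts, ]
  sp3 <- gene_span(g3)

  # 3'-side test: breakend reading into the gene on its coding strand, with
  # at least one acceptor exon downstream
  three_side <- function(e) {
    if (e$chrom != sp3$chrom) return(NULL)
    if (g3$strand == "+") {
      if (e$side != "right") return(NULL)
      down <- acceptors[acceptors$start > e$pos, ]
      if (nrow(down) == 0) return(NULL)
      min(down$number)
    } else {
      if (e$side != "left") return(NULL)
      down <- acceptors[acceptors$end < e$pos, ]
      if (nrow(down) == 0) return(NULL)
      min(down$number)
    }
  }

  # 5'-end-only test: breakend inside the 3' gene retaining only its 5' part
  five_end_only <- function(e) {
    if (!gene_contains(g3, e$chrom, e$pos)) return(FALSE)
    if (g3$strand == "+") e$side == "left" else e$side == "right"
  }

  # 5'-partner test: breakend inside a candidate gene retaining its
  # promoter-proximal exons on the coding strand; also derives the partner's
  # donor exon (last retained exon upstream of the breakend)
  five_side <- function(e) {
    for (g in five_prime_candidates) {
      if (gene_contains(g, e$chrom, e$pos, flank_bp)) {
        ok <- if (g$strand == "+") e$side == "left" else e$side == "right"
        if (!ok) return(list(name = NA_character_))  # wrong orientation
        retained <- if (g$strand == "+") which(g$exons$end <= e$pos)
                    else which(g$exons$start >= e$pos)
        donor <- if (length(retained)) g$exons$label[max(retained)]
                 else NA_character_
        return(list(name = g$name, donor_label = donor))
      }
    }
    NULL  # in no modelled 5' gene
  }

  for (ord in list(c(1, 2), c(2, 1))) {
    eA <- ends[[ord[1]]]; eB <- ends[[ord[2]]]
    spliced <- three_side(eB)
    if (is.null(spliced)) next
    fp <- five_side(eA)
    if (is.list(fp) && !is.na(fp$name)) {
      return(tibble::tibble(junction_id = junction$id, five_prime = fp$name,
                            three_prime = g3$name,
                            spliced_in_exon = as.integer(spliced),
                            donor_label = fp$donor_label,
                            status = "candidate"))
    }
    if (is.null(fp) && allow_novel_partner &&
        !gene_contains(g3, eA$chrom, eA$pos)) {
      return(tibble::tibble(junction_id = junction$id, five_prime = "novel",
                            three_prime = g3$name,
                            spliced_in_exon = as.integer(spliced),
                            donor_label = NA_character_,
                            status = "novel_partner"))
    }
  }

  # inactivating pattern: one breakend retains only the 5' part of the 3' gene
  for (e in ends) {
    if (five_end_only(e)) {
      return(tibble::tibble(junction_id = junction$id,
                            five_prime = NA_character_,
                            three_prime = g3$name,
                            spliced_in_exon = NA_integer_,
                            donor_label = NA_character_,
                            status = "five_prime_end_only"))
    }
  }
  structure(list(), reason = "no orientation-consistent sense-sense fusion",
            class = "no_fusion")
}

#' @export
print.no_fusion <- function(x, ...) {
  cat("<no fusion>", attr(x, "reason"), "\n")
  invisible(x)
}

#' Is a prediction result an actual candidate?
#'
#' @param x result of [predict_fusion_from_junction()].
#' @return logical.
#' @export
is_fusion_candidate <- function(x) !inherits(x, "no_fusion") && !is.null(x)

# exon number carrying the EGF_like tag (receptor-binding exon)
egf_exon_number <- function(gene) {
  has <- vapply(gene$exons$tags, function(t) "EGF_like" %in% t, logical(1))
  if (!any(has)) return(NA_integer_)
  gene$exons$number[which(has)[1]]
}
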