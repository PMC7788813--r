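# Derivative-chromosome reconstruction: a segment graph built from filtered
# junctions (segments = maximal intervals between breakpoints, adjacencies =
# oriented segment-end pairs induced by junctions plus reference
# adjacencies), bounded enumeration of derivative walks, transcript
# explanation against a walk, and recognition of the
# tandem-duplication-with-inverted-insertion motif.
#
# Breakend-to-cut convention: a breakend retaining the left of pos cuts the
# chromosome between pos and pos+1 and the junction attaches to the RIGHT end
# of the segment ending at pos; retaining the right of pos cuts between pos-1
# and pos and attaches to the LEFT end of the segment starting at pos.

breakend_cut <- function(pos, side) if (side == "left") pos else pos - 1L

#' Build a segment graph from junctions
#'
#' @param junctions junction tibble (filtered, deduplicated).
#' @param extents named integer vector of chromosome lengths.
#' @return a `segment_graph`: list(segments = tibble(seg_id, chrom, start,
#'   end), adjacencies = tibble(seg1, end1, seg2, end2, junction_id, type)).
#'   Per chromosome, segment count = distinct breakpoint count + 1.
#' @export
build_segment_graph <- function(junctions, extents) {
  ends <- dplyr::bind_rows(
    tibble::tibble(id = junctions$id, chrom = junctions$chromA,
                   pos = junctions$posA, side = junctions$sideA),
    tibble::tibble(id = junctions$id, chrom = junctions$chromB,
                   pos = junctions$posB, side = junctions$sideB))
  bad <- is.na(match(ends$chrom, names(extents))) |
    ends$pos < 1L | ends$pos > extents[ends$chrom]
  if (any(bad))
    stop("junction breakend outside chromosome extents: ",
         paste(sprintf("%s:%d", ends$chrom[bad], ends$pos[bad]),
               collapse = ", "))
  cuts_by_chrom <- lapply(stats::setNames(names(extents), names(extents)),
    function(ch) {
      e <- ends[ends$chrom == ch, ]
      if (nrow(e) == 0) return(integer(0))
      sort(unique(as.integer(mapply(breakend_cut, e$pos, e$side))))
    })
  segments <- purrr::map_dfr(names(extents), function(ch) {
    cuts <- cuts_by_chrom[[ch]]
    bounds <- c(0L, cuts, extents[[ch]])
    tibble::tibble(chrom = ch,
                   start = as.integer(bounds[-length(bounds)] + 1L),
                   end = as.integer(bounds[-1]))
  })
  segments$seg_id <- paste0(segments$chrom, ".", stats::ave(
    seq_len(nrow(segments)), segments$chrom, FUN = seq_along))
  # segment end holding a given breakend
  locate <- function(chrom, pos, side) {
    cut <- breakend_cut(pos, side)
    if (side == "left") {
      i <- which(segments$chrom == chrom & segments$end == cut)
      list(seg = segments$seg_id[i], end = "R")
    } else {
      i <- which(segments$chrom == chrom & segments$start == cut + 1L)
      list(seg = segments$seg_id[i], end = "L")
    }
  }
  variant <- purrr::map_dfr(seq_len(nrow(junctions)), function(i) {
    j <- junctions[i, ]
    a <- locate(j$chromA, j$posA, j$sideA)
    b <- locate(j$chromB, j$posB, j$sideB)
    tibble::tibble(seg1 = a$seg, end1 = a$end, seg2 = b$seg, end2 = b$end,
                   junction_id = j$id, type = "variant")
  })
  reference <- purrr::map_dfr(names(extents), function(ch) {
    segs <- segments[segments$chrom == ch, ]
    if (nrow(segs) < 2) return(NULL)
    tibble::tibble(seg1 = segs$seg_id[-nrow(segs)], end1 = "R",
                   seg2 = segs$seg_id[-1], end2 = "L",
                   junction_id = NA_character_, type = "reference")
  })
  proto <- tibble::tibble(seg1 = character(0), end1 = character(0),
                          seg2 = character(0), end2 = character(0),
                          junction_id = character(0), type = character(0))
  structure(list(segments = segments,
                 adjacencies = dplyr::bind_rows(proto, variant, reference)),
            class = "segment_graph")
}

#' @export
print.segment_graph <- function(x, ...) {
  cat(sprintf("<segment_graph> %d segments, %d adjacencies (%d variant)\n",
              nrow(x$segments), nrow(x$adjacencies),
              sum(x$adjacencies$type == "variant")))
  invisible(x)
}

#' Segment containing a genomic position
#'
#' @param graph segment_graph.
#' @param chrom,pos position.
#' @return seg_id.
#' @export
segment_at <- function(graph, chrom, pos) {
  s <- graph$segments
  i <- which(s$chrom == chrom & s$start <= pos & s$end >= pos)
  if (length(i) != 1) stop("position not in exactly one segment")
  s$seg_id[i]
}

# adjacencies incident to a given (segment, end), as (other seg, other end)
incident <- function(graph, seg, end) {
  a <- graph$adjacencies
  fwd <- a[a$seg1 == seg & a$end1 == end, c("seg2", "end2", "junction_id",
                                            "type")]
  names(fwd) <- c("seg", "end", "junction_id", "type")
  rev <- a[a$seg2 == seg & a$end2 == end, c("seg1", "end1", "junction_id",
                                            "type")]
  names(rev) <- c("seg", "end", "junction_id", "type")
  dplyr::bind_rows(fwd, rev)
}

walk_key <- function(walk)
  paste(paste0(walk$seg_id, walk$orient), collapse = " ")

reverse_walk <- function(walk) {
  tibble::tibble(seg_id = rev(walk$seg_id),
                 orient = ifelse(rev(walk$orient) == "+", "-", "+"))
}

#' Enumerate derivative walks
#'
#' Depth-first enumeration of walks through the segment graph: a walk
#' alternates segment traversals (in + or - orientation) and adjacencies
#' (variant or reference), starting at `from` and ending at `to`. Walks are
#' deduplicated up to reverse complement. The search is exhaustive below
#' `max_length` segment traversals; if any walk is truncated by the cap the
#' result carries attribute `truncated = TRUE`.
#'
#' @param graph segment_graph.
#' @param from list(seg, orient) starting segment and orientation.
#' @param to list(seg, orient) required final segment (orientation optional:
#'   NULL matches either).
#' @param max_length maximum number of segment traversals (default 12).
#' @return list of `derivative_model`s: each list(walk = tibble(seg_id,
#'   orient), multiplicity = named counts per segment).
#' @export
enumerate_walks <- function(graph, from, to, max_length = 12L) {
  results <- list()
  truncated <- FALSE
  walk <- tibble::tibble(seg_id = character(0), orient = character(0))
  recurse <- function(seg, orient, walk) {
    walk <- dplyr::bind_rows(walk,
                             tibble::tibble(seg_id = seg, orient = orient))
    if (seg == to$seg && (is.null(to$orient) || orient == to$orient)) {
      results[[length(results) + 1]] <<- walk
    }
    if (nrow(walk) >= max_length) {
      truncated <<- TRUE
      return(invisible())
    }
    exit_end <- if (orient == "+") "R" else "L"
    nxt <- incident(graph, seg, exit_end)
    for (i in seq_len(nrow(nxt))) {
      n_orient <- if (nxt$end[i] == "L") "+" else "-"
      recurse(nxt$seg[i], n_orient, walk)
    }
    invisible()
  }
  recurse(from$seg, from$orient, walk)
  # dedupe up to reverse complement
  seen <- character(0)
  keep <- list()
  for (w in results) {
    key <- min(walk_key(w), walk_key(reverse_walk(w)))
    if (key %in% seen) next
    seen <- c(seen, key)
    keep[[length(keep) + 1]] <- w
  }
  models <- lapply(keep, function(w) {
    structure(list(walk = w,
                   multiplicity = table(w$seg_id)),
              class = "derivative_model")
  })
  attr(models, "truncated") <- truncated
  models
}

#' Validate a walk against its graph
#'
#' Independent checker: every consecutive pair of walk elements must be
#' connected by a reference or variant adjacency joining the exit end of the
#' first to the entry end of the second.
#'
#' @param graph segment_graph.
#' @param walk tibble(seg_id, orient).
#' @return TRUE/FALSE.
#' @export
walk_is_connected <- function(graph, walk) {
  if (nrow(walk) < 2) return(TRUE)
  for (i in seq_len(nrow(walk) - 1L)) {
    exit_end <- if (walk$orient[i] == "+") "R" else "L"
    entry_end <- if (walk$orient[i + 1] == "+") "L" else "R"
    nxt <- incident(graph, walk$seg_id[i], exit_end)
    if (!any(nxt$seg == walk$seg_id[i + 1] & nxt$end == entry_end))
      return(FALSE)
  }
  TRUE
}

# ordered (exon, sense) occurrences along a walk; exons must lie wholly
# within one segment to be located
walk_exon_order <- function(model, graph, genes, exon_ids) {
  rows <- lapply(exon_ids, function(q) {
    e <- resolve_exon(genes, q)
    e$qid <- q
    e
  })
  occ <- list()
  for (i in seq_len(nrow(model$walk))) {
    seg <- graph$segments[graph$segments$seg_id == model$walk$seg_id[i], ]
    orient <- model$walk$orient[i]
    inside <- Filter(function(e)
      e$chrom == seg$chrom && e$start >= seg$start && e$end <= seg$end, rows)
    if (length(inside) == 0) next
    pos <- vapply(inside, function(e) e$start, 1L)
    ord <- order(pos, decreasing = (orient == "-"))
    for (e in inside[ord]) {
      sense <- (orient == "+" && e$strand == "+") ||
        (orient == "-" && e$strand == "-")
      occ[[length(occ) + 1]] <- list(qid = e$qid, sense = sense)
    }
  }
  occ
}

#' Does a derivative walk explain an observed transcript junction?
#'
#' TRUE iff the two exons of the junction occur along the walk (or its
#' reverse) in transcription order, both transcribed in the walk direction,
#' with no intervening antisense exon of the same genes.
#'
#' @param model derivative_model.
#' @param graph segment_graph the walk came from.
#' @param genes list of gene_models (for exon coordinates).
#' @param junction character vector c(five_exon, three_exon) of qualified
#'   exon ids.
#' @return logical.
#' @export
explain_transcript <- function(model, graph, genes, junction) {
  stopifnot(length(junction) == 2)
  if (nrow(model$walk) == 0) return(FALSE)
  genes_of <- vapply(strsplit(junction, ":"), `[`, "", 1)
  check <- function(walk) {
    m <- structure(list(walk = walk), class = "derivative_model")
    occ <- walk_exon_order(m, graph, genes, junction)
    ia <- which(vapply(occ, function(o) o$qid == junction[1] && o$sense,
                       logical(1)))
    ib <- which(vapply(occ, function(o) o$qid == junction[2] && o$sense,
                       logical(1)))
    for (a in ia) for (b in ib) {
      if (a < b) {
        between <- occ[seq(a, b)]
        anti <- vapply(between, function(o) !o$sense, logical(1))
        if (!any(anti)) return(TRUE)
      }
    }
    FALSE
  }
  check(model$walk) || check(reverse_walk(model$walk))
}

#' Detect a tandem duplication with inverted insertion
#'
#' Pattern-matches the two-junction signature of a tandem duplication whose
#' internal junction is interrupted by an inverted fragment: one junction
#' joining the duplication end to the insert end with both left sides
#' retained, and one joining the insert start to the duplication start with
#' both right sides retained. Reports the duplicated and inserted spans in
#' bp. Requires >= 3 junctions (the motif plus at least the fusion-forming
#' junction); returns NULL when no junction pair matches.
#'
#' The two-junction signature is symmetric in which fragment is "the
#' duplication" and which "the insert"; when `gene` is supplied the
#' assignment whose duplicated span overlaps the gene is preferred
#' (ties/no-overlap: the larger duplicated span).
#'
#' @param junctions junction tibble near the gene of interest.
#' @param gene optional gene_model used to resolve the dup/insert ambiguity.
#' @return NULL, or list(dup_chrom, dup_start, dup_end, dup_span_bp,
#'   insert_chrom, insert_start, insert_end, insert_span_bp, junction_ids).
#' @export
detect_dup_with_inverted_insertion <- function(junctions, gene = NULL) {
  if (nrow(junctions) < 3) return(NULL)
  canon <- canonical_junctions(junctions)
  ll <- canon[canon$sideA == "left" & canon$sideB == "left", ]
  rr <- canon[canon$sideA == "right" & canon$sideB == "right", ]
  found <- list()
  for (i in seq_len(nrow(ll))) for (j in seq_len(nrow(rr))) {
    a <- ll[i, ]; b <- rr[j, ]
    # try both assignments of (dup end, insert end) within each junction
    for (flip_a in c(FALSE, TRUE)) for (flip_b in c(FALSE, TRUE)) {
      d2 <- if (flip_a) list(chrom = a$chromB, pos = a$posB)
            else list(chrom = a$chromA, pos = a$posA)
      i2 <- if (flip_a) list(chrom = a$chromA, pos = a$posA)
            else list(chrom = a$chromB, pos = a$posB)
      i1 <- if (flip_b) list(chrom = b$chromB, pos = b$posB)
            else list(chrom = b$chromA, pos = b$posA)
      d1 <- if (flip_b) list(chrom = b$chromA, pos = b$posA)
            else list(chrom = b$chromB, pos = b$posB)
      if (d1$chrom == d2$chrom && i1$chrom == i2$chrom &&
          d1$pos < d2$pos && i1$pos < i2$pos &&
          # the inverted insert is a fragment distinct from the duplication
          !(i1$pos == d1$pos && i2$pos == d2$pos)) {
        found[[length(found) + 1]] <- list(
          dup_chrom = d1$chrom, dup_start = d1$pos, dup_end = d2$pos,
          dup_span_bp = d2$pos - d1$pos + 1L,
          insert_chrom = i1$chrom, insert_start = i1$pos,
          insert_end = i2$pos,
          insert_span_bp = i2$pos - i1$pos + 1L,
          junction_ids = c(a$id, b$id))
      }
    }
  }
  if (length(found) == 0) return(NULL)
  overlap <- function(m) {
    if (is.null(gene)) return(0L)
    sp <- gene_span(gene)
    if (m$dup_chrom != sp$chrom) return(0L)
    max(0L, min(m$dup_end, sp$end) - max(m$dup_start, sp$start) + 1L)
  }
  score <- vapply(found, function(m) overlap(m) + m$dup_span_bp / 1e9,
                  numeric(1))
  found[[which.max(score)]]
}

#' Soft copy-number consistency of a walk
#'
#' Fraction of profiled segments whose walk multiplicity (plus one reference
#' copy outside the derivative, if `background_copies` is set) matches the
#' rounded copy-number ratio.
#'
#' @param model derivative_model.
#' @param segment_ratios tibble(seg_id, ratio) of rounded or raw ratios.
#' @param background_copies reference copies to add to each segment's walk
#'   multiplicity (default 1).
#' @return fraction in `[0, 1]`.
#' @export
walk_cn_consistency <- function(model, segment_ratios,
                                background_copies = 1L) {
  mult <- model$multiplicity
  got <- vapply(segment_ratios$seg_id, function(s) {
    m <- if (s %in% names(mult)) mult[[s]] else 0L
    m + background_copies
  }, 1L)
  mean(got == round(segment_ratios$ratio))
}

#' Export a segment graph as GraphViz DOT
#'
#' @param graph segment_graph.
#' @param path output path.
#' @return invisible path.
#' @export
write_segment_graph_dot <- function(graph, path) {
  lines <- c("graph segments {", "  node [shape=box];")
  for (i in seq_len(nrow(graph$segments))) {
    s <- graph$segments[i, ]
    lines <- c(lines, sprintf("  \"%s\" [label=\"%s:%d-%d\"];",
                              s$seg_id, s$chrom, s$start, s$end))
  }
  for (i in seq_len(nrow(graph$adjacencies))) {
    a <- graph$adjacencies[i, ]
    style <- if (a$type == "variant") "solid" else "dotted"
    lab <- if (is.na(a$junction_id)) "" else
      sprintf(" label=\"%s\"", a$junction_id)
    lines <- c(lines, sprintf(
      "  \"%s\" -- \"%s\" [style=%s taillabel=\"%s\" headlabel=\"%s\"%s];",
      a$seg1, a$seg2, style, a$end1, a$end2, lab))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
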