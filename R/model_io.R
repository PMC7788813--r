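# Gene-model IO: GTF exon/CDS features for coordinates, plus a YAML side file
# for what GTF cannot express (alternative exon groups, role tags, the beta3
# extension block, cryptic antisense exons).

#' Write gene models as GTF + YAML overrides
#'
#' Exon features carry `gene_name`, `transcript_id` and `exon_number`
#' (the label); coding exons additionally emit a CDS feature over the same
#' interval. Splicing combinatorics, role tags and cryptic exons go to the
#' YAML overrides file.
#'
#' @param genes list of gene_models.
#' @param gtf_path,yaml_path output paths.
#' @return invisible list of the two paths.
#' @export
write_gene_models <- function(genes, gtf_path, yaml_path) {
  feats <- purrr::map_dfr(genes, function(g) {
    ex <- g$exons
    tibble::tibble(chrom = ex$chrom, start = ex$start, end = ex$end,
                   strand = ex$strand, type = "exon", gene_name = g$name,
                   label = ex$label, coding = ex$coding, phase = ex$phase)
  })
  gr <- GenomicRanges::GRanges(
    feats$chrom, IRanges::IRanges(feats$start, feats$end),
    strand = feats$strand, type = feats$type, gene_name = feats$gene_name,
    gene_id = feats$gene_name,
    transcript_id = paste0(feats$gene_name, ".t1"), exon_number = feats$label,
    phase = NA_integer_)
  cds <- gr[feats$coding]
  if (length(cds) > 0) {
    cds$type <- "CDS"
    cds$phase <- feats$phase[feats$coding]
  }
  rtracklayer::export(c(gr, cds), gtf_path, format = "gtf")

  ov <- lapply(genes, function(g) {
    o <- list(strand = g$strand,
              alt_exon_groups = lapply(g$alt_groups, as.integer),
              tail_exons = as.integer(g$tail_exons))
    if (!is.null(g$beta3_extension))
      o$beta3_extension <- list(exon = g$beta3_extension$exon,
                                ext_end = g$beta3_extension$ext_end)
    tags <- g$exons$tags
    names(tags) <- g$exons$label
    tags <- tags[vapply(tags, length, 0L) > 0]
    if (length(tags)) o$role_tags <- lapply(tags, as.character)
    if (!is.null(g$cryptic_exons)) {
      ce <- g$cryptic_exons
      o$cryptic_exons <- lapply(seq_len(nrow(ce)), function(i) list(
        gene = ce$gene[i], label = ce$label[i], chrom = ce$chrom[i],
        start = ce$start[i], end = ce$end[i], strand = ce$strand[i],
        coding = ce$coding[i]))
    }
    o
  })
  names(ov) <- vapply(genes, function(g) g$name, "")
  yaml::write_yaml(ov, yaml_path)
  invisible(list(gtf = gtf_path, yaml = yaml_path))
}

#' Load gene models from GTF + YAML overrides
#'
#' Reads exon/CDS features (restricted to records with a `gene_name`
#' attribute) and reassembles gene_models using the YAML side file written by
#' [write_gene_models()]. Exons are ordered in transcript order (ascending
#' genomic start for + strand genes, descending for -).
#'
#' @param gtf_path,yaml_path input paths.
#' @return named list of gene_models.
#' @export
load_gene_models <- function(gtf_path, yaml_path) {
  gr <- rtracklayer::import(gtf_path)
  gr <- gr[!is.na(gr$gene_name) & gr$type %in% c("exon", "CDS")]
  ov <- yaml::read_yaml(yaml_path)
  genes <- lapply(names(ov), function(nm) {
    o <- ov[[nm]]
    sub <- gr[gr$gene_name == nm]
    exon_feats <- sub[sub$type == "exon"]
    cds_keys <- paste(GenomicRanges::start(sub), GenomicRanges::end(sub))[sub$type == "CDS"]
    ord <- order(GenomicRanges::start(exon_feats),
                 decreasing = (o$strand == "-"))
    exon_feats <- exon_feats[ord]
    labels <- exon_feats$exon_number
    tags <- lapply(labels, function(l)
      as.character(o$role_tags[[l]] %||% character(0)))
    ex <- exon_table(
      gene = nm, label = labels,
      number = suppressWarnings(as.integer(labels)),
      chrom = as.character(GenomicRanges::seqnames(exon_feats)),
      start = GenomicRanges::start(exon_feats),
      end = GenomicRanges::end(exon_feats),
      strand = as.character(GenomicRanges::strand(exon_feats)),
      coding = paste(GenomicRanges::start(exon_feats),
                     GenomicRanges::end(exon_feats)) %in% cds_keys,
      tags = tags)
    cryp <- NULL
    if (!is.null(o$cryptic_exons)) {
      cryp <- purrr::map_dfr(o$cryptic_exons, function(ce)
        exon_table(ce$gene, ce$label, NA_integer_, ce$chrom, ce$start, ce$end,
                   ce$strand, ce$coding, tags = list("cryptic")))
    }
    b3 <- if (!is.null(o$beta3_extension))
      list(exon = as.integer(o$beta3_extension$exon),
           ext_end = as.integer(o$beta3_extension$ext_end)) else NULL
    gene_model(nm, o$strand, ex,
               alt_groups = lapply(o$alt_exon_groups %||% list(), as.integer),
               tail_exons = as.integer(o$tail_exons %||% integer(0)),
               beta3_extension = b3, cryptic_exons = cryp)
  })
  stats::setNames(genes, names(ov))
}
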