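#' Round half away from zero
#'
#' Base [round()] rounds half to even; fusion-frequency and split-read
#' percentages in this package are reported with the conventional
#' "half away from zero" rule instead (so 23.75% of reads prints as 24%).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Reverse complement of character sequences
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Records the configuration, seed and package version of a pipeline run as
#' JSON, together with an md5 hash of the serialised configuration, so that
#' re-runs with identical settings produce identical manifest hashes.
#'
#' @param path output JSON path.
#' @param config named list of configuration values.
#' @param seed integer seed used for the run.
#' @return (invisibly) the manifest list.
#' @export
write_run_manifest <- function(path, config, seed = NA_integer_) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(cfg_json, tmp)
  manifest <- list(
    config = config,
    seed = seed,
    config_hash = unname(tools::md5sum(tmp)),
    package = "nrgfusion",
    version = as.character(utils::packageVersion("nrgfusion"))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
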