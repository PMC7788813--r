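# Copy number from windowed read counts over a targeted region:
# tumour/reference ratio per fixed-width window, change-point detection by
# recursive binary segmentation on the mean ratio, and concordance between
# copy-number steps and rearrangement junction positions (balanced vs
# unbalanced junctions).

#' Windowed read counts and copy-number ratio
#'
#' Tiles the target region with fixed-width windows, counts read start
#' positions per window for tumour and reference, and computes the
#' library-size normalised ratio (tumour fraction / reference fraction).
#' Windows with zero reference count are masked and excluded from
#' segmentation.
#'
#' @param tumour_pos,reference_pos integer vectors of read start positions on
#'   the region's chromosome.
#' @param region list(chrom, start, end).
#' @param window_bp window width in bp (>= 100).
#' @return a `cn_profile`: tibble(chrom, start, end, tumour, reference,
#'   ratio, masked) with attributes region and window_bp.
#' @export
window_read_counts <- function(tumour_pos, reference_pos, region,
                               window_bp = 1000L) {
  if (window_bp < 100L) stop("window_bp must be >= 100")
  if (is.null(region$start) || is.null(region$end) ||
      region$end < region$start) stop("empty region")
  breaks <- seq(region$start, region$end + window_bp, by = window_bp)
  n <- length(breaks) - 1L
  count_in <- function(pos) {
    pos <- pos[pos >= region$start & pos <= region$end]
    tabulate(findInterval(pos, breaks, rightmost.closed = FALSE), nbins = n)
  }
  tum <- count_in(tumour_pos)
  ref <- count_in(reference_pos)
  tum_total <- sum(tum); ref_total <- sum(ref)
  if (tum_total == 0 || ref_total == 0)
    stop("no reads in region for tumour or reference")
  ratio <- (tum / tum_total) / (ref / ref_total)
  ratio[ref == 0] <- NA_real_
  out <- tibble::tibble(
    chrom = region$chrom,
    start = as.integer(breaks[-length(breaks)]),
    end = as.integer(pmin(breaks[-1] - 1L, region$end)),
    tumour = tum, reference = ref, ratio = ratio, masked = ref == 0)
  attr(out, "region") <- region
  attr(out, "window_bp") <- as.integer(window_bp)
  class(out) <- c("cn_profile", class(out))
  out
}

# recursive binary segmentation over indices of unmasked windows:
# split where |mean(left) - mean(right)| is maximal, accept if >= min_step;
# segments shorter than min_width windows are never created (single noisy
# windows cannot become segments)
binseg <- function(x, lo, hi, min_step, min_width = 2L) {
  n <- hi - lo + 1L
  if (n < 2L * min_width) return(integer(0))
  best_i <- NA_integer_; best_d <- -Inf
  cs <- cumsum(x[lo:hi])
  for (i in min_width:(n - min_width)) {
    d <- abs(cs[i] / i - (cs[n] - cs[i]) / (n - i))
    if (d > best_d) { best_d <- d; best_i <- i }
  }
  if (best_d < min_step) return(integer(0))
  cut <- lo + best_i - 1L  # last index of the left segment
  c(binseg(x, lo, cut, min_step, min_width), cut,
    binseg(x, cut + 1L, hi, min_step, min_width))
}

#' Detect copy-number steps
#'
#' Recursive binary segmentation of the (unmasked) ratio profile with a mean
#' ratio-change threshold `min_step`. Each accepted change-point is reported
#' as a step at the boundary between two windows, with direction (up/down in
#' the direction of increasing coordinate) and magnitude (difference of
#' adjacent segment means).
#'
#' @param profile cn_profile from [window_read_counts()].
#' @param min_step minimum ratio change to call a step (default 0.3).
#' @param min_width minimum segment width in windows (default 2).
#' @return list(steps = tibble(pos, direction, magnitude, left_mean,
#'   right_mean), segments = tibble(start, end, mean_ratio)) — `pos` is the
#'   genomic boundary (end of the left window).
#' @export
detect_steps <- function(profile, min_step = 0.3, min_width = 2L) {
  ok <- which(!profile$masked & !is.na(profile$ratio))
  x <- profile$ratio[ok]
  if (length(x) == 0)
    return(list(steps = empty_steps(), segments = tibble::tibble(
      start = integer(0), end = integer(0), mean_ratio = numeric(0))))
  cuts <- sort(binseg(x, 1L, length(x), min_step, min_width))
  # prune: the split criterion compares half means, so adjacent final
  # segments can end up closer than min_step; merge such neighbours until
  # every remaining step has magnitude >= min_step
  repeat {
    if (length(cuts) == 0) break
    bounds <- c(0L, cuts, length(x))
    means <- vapply(seq_len(length(bounds) - 1L), function(s)
      mean(x[(bounds[s] + 1L):bounds[s + 1L]]), numeric(1))
    diffs <- abs(diff(means))
    if (all(diffs >= min_step)) break
    cuts <- cuts[-which.min(diffs)]
  }
  seg_bounds <- c(0L, cuts, length(x))
  segments <- purrr::map_dfr(seq_len(length(seg_bounds) - 1L), function(s) {
    idx <- ok[(seg_bounds[s] + 1L):seg_bounds[s + 1L]]
    tibble::tibble(start = profile$start[idx[1]],
                   end = profile$end[idx[length(idx)]],
                   mean_ratio = mean(profile$ratio[idx]))
  })
  steps <- if (length(cuts) == 0) empty_steps() else
    purrr::map_dfr(seq_along(cuts), function(s) {
      tibble::tibble(
        pos = profile$end[ok[cuts[s]]],
        direction = ifelse(segments$mean_ratio[s + 1] >
                             segments$mean_ratio[s], "up", "down"),
        magnitude = abs(segments$mean_ratio[s + 1] - segments$mean_ratio[s]),
        left_mean = segments$mean_ratio[s],
        right_mean = segments$mean_ratio[s + 1])
    })
  list(steps = steps, segments = segments)
}

empty_steps <- function() {
  tibble::tibble(pos = integer(0), direction = character(0),
                 magnitude = numeric(0), left_mean = numeric(0),
                 right_mean = numeric(0))
}

#' Junction / copy-number-step concordance
#'
#' Labels each junction breakend falling in the profiled region as
#' `unbalanced` (a copy-number step lies within `tol_windows` windows of the
#' breakend, reported with the step's direction) or `balanced` (no nearby
#' step — e.g. a reciprocal junction pair with no net dosage change).
#'
#' @param junctions junction tibble (per-id breakends are tested
#'   independently).
#' @param profile cn_profile.
#' @param steps step tibble from [detect_steps()].
#' @param tol_windows matching tolerance in windows (default 1).
#' @return tibble(id, chrom, pos, side, verdict, step_direction, step_pos).
#' @export
junction_cn_concordance <- function(junctions, profile, steps,
                                    tol_windows = 1L) {
  region <- attr(profile, "region")
  window_bp <- attr(profile, "window_bp")
  tol_bp <- tol_windows * window_bp
  ends <- dplyr::bind_rows(
    tibble::tibble(id = junctions$id, chrom = junctions$chromA,
                   pos = junctions$posA, side = junctions$sideA),
    tibble::tibble(id = junctions$id, chrom = junctions$chromB,
                   pos = junctions$posB, side = junctions$sideB))
  ends <- ends[ends$chrom == region$chrom & ends$pos >= region$start &
                 ends$pos <= region$end, ]
  if (nrow(ends) == 0) return(tibble::tibble(
    id = character(0), chrom = character(0), pos = integer(0),
    side = character(0), verdict = character(0),
    step_direction = character(0), step_pos = integer(0)))
  verdict <- character(nrow(ends))
  sdir <- character(nrow(ends)); spos <- integer(nrow(ends))
  for (i in seq_len(nrow(ends))) {
    if (nrow(steps) > 0) {
      d <- abs(steps$pos - ends$pos[i])
      j <- which.min(d)
      if (d[j] <= tol_bp) {
        verdict[i] <- "unbalanced"
        sdir[i] <- steps$direction[j]
        spos[i] <- steps$pos[j]
        next
      }
    }
    verdict[i] <- "balanced"; sdir[i] <- NA_character_; spos[i] <- NA_integer_
  }
  dplyr::bind_cols(ends, tibble::tibble(verdict = verdict,
                                        step_direction = sdir,
                                        step_pos = spos))
}
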