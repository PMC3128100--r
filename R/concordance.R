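#' Merge peaks across cross-linking conditions
#'
#' To retain only concordant open-chromatin regions, the peak sets called
#' under two formaldehyde cross-linking conditions are intersected at the
#' region level: connected components of overlapping peaks (>= 1 bp) across
#' the union of both sets are computed, and only components containing at
#' least one peak from each condition are kept.  The emitted interval is
#' the union span of the component and `score_pct` the maximum over its
#' members.
#'
#' @param peaks_a,peaks_b peak sets from the two conditions.
#' @return merged peak data.frame (chrom, start, end, score_pct,
#'   n_probes = sum over members, source = "merged"), sorted.
#' @export
merge_conditions <- function(peaks_a, peaks_b) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), score_pct = numeric(0),
                      n_probes = integer(0), source = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(peaks_a) || !nrow(peaks_b)) return(empty)
  comp <- overlap_components(peaks_a, peaks_b)
  keep <- comp$components[comp$components$has_a & comp$components$has_b, ,
                          drop = FALSE]
  if (!nrow(keep)) return(empty)
  out <- data.frame(chrom = keep$chrom, start = keep$start, end = keep$end,
                    score_pct = keep$score_pct, n_probes = keep$n_probes,
                    source = "merged", stringsAsFactors = FALSE)
  out <- sort_intervals(out)
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  out
}

# Connected components (>= 1 bp overlap) of the union of two interval
# sets.  Returns per-component span, membership flags and per-interval
# component assignment.
overlap_components <- function(a, b) {
  all <- rbind(a[, c("chrom", "start", "end")], b[, c("chrom", "start", "end")])
  from_a <- rep(c(TRUE, FALSE), c(nrow(a), nrow(b)))
  gr <- intervals_to_gr(all)
  red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  hit <- GenomicRanges::findOverlaps(gr, red, ignore.strand = TRUE)
  comp_of <- rep(NA_integer_, length(gr))
  comp_of[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  span <- gr_to_intervals(red)
  score <- if ("score_pct" %in% names(a) && "score_pct" %in% names(b))
    c(a$score_pct, b$score_pct) else rep(NA_real_, length(gr))
  nprobe <- if ("n_probes" %in% names(a) && "n_probes" %in% names(b))
    c(a$n_probes, b$n_probes) else rep(NA_integer_, length(gr))
  components <- data.frame(
    chrom = span$chrom, start = span$start, end = span$end,
    has_a = as.logical(tapply(from_a, comp_of, any)[as.character(seq_len(nrow(span)))]),
    has_b = as.logical(tapply(!from_a, comp_of, any)[as.character(seq_len(nrow(span)))]),
    score_pct = as.numeric(tapply(score, comp_of, max)[as.character(seq_len(nrow(span)))]),
    n_probes = as.integer(tapply(nprobe, comp_of, sum)[as.character(seq_len(nrow(span)))]),
    stringsAsFactors = FALSE)
  list(components = components, comp_of = comp_of, from_a = from_a)
}

#' Concordance rate between two peak sets
#'
#' Percentage of peaks in each set that overlap (>= 1 bp) at least one
#' peak of the other set; used to quantify agreement between cross-linking
#' conditions.
#'
#' @param peaks_a,peaks_b peak sets.
#' @return named numeric `c(pct_a, pct_b)`.
#' @export
concordance_rate <- function(peaks_a, peaks_b) {
  if (!nrow(peaks_a) || !nrow(peaks_b))
    stop("concordance_rate undefined for empty peak sets")
  c(pct_a = 100 * mean(overlaps_any(peaks_a, peaks_b)),
    pct_b = 100 * mean(overlaps_any(peaks_b, peaks_a)))
}

#' Compare condition-merged peak sets of two cell types
#'
#' A peak is "shared" when it overlaps (>= 1 bp) a peak of the other cell
#' type.  Shared regions are counted as connected components across both
#' sets, so a single count `n_shared` is valid from either side; the
#' reported fractions are `100 * n_shared / n_a` and `100 * n_shared /
#' n_b`, rounded to one decimal.
#'
#' @param peaks_a,peaks_b condition-merged peak sets (e.g. MK and EB cells).
#' @return list of class `"comparison_report"`: `n_a`, `n_b`, `n_shared`,
#'   `frac_a_shared`, `frac_b_shared`, and `class_a`/`class_b`
#'   (per-peak `"shared"`/`"a_only"`/`"b_only"` labels).
#' @export
compare_cell_types <- function(peaks_a, peaks_b) {
  n_a <- nrow(peaks_a); n_b <- nrow(peaks_b)
  if (!n_a || !n_b) {
    return(structure(list(
      n_a = n_a, n_b = n_b, n_shared = 0L,
      frac_a_shared = if (n_a) 0 else NA_real_,
      frac_b_shared = if (n_b) 0 else NA_real_,
      class_a = rep("a_only", n_a), class_b = rep("b_only", n_b)),
      class = "comparison_report"))
  }
  shared_a <- overlaps_any(peaks_a, peaks_b)
  shared_b <- overlaps_any(peaks_b, peaks_a)
  comp <- overlap_components(peaks_a, peaks_b)
  both <- comp$components$has_a & comp$components$has_b
  n_shared <- sum(both)
  structure(list(
    n_a = n_a, n_b = n_b, n_shared = n_shared,
    frac_a_shared = round(100 * n_shared / n_a, 1),
    frac_b_shared = round(100 * n_shared / n_b, 1),
    class_a = ifelse(shared_a, "shared", "a_only"),
    class_b = ifelse(shared_b, "shared", "b_only")),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("peak-set comparison: %d vs %d peaks, %d shared regions (%.1f%% / %.1f%%)\n",
              x$n_a, x$n_b, x$n_shared, x$frac_a_shared, x$frac_b_shared))
  invisible(x)
}

#' Peak density per megabase
#'
#' @param peaks peak set.
#' @param footprint_bp interrogated genomic footprint in bp.
#' @return peaks per Mb.
#' @examples
#' peak_density(data.frame(chrom = "c", start = 0, end = 1)[rep(1, 10), ], 1e6)
#' @export
peak_density <- function(peaks, footprint_bp) {
  if (footprint_bp <= 0) stop("footprint must be positive")
  nrow(peaks) / (footprint_bp / 1e6)
}
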