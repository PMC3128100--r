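#' Construct a validated table of genomic intervals
#'
#' Internal convention everywhere in the package: 0-based half-open
#' `[start, end)` coordinates, exact string chromosome names (no "chr"
#' normalization).
#'
#' @param chrom character chromosome names.
#' @param start,end numeric 0-based half-open coordinates, `start < end`.
#' @param strand strand per interval, one of `"+"`, `"-"`, `"."`.
#' @return data.frame with columns chrom, start, end, strand.
#' @examples
#' genomic_intervals("chr7", 106159393, 106159887)
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop(what, ": chromosome names must be non-empty")
  bad <- which(!(df$start < df$end))
  if (length(bad))
    stop(what, ": start must be < end (row ", bad[1], ": ",
         df$start[bad[1]], " >= ", df$end[bad[1]], ")")
  invisible(df)
}

#' Interval length under a named coordinate convention
#'
#' Half-open intervals have length `end - start`; 1-based inclusive
#' intervals (the convention of printed locus coordinates such as PCR
#' product spans) have length `end - start + 1`.
#'
#' @param start,end interval coordinates (vectorized).
#' @param convention `"half_open"` or `"one_based_inclusive"`.
#' @return integer lengths in bp.
#' @examples
#' interval_length(106159328, 106159998, "one_based_inclusive") # 671
#' interval_length(106159393, 106159887, "half_open")           # 494
#' @export
interval_length <- function(start, end,
                            convention = c("half_open", "one_based_inclusive")) {
  convention <- match.arg(convention)
  len <- switch(convention,
                half_open = end - start,
                one_based_inclusive = end - start + 1)
  if (any(len < 0)) stop("negative interval length")
  len
}

# data.frame (0-based half-open) -> GRanges (1-based inclusive).
intervals_to_gr <- function(df) {
  strand <- if ("strand" %in% names(df)) {
    s <- df$strand
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1, df$end),
                         strand = strand)
}

gr_to_intervals <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  s[s == "*"] <- "."
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             strand = s,
             stringsAsFactors = FALSE)
}

# Sort intervals by (chrom, start, end); stable.
sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

# Logical: does each interval in `a` overlap (>= 1 bp) any interval in `b`?
overlaps_any <- function(a, b) {
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  GenomicRanges::countOverlaps(intervals_to_gr(a), intervals_to_gr(b),
                               ignore.strand = TRUE) > 0
}
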