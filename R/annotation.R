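#' Classify peaks against gene structure
#'
#' Each peak gets exactly one feature class with precedence
#' `promoter_5utr > utr3 > exonic > intronic > intergenic`.  The promoter
#' window is the `promoter_bp` bases immediately upstream of the TSS on
#' the gene's strand, unioned with any annotated 5'-UTR; any >= 1 bp
#' overlap with a class's features assigns that class, subject to
#' precedence.  Intronic means overlap with a gene body without any
#' higher-precedence overlap.
#'
#' @param peaks peak set (interval table).
#' @param genes gene models (see [read_gene_table()]).
#' @param promoter_bp upstream promoter window (default 2 kb).
#' @return character vector of feature classes, one per peak.
#' @export
classify_peaks <- function(peaks, genes, promoter_bp = 2000) {
  n <- nrow(peaks)
  if (!n) return(character(0))
  cls <- rep("intergenic", n)
  if (!nrow(genes)) return(cls)
  prom <- promoter_windows(genes, promoter_bp)
  if (any(!is.na(genes$utr5_start)))
    prom <- rbind(prom, data.frame(
      chrom = genes$chrom[!is.na(genes$utr5_start)],
      start = genes$utr5_start[!is.na(genes$utr5_start)],
      end = genes$utr5_end[!is.na(genes$utr5_start)]))
  utr3 <- genes[!is.na(genes$utr3_start),
                c("chrom", "utr3_start", "utr3_end"), drop = FALSE]
  names(utr3) <- c("chrom", "start", "end")
  exons <- data.frame(
    chrom = rep(genes$chrom, lengths(genes$exon_starts)),
    start = unlist(genes$exon_starts),
    end = unlist(genes$exon_ends), stringsAsFactors = FALSE)
  body <- genes[, c("chrom", "start", "end")]
  cls[overlaps_any(peaks, body)] <- "intronic"
  cls[overlaps_any(peaks, exons)] <- "exonic"
  if (nrow(utr3)) cls[overlaps_any(peaks, utr3)] <- "utr3"
  cls[overlaps_any(peaks, prom)] <- "promoter_5utr"
  cls
}

# Promoter windows, strand-aware, 0-based half-open: [tss - w, tss) on the
# plus strand, [tss + 1, tss + 1 + w) on the minus strand.
promoter_windows <- function(genes, promoter_bp) {
  plus <- genes$strand != "-"
  data.frame(chrom = genes$chrom,
             start = ifelse(plus, pmax(0, genes$tss - promoter_bp),
                            genes$tss + 1),
             end = ifelse(plus, genes$tss, genes$tss + 1 + promoter_bp),
             stringsAsFactors = FALSE)
}

#' Signed distance from peaks to the nearest TSS
#'
#' The distance is measured from the peak midpoint to the nearest TSS over
#' all genes (any chromosome mismatch excludes a gene).  The sign is
#' negative when the midpoint lies upstream (5') of the TSS in the gene's
#' orientation.  Ties in absolute distance are broken by the
#' lexicographically smaller gene id.
#'
#' @param peaks peak set.
#' @param genes gene models with `tss` and `strand`.
#' @return data.frame with `nearest_gene_id` and signed `tss_distance_bp`.
#' @export
tss_distance <- function(peaks, genes) {
  if (!nrow(genes)) stop("tss_distance: no genes")
  mid <- floor((peaks$start + peaks$end) / 2)
  o <- order(genes$gene_id)
  genes <- genes[o, , drop = FALSE]
  nearest <- character(nrow(peaks)); dist <- numeric(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    sel <- genes$chrom == peaks$chrom[i]
    if (!any(sel)) { nearest[i] <- NA; dist[i] <- NA; next }
    g <- genes[sel, , drop = FALSE]
    d_abs <- abs(mid[i] - g$tss)
    j <- which.min(d_abs)  # first minimum = smallest gene_id (pre-sorted)
    signed <- (mid[i] - g$tss[j]) * ifelse(g$strand[j] == "-", -1, 1)
    nearest[i] <- g$gene_id[j]; dist[i] <- signed
  }
  data.frame(nearest_gene_id = nearest, tss_distance_bp = dist,
             stringsAsFactors = FALSE)
}

#' Summarize TSS proximity of a peak set
#'
#' @param tss_distances signed distances from [tss_distance()].
#' @param window_bp proximity window (default 20 kb).
#' @return list: `frac_within_window` (share of peaks with
#'   `|distance| <= window_bp`) and `mean_upstream_bp` (mean distance of
#'   the strictly upstream peaks, as a positive number; 0 when no peak is
#'   upstream).
#' @export
tss_summary <- function(tss_distances, window_bp = 20000) {
  d <- tss_distances$tss_distance_bp
  d <- d[!is.na(d)]
  if (!length(d)) stop("tss_summary: empty annotation set")
  up <- -d[d < 0]
  list(frac_within_window = mean(abs(d) <= window_bp),
       mean_upstream_bp = if (length(up)) mean(up) else 0)
}

#' Fold enrichment between two class fractions
#'
#' Ratio of the class fraction in shared peaks to the fraction in
#' cell-type-specific peaks, rounded to one decimal (the presentation used
#' for promoter/5'-UTR enrichment).
#'
#' @param frac_shared_pct,frac_specific_pct class percentages.
#' @return fold change, one decimal.
#' @examples
#' class_fraction_fold(28.4, 4.6) # 6.2
#' @export
class_fraction_fold <- function(frac_shared_pct, frac_specific_pct) {
  if (any(frac_specific_pct <= 0)) stop("zero denominator fraction")
  round(frac_shared_pct / frac_specific_pct, 1)
}

#' Full peak annotation table
#'
#' Convenience wrapper combining [classify_peaks()] and [tss_distance()].
#'
#' @inheritParams classify_peaks
#' @return the peak table with `feature_class`, `nearest_gene_id` and
#'   `tss_distance_bp` columns appended.
#' @export
annotate_peaks <- function(peaks, genes, promoter_bp = 2000) {
  out <- peaks
  out$feature_class <- classify_peaks(peaks, genes, promoter_bp)
  td <- tss_distance(peaks, genes)
  out$nearest_gene_id <- td$nearest_gene_id
  out$tss_distance_bp <- td$tss_distance_bp
  out
}
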