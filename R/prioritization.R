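#' Expand GWA index SNPs to their LD proxies
#'
#' Each index SNP maps to itself (r2 = 1.00) plus every panel SNP with
#' `r2 >= r2_min` to the index and `MAF >= maf_min`; no distance filter is
#' applied.
#'
#' @param index_snps character vector of index SNP ids.
#' @param ld canonicalized LD table (see [read_ld_table()]).
#' @param snps SNP panel (see [read_snp_panel()]).
#' @param r2_min,maf_min thresholds (defaults 0.8 and 0.05).
#' @return named list: per index SNP a data.frame `snp_id`, `r2` with the
#'   index itself first.
#' @export
expand_proxies <- function(index_snps, ld, snps, r2_min = 0.8,
                           maf_min = 0.05) {
  missing <- setdiff(index_snps, snps$snp_id)
  if (length(missing))
    stop("index SNP absent from panel: ", paste(missing, collapse = ", "))
  out <- lapply(index_snps, function(idx) {
    sel <- (ld$snp_a == idx | ld$snp_b == idx) & ld$snp_a != ld$snp_b
    partner <- ifelse(ld$snp_a[sel] == idx, ld$snp_b[sel], ld$snp_a[sel])
    r2 <- ld$r2[sel]
    keep <- r2 >= r2_min & partner %in% snps$snp_id
    if (any(keep)) {
      maf <- snps$maf[match(partner[keep], snps$snp_id)]
      keep2 <- maf >= maf_min
      partner <- partner[keep][keep2]; r2 <- r2[keep][keep2]
    } else {
      partner <- character(0); r2 <- numeric(0)
    }
    data.frame(snp_id = c(idx, partner), r2 = c(1.00, r2),
               stringsAsFactors = FALSE)
  })
  names(out) <- index_snps
  out
}

#' Intersect LD-expanded SNPs with cell-type-resolved NDRs
#'
#' A SNP lies in a peak when its (0-based) position falls in the half-open
#' interval `[start, end)`.  All peaks containing a SNP necessarily
#' overlap one another, so each reported SNP gets a single harboring
#' region (the union span of its containing peaks) and a cell-type
#' specificity derived from which cell types contribute a containing
#' peak: `"<type>_only"` when exactly one does, `"shared"` when all do.
#'
#' @param proxy_map output of [expand_proxies()].
#' @param snps SNP panel with 0-based `pos`.
#' @param peaks_by_celltype named list of condition-merged peak sets, one
#'   per cell type (e.g. `list(MK = ..., EB = ...)`).
#' @return data.frame of prioritized variants: snp_id, chrom, pos, maf,
#'   index_snp_id, r2_to_index, distance_to_index_bp, distance_kb,
#'   cell_specificity, peak_chrom, peak_start, peak_end.
#' @export
intersect_snps_ndrs <- function(proxy_map, snps, peaks_by_celltype) {
  stopifnot(length(names(peaks_by_celltype)) == length(peaks_by_celltype))
  rows <- list()
  for (idx in names(proxy_map)) {
    pm <- proxy_map[[idx]]
    idx_row <- snps[match(idx, snps$snp_id), ]
    for (k in seq_len(nrow(pm))) {
      srow <- snps[match(pm$snp_id[k], snps$snp_id), ]
      if (is.na(srow$snp_id)) next
      hits <- lapply(peaks_by_celltype, function(p) {
        if (!nrow(p)) return(p[0, , drop = FALSE])
        p[p$chrom == srow$chrom & p$start <= srow$pos & srow$pos < p$end, ,
          drop = FALSE]
      })
      in_type <- vapply(hits, nrow, integer(1)) > 0
      if (!any(in_type)) next
      spec <- if (all(in_type)) "shared"
              else paste0(names(which(in_type)), "_only")
      span <- do.call(rbind, lapply(hits[in_type],
                                    function(h) h[, c("chrom", "start", "end")]))
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = srow$snp_id, chrom = srow$chrom, pos = srow$pos,
        maf = srow$maf, index_snp_id = idx, r2_to_index = pm$r2[k],
        distance_to_index_bp = abs(srow$pos - idx_row$pos),
        distance_kb = round(abs(srow$pos - idx_row$pos) / 1000),
        cell_specificity = spec, peak_chrom = span$chrom[1],
        peak_start = min(span$start), peak_end = max(span$end),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(snp_id = character(0), chrom = character(0),
                      pos = numeric(0), maf = numeric(0),
                      index_snp_id = character(0), r2_to_index = numeric(0),
                      distance_to_index_bp = numeric(0),
                      distance_kb = numeric(0),
                      cell_specificity = character(0),
                      peak_chrom = character(0), peak_start = numeric(0),
                      peak_end = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Peak density in and around lineage-labelled genes
#'
#' Counts the peaks overlapping each gene body extended by `flank_bp` on
#' both sides and normalizes by the gene length (peaks per Mb of gene).
#'
#' @param peaks peak set.
#' @param genes gene models (typically filtered to one lineage label).
#' @param flank_bp flank around the gene body (default 2 kb).
#' @return data.frame gene_id, n_peaks, density_per_mb.
#' @export
lineage_peak_density <- function(peaks, genes, flank_bp = 2000) {
  flanked <- data.frame(chrom = genes$chrom,
                        start = pmax(0, genes$start - flank_bp),
                        end = genes$end + flank_bp,
                        stringsAsFactors = FALSE)
  n_peaks <- if (nrow(peaks))
    GenomicRanges::countOverlaps(intervals_to_gr(flanked),
                                 intervals_to_gr(peaks),
                                 ignore.strand = TRUE)
  else rep(0L, nrow(genes))
  len_mb <- (genes$end - genes$start) / 1e6
  data.frame(gene_id = genes$gene_id, n_peaks = as.integer(n_peaks),
             density_per_mb = n_peaks / len_mb, stringsAsFactors = FALSE)
}

.ranksum_cache <- new.env(parent = emptyenv())

# Exact null distribution of the rank sum of the first group: rank sums
# over all C(n, n1) subsets of the pooled (mid-)ranks.
ranksum_distribution <- function(r, n1) {
  n <- length(r)
  key <- paste(n1, paste(signif(sort(r), 12), collapse = ","), sep = "|")
  hit <- get0(key, envir = .ranksum_cache)
  if (!is.null(hit)) return(hit)
  idx <- combn(n, n1)
  dist <- colSums(matrix(r[idx], nrow = n1))
  assign(key, dist, envir = .ranksum_cache)
  dist
}

#' Wilcoxon rank-sum test for lineage peak enrichment
#'
#' Mann-Whitney/Wilcoxon rank-sum test comparing per-gene peak densities
#' between two cell types.  For combined sample sizes up to
#' `exact_max_n` the null distribution is obtained by exact enumeration of
#' all subset rank sums (mid-ranks handle ties, so the enumeration is a
#' full permutation test on the ranks); above that a normal approximation
#' with tie-corrected variance and continuity correction is used.
#'
#' @param x,y numeric samples (e.g. densities from
#'   [lineage_peak_density()]).
#' @param alternative `"two_sided"` (default), `"greater"` (x tends
#'   larger) or `"less"`.
#' @param exact_max_n largest combined n for exact enumeration.
#' @return list: `U` (Mann-Whitney U for `x`), `W` (rank sum of `x`),
#'   `p_value`, `method`.
#' @examples
#' lineage_enrichment_test(c(5, 6, 7, 8), c(1, 2, 3, 4), "greater")
#' @export
lineage_enrichment_test <- function(x, y,
                                    alternative = c("two_sided", "greater",
                                                    "less"),
                                    exact_max_n = 20) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 1 || n2 < 1) stop("both samples need at least one value")
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1)
    return(list(U = U, W = W, p_value = 1, method = "degenerate"))
  if (n <= exact_max_n) {
    dist <- ranksum_distribution(r, n1)
    eps <- 1e-9
    p_le <- mean(dist <= W + eps)
    p_ge <- mean(dist >= W - eps)
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two_sided = min(1, 2 * min(p_le, p_ge)))
    return(list(U = U, W = W, p_value = p, method = "exact enumeration"))
  }
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  cc <- 0.5
  z_ge <- (W - mu - cc) / sqrt(sigma2)
  z_le <- (W - mu + cc) / sqrt(sigma2)
  p <- switch(alternative,
              greater = pnorm(z_ge, lower.tail = FALSE),
              less = pnorm(z_le),
              two_sided = min(1, 2 * min(pnorm(z_le),
                                         pnorm(z_ge, lower.tail = FALSE))))
  list(U = U, W = W, p_value = p, method = "normal approximation")
}

#' Flag variants inside allele-differential motif intervals
#'
#' Consumes a table of externally predicted transcription-factor binding
#' motif intervals, annotated per allele (`"ref"`, `"alt"` or `"both"`).
#' A variant is flagged with every motif whose interval contains its
#' position and whose presence differs between the two alleles (i.e. the
#' substitution creates or disrupts the predicted site).
#'
#' @param variants prioritized variants (need `chrom`, `pos`).
#' @param motif_intervals data.frame `motif_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `allele`; or NULL for no motif data.
#' @return character vector of comma-separated motif ids (empty string
#'   when none), one per variant.
#' @export
annotate_motif_overlap <- function(variants, motif_intervals = NULL) {
  if (is.null(motif_intervals) || !nrow(motif_intervals))
    return(rep("", nrow(variants)))
  diffm <- motif_intervals[motif_intervals$allele != "both", , drop = FALSE]
  vapply(seq_len(nrow(variants)), function(i) {
    sel <- diffm$chrom == variants$chrom[i] &
      diffm$start <= variants$pos[i] & variants$pos[i] < diffm$end
    paste(sort(unique(diffm$motif_id[sel])), collapse = ",")
  }, character(1))
}
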