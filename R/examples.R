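#' Bundled worked example: seven NDR variants at cardiovascular trait loci
#'
#' The package ships a small table
#' (`inst/extdata/ndr_variants.tsv`) of seven reported sequence variants
#' located in nucleosome-depleted regions at hematological/cardiovascular
#' trait loci, with their cell-type specificity (MK, EB or both), MAF,
#' LD to the GWA index SNP and distance to it.  This function expands the
#' table into runnable prioritization inputs: a SNP panel, an LD table
#' and per-cell-type peak sets.  Genomic positions are not part of the
#' published table, so synthetic coordinates are laid out
#' deterministically (one chromosome per locus, index SNP at 1 Mb, proxy
#' offset by the reported distance, a 500 bp NDR around each variant);
#' only the relational structure is real.
#'
#' @param path the variant table (default: the bundled copy).
#' @return list: `variants` (the table), `snps`, `ld`,
#'   `peaks_by_celltype` (list with `MK` and `EB` peak sets), and
#'   `index_snps`.
#' @examples
#' ex <- example_prioritization_inputs()
#' pm <- expand_proxies(ex$index_snps, ex$ld, ex$snps)
#' hits <- intersect_snps_ndrs(pm, ex$snps, ex$peaks_by_celltype)
#' table(hits$cell_specificity)
#' @export
example_prioritization_inputs <- function(
    path = system.file("extdata", "ndr_variants.tsv",
                       package = "fairechip")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  n <- nrow(tab)
  chrom <- sprintf("chrL%02d", seq_len(n))
  idx_pos <- rep(1e6, n)
  snp_pos <- idx_pos + tab$distance_kb * 1000
  is_index <- tab$snp_id == tab$index_snp_id
  snp_rows <- data.frame(
    snp_id = c(tab$snp_id, tab$index_snp_id[!is_index]),
    chrom = c(chrom, chrom[!is_index]),
    pos = c(snp_pos, idx_pos[!is_index]),
    ref = "A", alt = "G",
    maf = c(tab$maf, rep(0.25, sum(!is_index))),
    stringsAsFactors = FALSE)
  ld <- canonicalize_ld(data.frame(snp_a = tab$index_snp_id,
                                   snp_b = tab$snp_id, r2 = tab$r2,
                                   stringsAsFactors = FALSE))
  peak <- data.frame(chrom = chrom, start = snp_pos - 200,
                     end = snp_pos + 300,
                     score_pct = 90, n_probes = 10L,
                     stringsAsFactors = FALSE)
  in_mk <- tab$cell_type %in% c("MK", "EB/MK")
  in_eb <- tab$cell_type %in% c("EB", "EB/MK")
  peaks <- list(MK = peak[in_mk, , drop = FALSE],
                EB = peak[in_eb, , drop = FALSE])
  list(variants = tab, snps = snp_rows, ld = ld,
       peaks_by_celltype = peaks, index_snps = unique(tab$index_snp_id))
}

#' Engineered peak sets with a prescribed shared-region count
#'
#' Builds two peak sets with exactly `n_a` and `n_b` peaks of which
#' `n_shared` form shared regions (one peak from each set overlapping
#' pairwise); the remainder are disjoint singletons.  Used to
#' demonstrate the cross-cell-type comparison arithmetic on published
#' peak counts.
#'
#' @param n_a,n_b peak counts per set.
#' @param n_shared number of shared regions (`<= min(n_a, n_b)`).
#' @return list of two peak data.frames `a` and `b`.
#' @examples
#' ps <- engineered_peak_sets(254, 251, 147)
#' compare_cell_types(ps$a, ps$b)
#' @export
engineered_peak_sets <- function(n_a, n_b, n_shared) {
  if (n_shared > min(n_a, n_b)) stop("n_shared larger than a side")
  step <- 1000
  mk_peak <- function(i, off) {
    data.frame(chrom = "chrE", start = i * step + off,
               end = i * step + off + 400, score_pct = 50,
               n_probes = 5L, stringsAsFactors = FALSE)
  }
  shared_a <- do.call(rbind, lapply(seq_len(n_shared), mk_peak, off = 0))
  shared_b <- do.call(rbind, lapply(seq_len(n_shared), mk_peak, off = 200))
  only_a <- do.call(rbind, lapply(seq_len(n_a - n_shared) + n_shared + n_b,
                                  mk_peak, off = 0))
  only_b <- do.call(rbind, lapply(seq_len(n_b - n_shared) + n_shared +
                                    n_a + n_b, mk_peak, off = 0))
  list(a = rbind(shared_a, only_a), b = rbind(shared_b, only_b))
}
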