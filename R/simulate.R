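#' Simulate a panel of trait-associated loci with gene models
#'
#' Emulates the layout of a custom tiling array interrogating a set of
#' GWA loci: `n_loci` non-overlapping loci (placed consecutively on one
#' synthetic chromosome, separated by 10 kb spacers) each carrying
#' `genes_per_locus` non-overlapping genes with a TSS, 2-4 exons and
#' 5'/3'-UTRs.  A subset of genes is labelled with a lineage
#' (`MK`/`EB`/`MONO`, default 8 genes per lineage, mirroring
#' lineage-specific reference gene sets).
#'
#' @param n_loci number of loci (default 62).
#' @param locus_length_bp locus length (default 155 kb, so the default
#'   panel spans ~9.6 Mb, matching a ~62-locus tiling design).
#' @param genes_per_locus genes per locus.
#' @param lineage_genes number of genes labelled per lineage (default 8).
#' @param seed integer seed.
#' @return list: `loci` (interval data.frame with `locus_id`) and `genes`
#'   (gene-model data.frame, see [read_gene_table()]).
#' @export
simulate_locus_panel <- function(n_loci = 62, locus_length_bp = 155000,
                                 genes_per_locus = 3, lineage_genes = 8,
                                 seed = 1) {
  if (n_loci < 1) stop("n_loci must be >= 1")
  slot <- floor(locus_length_bp / genes_per_locus)
  if (slot < 2000)
    stop("locus_length_bp too small for ", genes_per_locus, " genes")
  withr::with_seed(seed, {
    gap <- 10000
    starts <- (seq_len(n_loci) - 1) * (locus_length_bp + gap)
    loci <- data.frame(chrom = "chrS", start = starts,
                       end = starts + locus_length_bp,
                       locus_id = sprintf("locus_%02d", seq_len(n_loci)),
                       stringsAsFactors = FALSE)
    rows <- vector("list", n_loci * genes_per_locus)
    gid <- 0
    for (i in seq_len(n_loci)) {
      for (j in seq_len(genes_per_locus)) {
        gid <- gid + 1
        slot_start <- loci$start[i] + (j - 1) * slot
        glen <- round(slot * runif(1, 0.3, 0.6))
        gstart <- slot_start + round(slot * runif(1, 0.05, 0.3))
        gend <- gstart + glen
        strand <- sample(c("+", "-"), 1)
        n_ex <- sample(2:4, 1)
        cuts <- sort(sample(seq(gstart + 50, gend - 50, by = 50),
                            2 * (n_ex - 1)))
        es <- c(gstart, cuts[seq_along(cuts) %% 2 == 0])
        ee <- c(cuts[seq_along(cuts) %% 2 == 1], gend)
        tss <- if (strand == "+") gstart else gend - 1
        if (strand == "+") {
          utr5 <- c(gstart, min(gstart + 150, ee[1]))
          utr3 <- c(max(es[n_ex], gend - 150), gend)
        } else {
          utr5 <- c(max(es[n_ex], gend - 150), gend)
          utr3 <- c(gstart, min(gstart + 150, ee[1]))
        }
        rows[[gid]] <- data.frame(
          gene_id = sprintf("gene_%03d", gid), chrom = loci$chrom[i],
          start = gstart, end = gend, strand = strand, tss = tss,
          utr5_start = utr5[1], utr5_end = utr5[2],
          utr3_start = utr3[1], utr3_end = utr3[2],
          lineage = "none", locus_id = loci$locus_id[i],
          stringsAsFactors = FALSE)
        rows[[gid]]$exon_starts <- list(es)
        rows[[gid]]$exon_ends <- list(ee)
      }
    }
    genes <- do.call(rbind, rows)
    lineages <- c("MK", "EB", "MONO")
    n_label <- min(lineage_genes * length(lineages), nrow(genes))
    if (n_label > 0) {
      pick <- sample(nrow(genes), n_label)
      genes$lineage[pick] <- rep(lineages, length.out = n_label)
    }
    validate_genes(genes)
    list(loci = loci, genes = genes)
  })
}

#' Simulate planted nucleosome-depleted regions (truth set)
#'
#' Places `ndrs_per_locus` non-overlapping NDRs of length `ndr_length_bp`
#' uniformly in each locus and assigns each one either to both cell types
#' (with probability `shared_fraction`) or to a single cell type chosen
#' uniformly.
#'
#' @param loci locus table from [simulate_locus_panel()].
#' @param ndrs_per_locus,ndr_length_bp NDR count and width.
#' @param shared_fraction probability an NDR is open in both cell types.
#' @param cell_types cell-type labels.
#' @param min_gap_bp minimum spacing between adjacent NDRs (default one
#'   sliding-window width, so distinct planted elements stay resolvable).
#' @param seed integer seed.
#' @return data.frame chrom, start, end, cell_type (`"shared"` or one of
#'   `cell_types`).
#' @export
simulate_truth_ndrs <- function(loci, ndrs_per_locus = 3,
                                ndr_length_bp = 500, shared_fraction = 0.6,
                                cell_types = c("MK", "EB"),
                                min_gap_bp = 300, seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(loci))) {
      span <- loci$end[i] - loci$start[i]
      k <- ndrs_per_locus
      # lay NDRs on a grid of k equal bins so they never overlap
      bin <- floor(span / k)
      if (bin <= ndr_length_bp + min_gap_bp)
        stop("locus too small for requested NDRs")
      off <- round(runif(k, min_gap_bp / 2,
                         bin - ndr_length_bp - min_gap_bp / 2))
      s <- loci$start[i] + (seq_len(k) - 1) * bin + off
      ct <- ifelse(runif(k) < shared_fraction, "shared",
                   sample(cell_types, k, replace = TRUE))
      rows[[i]] <- data.frame(chrom = loci$chrom[i], start = s,
                              end = s + ndr_length_bp, cell_type = ct,
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate the tiling-probe layout over a locus panel
#'
#' Tiles each locus with probes whose start-to-start spans are uniform
#' integers centred on `mean_span_bp` (+- 10 bp) and whose lengths are
#' uniform on `probe_len_range`, emulating a 50-75-mer design with a
#' ~23 bp mean probe span.  Ratios are initialized to zero; add signal
#' with [simulate_faire_signal()].
#'
#' @param loci locus table.
#' @param mean_span_bp target mean inter-probe span (default 23).
#' @param probe_len_range probe length range (default 50-75).
#' @param seed integer seed.
#' @return an unscaled [probe_track()] with condition `"template"`.
#' @export
simulate_probe_track <- function(loci, mean_span_bp = 23,
                                 probe_len_range = c(50, 75), seed = 1) {
  if (mean_span_bp <= 0) stop("mean_span_bp must be positive")
  jitter <- min(10, mean_span_bp - 1)
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(loci))) {
      span <- loci$end[i] - loci$start[i]
      n_max <- ceiling(span / max(1, mean_span_bp - jitter)) + 1
      gaps <- sample(seq(mean_span_bp - jitter, mean_span_bp + jitter),
                     n_max, replace = TRUE)
      s <- loci$start[i] + c(0, cumsum(gaps))
      s <- s[s < loci$end[i]]
      rows[[i]] <- data.frame(
        chrom = loci$chrom[i], start = s,
        length = sample(seq(probe_len_range[1], probe_len_range[2]),
                        length(s), replace = TRUE),
        stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    probe_track(df$chrom, df$start, df$length, 0, condition = "template")
  })
}

#' Simulate FAIRE enrichment signal on a probe track
#'
#' For every condition label, probes whose start lies inside a truth NDR
#' get a mean log2 ratio of `baseline + enrichment_log2` (optionally
#' perturbed per condition by a Gaussian jitter with SD
#' `condition_jitter`, emulating cross-linking-time differences); all
#' other probes sit at `baseline`.  I.i.d. Gaussian noise with SD
#' `noise_sd` is added throughout.
#'
#' @param track template track from [simulate_probe_track()].
#' @param truth_ndrs intervals open in this cell type.
#' @param enrichment_log2 planted enrichment (log2 units, > 0).
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param conditions condition labels (default 8 and 12 min cross-link).
#' @param condition_jitter SD of the per-condition enrichment perturbation.
#' @param baseline background log2 ratio.
#' @param seed integer seed.
#' @return an unscaled multi-condition [probe_track()].
#' @export
simulate_faire_signal <- function(track, truth_ndrs, enrichment_log2 = 2,
                                  noise_sd = 0.5,
                                  conditions = c("8min", "12min"),
                                  condition_jitter = 0, baseline = 0,
                                  seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  withr::with_seed(seed, {
    inside <- rep(FALSE, nrow(track))
    if (nrow(truth_ndrs)) {
      for (i in seq_len(nrow(truth_ndrs))) {
        inside <- inside | (track$chrom == truth_ndrs$chrom[i] &
                              track$start >= truth_ndrs$start[i] &
                              track$start < truth_ndrs$end[i])
      }
    }
    out <- list()
    for (cond in conditions) {
      enr <- enrichment_log2 +
        if (condition_jitter > 0) rnorm(1, 0, condition_jitter) else 0
      ratio <- baseline + ifelse(inside, enr, 0) +
        if (noise_sd > 0) rnorm(nrow(track), 0, noise_sd) else 0
      out[[cond]] <- data.frame(chrom = track$chrom, start = track$start,
                                length = track$length, log2_ratio = ratio,
                                condition = cond, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, out)
    probe_track(df$chrom, df$start, df$length, df$log2_ratio,
                condition = df$condition)
  })
}

#' Simulate an index-SNP / LD-proxy panel
#'
#' Each index SNP is placed in its own locus together with
#' `proxies_per_index` proxy SNPs; LD is star-shaped around the index
#' (index-proxy r2 drawn from `r2_dist`), matching how proxy search
#' engines report LD.  The LD table carries the index self pair
#' (r2 = 1) explicitly.
#'
#' @param loci locus table.
#' @param n_index number of index SNPs (must be <= number of loci).
#' @param proxies_per_index proxies per index SNP (>= 0).
#' @param r2_dist,maf_dist functions `n -> values` drawing r2 and MAF
#'   (defaults: r2 ~ U(0.5, 1), MAF ~ U(0.05, 0.5)).
#' @param seed integer seed.
#' @return list: `snps` (panel with 0-based `pos`) and `ld`
#'   (canonicalized LD table).
#' @export
simulate_ld_panel <- function(loci, n_index = 7, proxies_per_index = 10,
                              r2_dist = function(n) runif(n, 0.5, 1),
                              maf_dist = function(n) runif(n, 0.05, 0.5),
                              seed = 1) {
  if (proxies_per_index < 0) stop("proxies_per_index must be >= 0")
  if (n_index > nrow(loci)) stop("more index SNPs than loci")
  withr::with_seed(seed, {
    snp_rows <- list(); ld_rows <- list()
    which_loci <- sample(nrow(loci), n_index)
    for (k in seq_len(n_index)) {
      li <- which_loci[k]
      idx_id <- sprintf("rsIDX%03d", k)
      pos <- sort(sample(loci$start[li]:(loci$end[li] - 1),
                         proxies_per_index + 1))
      ids <- c(idx_id, sprintf("rsPX%03d_%02d", k,
                               seq_len(proxies_per_index)))
      maf <- maf_dist(proxies_per_index + 1)
      snp_rows[[k]] <- data.frame(snp_id = ids, chrom = loci$chrom[li],
                                  pos = pos, ref = "A", alt = "G",
                                  maf = maf, stringsAsFactors = FALSE)
      r2 <- if (proxies_per_index > 0) r2_dist(proxies_per_index) else numeric(0)
      ld_rows[[k]] <- data.frame(
        snp_a = c(idx_id, rep(idx_id, proxies_per_index)),
        snp_b = c(idx_id, ids[-1]),
        r2 = c(1, r2), stringsAsFactors = FALSE)
    }
    snps <- do.call(rbind, snp_rows)
    rownames(snps) <- NULL
    list(snps = snps, ld = canonicalize_ld(do.call(rbind, ld_rows)))
  })
}

#' Simulate a group-structured expression matrix with planted fold changes
#'
#' Genes have uniform baseline log2 expression in (6, 12); `n_de` planted
#' differentially expressed genes shift the mean of the first group by
#' `+-log2_fc` (random sign); i.i.d. Gaussian noise with SD `noise_sd` is
#' added.  Detection P-values are assigned per gene and sample:
#' expressed genes (fraction `expressed_fraction`) draw from U(0, 0.005),
#' the rest from U(0.02, 1).
#'
#' @param n_genes number of genes.
#' @param groups named integer vector of samples per group,
#'   e.g. `c(KO = 3, WT = 3)`.
#' @param n_de number of planted DE genes.
#' @param log2_fc planted absolute log2 fold change (first group minus
#'   second).
#' @param noise_sd Gaussian noise SD.
#' @param expressed_fraction fraction of genes detected as expressed.
#' @param seed integer seed.
#' @return list: `expr` (an [expression_matrix()]) and `truth`
#'   (data.frame gene_id, true_log2_fc).
#' @export
simulate_expression <- function(n_genes = 500, groups = c(KO = 3, WT = 3),
                                n_de = 50, log2_fc = 1.5, noise_sd = 0.3,
                                expressed_fraction = 0.8, seed = 1) {
  if (length(groups) < 2) stop("need at least two groups")
  if (n_de > n_genes) stop("n_de cannot exceed n_genes")
  withr::with_seed(seed, {
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    sample_ids <- unlist(lapply(names(groups), function(g)
      sprintf("%s_%d", g, seq_len(groups[[g]]))))
    group_of <- rep(names(groups), unlist(groups))
    base <- runif(n_genes, 6, 12)
    true_fc <- rep(0, n_genes)
    if (n_de > 0) {
      de_idx <- sample(n_genes, n_de)
      true_fc[de_idx] <- log2_fc * sample(c(-1, 1), n_de, replace = TRUE)
    }
    mu <- outer(base, rep(1, length(group_of)))
    mu[, group_of == names(groups)[1]] <-
      mu[, group_of == names(groups)[1]] + true_fc
    values <- mu + if (noise_sd > 0)
      matrix(rnorm(length(mu), 0, noise_sd), nrow = n_genes) else 0
    dimnames(values) <- list(gene_ids, sample_ids)
    expressed <- runif(n_genes) < expressed_fraction
    detection <- matrix(NA_real_, n_genes, length(sample_ids),
                        dimnames = dimnames(values))
    detection[expressed, ] <- runif(sum(expressed) * ncol(detection),
                                    0, 0.005)
    detection[!expressed, ] <- runif(sum(!expressed) * ncol(detection),
                                     0.02, 1)
    expr <- expression_matrix(values, setNames(group_of, sample_ids),
                              detection)
    list(expr = expr,
         truth = data.frame(gene_id = gene_ids, true_log2_fc = true_fc,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a seed-centred interactome with detection P-values
#'
#' Generates first-order interactors around a set of core proteins:
#' every core-interactor and interactor-interactor pair becomes an edge
#' independently with probability `edge_density`.  A fraction
#' `expressed_fraction` of interactors receives a detection P <= 0.01
#' (expressed); cores are always expressed.
#'
#' @param core_ids character vector of core protein ids.
#' @param n_interactors number of candidate interactors.
#' @param edge_density edge probability.
#' @param expressed_fraction fraction of interactors detected as
#'   expressed.
#' @param seed integer seed.
#' @return list: `interactions` (canonicalized pair table) and
#'   `detection` (data.frame protein_id, detection_p).
#' @export
simulate_interactome <- function(core_ids, n_interactors = 100,
                                 edge_density = 0.05,
                                 expressed_fraction = 0.7, seed = 1) {
  withr::with_seed(seed, {
    inter_ids <- sprintf("INT%03d", seq_len(n_interactors))
    all_ids <- c(core_ids, inter_ids)
    pairs <- t(combn(all_ids, 2))
    keep <- runif(nrow(pairs)) < edge_density
    interactions <- canonicalize_interactions(
      data.frame(protein_a = pairs[keep, 1], protein_b = pairs[keep, 2],
                 stringsAsFactors = FALSE))
    n_expr <- round(expressed_fraction * n_interactors)
    expressed <- c(rep(TRUE, length(core_ids)),
                   sample(rep(c(TRUE, FALSE),
                              c(n_expr, n_interactors - n_expr))))
    detection <- data.frame(
      protein_id = all_ids,
      detection_p = ifelse(expressed, runif(length(all_ids), 0, 0.009),
                           runif(length(all_ids), 0.02, 1)),
      stringsAsFactors = FALSE)
    list(interactions = interactions, detection = detection)
  })
}

#' Simulate a full FAIRE-chip experiment
#'
#' Umbrella generator: locus panel with genes, planted truth NDRs shared
#' between two cell types, a tiling-probe template and noisy
#' two-condition signal tracks per cell type.  Per-stage seeds are
#' derived deterministically from the single global seed.
#'
#' @param n_loci,locus_length_bp,genes_per_locus see
#'   [simulate_locus_panel()].
#' @param ndrs_per_locus,ndr_length_bp,shared_fraction see
#'   [simulate_truth_ndrs()].
#' @param enrichment_log2,noise_sd,conditions,condition_jitter see
#'   [simulate_faire_signal()].
#' @param cell_types cell-type labels.
#' @param seed global integer seed.
#' @return list: `loci`, `genes`, `truth`, and `tracks` (named list of
#'   multi-condition probe tracks per cell type).
#' @export
simulate_faire_experiment <- function(n_loci = 62, locus_length_bp = 155000,
                                      genes_per_locus = 3,
                                      ndrs_per_locus = 3,
                                      ndr_length_bp = 500,
                                      shared_fraction = 0.6,
                                      enrichment_log2 = 2, noise_sd = 0.5,
                                      conditions = c("8min", "12min"),
                                      condition_jitter = 0.2,
                                      cell_types = c("MK", "EB"),
                                      seed = 1) {
  panel <- simulate_locus_panel(n_loci, locus_length_bp, genes_per_locus,
                                seed = derive_seed(seed, 1))
  truth <- simulate_truth_ndrs(panel$loci, ndrs_per_locus, ndr_length_bp,
                               shared_fraction, cell_types,
                               seed = derive_seed(seed, 2))
  template <- simulate_probe_track(panel$loci, seed = derive_seed(seed, 3))
  tracks <- lapply(seq_along(cell_types), function(k) {
    ct <- cell_types[k]
    ndrs <- truth[truth$cell_type %in% c("shared", ct), , drop = FALSE]
    simulate_faire_signal(template, ndrs, enrichment_log2, noise_sd,
                          conditions, condition_jitter,
                          seed = derive_seed(seed, 10 + k))
  })
  names(tracks) <- cell_types
  list(loci = panel$loci, genes = panel$genes, truth = truth,
       tracks = tracks)
}
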