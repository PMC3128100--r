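make_panel <- function(n, seed) {
  withr::with_seed(seed, {
    data.frame(snp_id = sprintf("rs%03d", seq_len(n)), chrom = "c1",
               pos = sort(sample(1e6, n)),
               maf = round(runif(n, 0.01, 0.5), 3),
               stringsAsFactors = FALSE)
  })
}

test_that("proxy expansion applies the r2 and MAF thresholds exactly", {
  snps <- data.frame(snp_id = c("idx", "p1", "p2", "p3"), chrom = "c1",
                     pos = c(100, 200, 300, 400),
                     maf = c(0.3, 0.2, 0.04, 0.2))
  ld <- canonicalize_ld(data.frame(
    snp_a = "idx", snp_b = c("p1", "p2", "p3"), r2 = c(0.85, 0.9, 0.79)))
  pm <- expand_proxies("idx", ld, snps)
  expect_equal(pm$idx$snp_id, c("idx", "p1"))  # p2 fails MAF, p3 fails r2
  expect_equal(pm$idx$r2, c(1.00, 0.85))
  # an index with no partners maps to itself at r2 = 1
  lone <- expand_proxies("p3", ld, snps, r2_min = 0.999)
  expect_equal(lone$p3$snp_id, "p3")
  expect_equal(lone$p3$r2, 1.00)
  expect_error(expand_proxies("nope", ld, snps), "nope")
})

test_that("proxy expansion equals a brute-force filter and is monotone", {
  snps <- make_panel(60, seed = 81)
  withr::with_seed(82, {
    ld <- canonicalize_ld(data.frame(
      snp_a = sample(snps$snp_id, 150, replace = TRUE),
      snp_b = sample(snps$snp_id, 150, replace = TRUE),
      r2 = 1))
    ld$r2 <- round(runif(nrow(ld), 0.4, 1), 3)
  })
  idx <- snps$snp_id[1]
  for (r2min in c(0.5, 0.8, 0.95)) {
    pm <- expand_proxies(idx, ld, snps, r2_min = r2min)[[1]]
    # brute force over the mirrored table
    partners <- unique(c(ld$snp_b[ld$snp_a == idx & ld$snp_b != idx &
                                    ld$r2 >= r2min],
                         ld$snp_a[ld$snp_b == idx & ld$snp_a != idx &
                                    ld$r2 >= r2min]))
    partners <- partners[snps$maf[match(partners, snps$snp_id)] >= 0.05]
    expect_setequal(pm$snp_id, union(idx, partners))
    expect_true(idx %in% pm$snp_id)
  }
  n_at <- vapply(c(0.5, 0.8, 0.95), function(r)
    nrow(expand_proxies(idx, ld, snps, r2_min = r)[[1]]), numeric(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("the bundled seven-variant example reproduces reported counts", {
  ex <- example_prioritization_inputs()
  pm <- expand_proxies(ex$index_snps, ex$ld, ex$snps)
  hits <- intersect_snps_ndrs(pm, ex$snps, ex$peaks_by_celltype)
  counts <- table(hits$cell_specificity)
  expect_equal(unname(counts[["MK_only"]]), 2)
  expect_equal(unname(counts[["EB_only"]]), 1)
  expect_equal(unname(counts[["shared"]]), 4)
  # every reported variant really lies inside its harboring region
  expect_true(all(hits$peak_start <= hits$pos & hits$pos < hits$peak_end))
  # reported distances match the bundled table
  m <- match(hits$snp_id, ex$variants$snp_id)
  expect_equal(hits$distance_kb, ex$variants$distance_kb[m])
})

test_that("SNP-in-peak containment is half-open", {
  snps <- data.frame(snp_id = c("sA", "sB"), chrom = "c1",
                     pos = c(500, 600), maf = 0.3)
  peaks <- data.frame(chrom = "c1", start = 500, end = 600)
  pm <- list(sA = data.frame(snp_id = c("sA", "sB"), r2 = c(1, 0.9)))
  hits <- intersect_snps_ndrs(pm, snps, list(MK = peaks, EB = peaks))
  expect_equal(hits$snp_id, "sA")  # position 600 == end is outside
})

test_that("random SNP/peak intersection equals the containment oracle", {
  withr::with_seed(83, {
    snps <- make_panel(80, seed = 84)
    peaks <- random_intervals(40, seed = 85, chroms = "c1", span = 1e6)
    pm <- list(idx = data.frame(snp_id = snps$snp_id,
                                r2 = runif(80, 0.8, 1)))
    snps2 <- rbind(snps[1, ], snps); snps2$snp_id[1] <- "idx"
    hits <- intersect_snps_ndrs(pm, snps2, list(MK = peaks, EB = peaks[0, ]))
    inside <- vapply(seq_len(nrow(snps)), function(i)
      any(peaks$start <= snps$pos[i] & snps$pos[i] < peaks$end),
      logical(1))
    expect_setequal(hits$snp_id, snps$snp_id[inside])
    expect_true(all(hits$cell_specificity == "MK_only"))
  })
})

test_that("lineage peak densities are counts per Mb of gene", {
  gene <- data.frame(gene_id = "g1", chrom = "c1", start = 100000,
                     end = 200000, stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "c1", start = c(120000, 150000),
                      end = c(120500, 150500))
  d <- lineage_peak_density(peaks, gene)
  expect_equal(d$density_per_mb, 20)
  expect_equal(lineage_peak_density(peaks[0, ], gene)$density_per_mb, 0)
  # flank inclusion: a peak 1 kb past the gene end still counts
  near <- data.frame(chrom = "c1", start = 201000, end = 201200)
  expect_equal(lineage_peak_density(near, gene)$n_peaks, 1L)
  far <- data.frame(chrom = "c1", start = 203000, end = 203200)
  expect_equal(lineage_peak_density(far, gene)$n_peaks, 0L)
})

test_that("exact rank-sum P-values match closed-form separations", {
  expect_equal(lineage_enrichment_test(c(9, 9, 9), c(9, 9, 9))$p_value, 1)
  expect_equal(lineage_enrichment_test(c(3, 4), c(1, 2),
                                       "greater")$p_value, 1 / 6)
  expect_equal(lineage_enrichment_test(9:16, 1:8,
                                       "greater")$p_value, 1 / 12870)
})

test_that("exact rank-sum matches wilcox.test on tie-free samples", {
  withr::with_seed(91, {
    for (i in 1:25) {
      n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
      x <- rnorm(n1); y <- rnorm(n2)
      mine <- lineage_enrichment_test(x, y)
      ref <- wilcox.test(x, y, exact = TRUE)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
      expect_equal(mine$U, unname(ref$statistic))
      mg <- lineage_enrichment_test(x, y, "greater")
      rg <- wilcox.test(x, y, alternative = "greater", exact = TRUE)
      expect_equal(mg$p_value, rg$p.value, tolerance = 1e-12)
    }
  })
})

test_that("tied samples are scored against direct enumeration", {
  x <- c(1, 2, 2, 5); y <- c(2, 3, 3)
  mine <- lineage_enrichment_test(x, y, "greater")
  r <- rank(c(x, y))
  sums <- combn(7, 4, function(ii) sum(r[ii]))
  expect_equal(mine$p_value, mean(sums >= sum(r[1:4]) - 1e-9))
})

test_that("large samples fall back to the corrected normal approximation", {
  withr::with_seed(92, {
    x <- rnorm(25); y <- rnorm(25, 0.8)
    mine <- lineage_enrichment_test(x, y)
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(mine$method, "normal approximation")
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  })
})

test_that("motif flags mark allele-differential containment only", {
  motifs <- data.frame(motif_id = c("EVI1", "GATA1", "RUNX1"),
                       chrom = "c1", start = c(100, 100, 400),
                       end = c(120, 120, 420),
                       allele = c("ref", "ref", "both"),
                       stringsAsFactors = FALSE)
  vars <- data.frame(chrom = "c1", pos = c(110, 410, 900))
  flags <- annotate_motif_overlap(vars, motifs)
  expect_equal(flags, c("EVI1,GATA1", "", ""))
  expect_equal(annotate_motif_overlap(vars, NULL), c("", "", ""))
})
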