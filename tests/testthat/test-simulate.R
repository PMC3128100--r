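test_that("locus panels honour their layout contract", {
  one <- simulate_locus_panel(n_loci = 1, locus_length_bp = 20000,
                              genes_per_locus = 1, seed = 3)
  expect_equal(nrow(one$loci), 1)
  expect_equal(nrow(one$genes), 1)
  expect_true(one$genes$start >= one$loci$start &&
                one$genes$end <= one$loci$end)

  def <- simulate_locus_panel(seed = 4)
  expect_equal(nrow(def$loci), 62)
  footprint <- sum(def$loci$end - def$loci$start)
  expect_lt(abs(footprint - 62 * 155000) / (62 * 155000), 0.05)
  # loci do not overlap
  expect_true(all(def$loci$start[-1] >= def$loci$end[-62]))
  # 8 genes labelled per lineage
  expect_equal(unname(table(def$genes$lineage)[c("MK", "EB", "MONO")]),
               rep(8L, 3), ignore_attr = TRUE)

  again <- simulate_locus_panel(seed = 4)
  expect_identical(def, again)
  expect_error(simulate_locus_panel(locus_length_bp = 3000,
                                    genes_per_locus = 10), "too small")
})

test_that("probe layouts reach the target span and length ranges", {
  loci <- data.frame(chrom = "chrS", start = 0, end = 1e5,
                     locus_id = "L1")
  tr <- simulate_probe_track(loci, seed = 6)
  spans <- diff(tr$start)
  expect_gt(mean(spans), 23 * 0.9)
  expect_lt(mean(spans), 23 * 1.1)
  expect_true(all(tr$length >= 50 & tr$length <= 75))
  expect_identical(tr, simulate_probe_track(loci, seed = 6))
  expect_error(simulate_probe_track(loci, mean_span_bp = 0), "positive")
})

test_that("noise-free signal plants the exact enrichment", {
  loci <- data.frame(chrom = "chrS", start = 0, end = 2e4, locus_id = "L1")
  tmpl <- simulate_probe_track(loci, seed = 7)
  ndr <- data.frame(chrom = "chrS", start = 5000, end = 5500)
  sig <- simulate_faire_signal(tmpl, ndr, enrichment_log2 = 2,
                               noise_sd = 0, condition_jitter = 0,
                               conditions = "12min", seed = 8)
  inside <- sig$start >= 5000 & sig$start < 5500
  expect_true(all(sig$log2_ratio[inside] == 2))
  expect_true(all(sig$log2_ratio[!inside] == 0))
  expect_error(simulate_faire_signal(tmpl, ndr, noise_sd = -1), "noise_sd")
})

test_that("planted enrichment is recovered within CLT error", {
  loci <- data.frame(chrom = "chrS", start = 0, end = 5e4, locus_id = "L1")
  tmpl <- simulate_probe_track(loci, seed = 9)
  ndr <- data.frame(chrom = "chrS", start = 10000, end = 15000)
  sig <- simulate_faire_signal(tmpl, ndr, enrichment_log2 = 2,
                               noise_sd = 0.5, condition_jitter = 0,
                               conditions = "8min", seed = 10)
  inside <- sig$start >= 10000 & sig$start < 15000
  n <- sum(inside)
  expect_lt(abs(mean(sig$log2_ratio[inside]) - 2), 3 * 0.5 / sqrt(n))
})

test_that("a null signal leaves no planted mean difference", {
  loci <- data.frame(chrom = "chrS", start = 0, end = 5e4, locus_id = "L1")
  tmpl <- simulate_probe_track(loci, seed = 11)
  ndr <- data.frame(chrom = "chrS", start = 10000, end = 15000)
  sig <- simulate_faire_signal(tmpl, ndr, enrichment_log2 = 0,
                               noise_sd = 0.3, condition_jitter = 0,
                               conditions = "8min", seed = 12)
  inside <- sig$start >= 10000 & sig$start < 15000
  expect_lt(abs(mean(sig$log2_ratio[inside]) -
                  mean(sig$log2_ratio[!inside])),
            4 * 0.3 / sqrt(sum(inside)))
})

test_that("LD panels are star-shaped with in-range draws", {
  loci <- data.frame(chrom = "chrS", start = c(0, 5e4),
                     end = c(4e4, 9e4), locus_id = c("L1", "L2"))
  lone <- simulate_ld_panel(loci, n_index = 1, proxies_per_index = 0,
                            seed = 13)
  expect_equal(nrow(lone$ld), 1)
  expect_equal(lone$ld$snp_a, lone$ld$snp_b)
  expect_equal(lone$ld$r2, 1)

  full <- simulate_ld_panel(loci, n_index = 2, proxies_per_index = 8,
                            seed = 14)
  expect_true(all(full$ld$r2 >= 0 & full$ld$r2 <= 1))
  expect_true(all(full$snps$maf > 0 & full$snps$maf <= 0.5))
  expect_equal(nrow(full$snps), 18)
  # proxies stay inside their index SNP's locus
  for (i in 1:2) {
    in_locus <- full$snps$pos >= loci$start[i] & full$snps$pos < loci$end[i]
    expect_true(sum(in_locus) %in% c(0, 9))
  }
  expect_identical(full, simulate_ld_panel(loci, n_index = 2,
                                           proxies_per_index = 8,
                                           seed = 14))
  expect_error(simulate_ld_panel(loci, proxies_per_index = -1), ">= 0")
})

test_that("expression simulation plants recoverable structure", {
  noiseless <- simulate_expression(n_genes = 30, n_de = 5, noise_sd = 0,
                                   seed = 15)
  de <- differential_expression(noiseless$expr, "KO", "WT")
  m <- match(noiseless$truth$gene_id, de$gene_id)
  expect_equal(de$log2_fc[m], noiseless$truth$true_log2_fc,
               tolerance = 1e-12)

  null <- simulate_expression(n_genes = 30, n_de = 0, noise_sd = 0,
                              seed = 16)
  de0 <- differential_expression(null$expr, "KO", "WT", fc_min = 1.0001)
  expect_false(any(de0$passes_fc))

  expect_identical(simulate_expression(seed = 17),
                   simulate_expression(seed = 17))
  expect_error(simulate_expression(n_genes = 5, n_de = 6), "exceed")
})

test_that("interactome simulation respects density and expression knobs", {
  none <- simulate_interactome("C1", n_interactors = 20, edge_density = 0,
                               seed = 18)
  expect_equal(nrow(none$interactions), 0)

  all_expr <- simulate_interactome(c("C1", "C2"), n_interactors = 25,
                                   edge_density = 0.2,
                                   expressed_fraction = 1, seed = 19)
  net <- build_ppi_network(c("C1", "C2"), all_expr$interactions,
                           all_expr$detection)
  expect_equal(length(net$dropped_interactors), 0)
  expect_identical(all_expr,
                   simulate_interactome(c("C1", "C2"), n_interactors = 25,
                                        edge_density = 0.2,
                                        expressed_fraction = 1, seed = 19))
})

test_that("the umbrella experiment is reproducible and serializable", {
  ex <- simulate_faire_experiment(n_loci = 2, locus_length_bp = 20000,
                                  seed = 20)
  ex2 <- simulate_faire_experiment(n_loci = 2, locus_length_bp = 20000,
                                   seed = 20)
  expect_identical(ex, ex2)
  expect_setequal(names(ex$tracks), c("MK", "EB"))
  # truth round-trips through BED
  path <- withr::local_tempfile(fileext = ".bed")
  truth <- ex$truth
  truth$score_pct <- 100
  truth$source <- truth$cell_type
  write_peaks_bed(truth, path)
  back <- read_intervals_bed(path)
  expect_equal(back$start, truth$start)
  expect_equal(back$end, truth$end)
  expect_equal(back$name, truth$cell_type)
})
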