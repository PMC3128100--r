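test_that("Spearman eQTL recovers monotone genotype effects", {
  res <- spearman_eqtl(c(0, 0, 1, 1, 2, 2), c(1, 2, 3, 4, 5, 6))
  expect_equal(res$rho, cor(rank(c(0, 0, 1, 1, 2, 2)), rank(1:6)))
  expect_gt(res$rho, 0.9)
  strict <- spearman_eqtl(c(0, 1, 2), c(5, 6, 7))
  expect_equal(strict$rho, 1)
  expect_error(spearman_eqtl(c(1, 1, 1), rnorm(3)), "degenerate")
  expect_error(spearman_eqtl(c(0, 1, 2), rep(2, 3)), "degenerate")
  expect_error(spearman_eqtl(c(0, 1), c(1, 2)), "3 samples")
})

test_that("Spearman eQTL is invariant to monotone transforms and matches
           the rank-then-Pearson definition on ties", {
  withr::with_seed(101, {
    for (i in 1:10) {
      g <- sample(0:2, 12, replace = TRUE)
      if (length(unique(g)) < 2) next
      e <- rnorm(12)
      a <- spearman_eqtl(g, e)
      b <- spearman_eqtl(g, exp(e))       # strictly monotone transform
      expect_equal(a$rho, b$rho, tolerance = 1e-12)
      expect_equal(a$nominal_p, b$nominal_p, tolerance = 1e-12)
      # definitional oracle on tied data
      e_tied <- round(e, 0)
      if (length(unique(e_tied)) < 2) next
      d <- spearman_eqtl(g, e_tied)
      expect_equal(d$rho, cor(rank(g), rank(e_tied)), tolerance = 1e-12)
      ref <- suppressWarnings(
        cor.test(g, e_tied, method = "spearman", exact = FALSE))
      expect_equal(d$rho, unname(ref$estimate), tolerance = 1e-12)
    }
  })
})

test_that("the cis scan only tests genes with a TSS inside the window", {
  genes <- data.frame(gene_id = c("near", "far", "other_chr"),
                      chrom = c("c1", "c1", "c2"),
                      start = c(0, 0, 0), end = c(5e6, 5e6, 5e6),
                      tss = c(1.2e6, 3e6, 1.2e6), stringsAsFactors = FALSE)
  v <- matrix(rnorm(18), 3, 6,
              dimnames = list(genes$gene_id, paste0("s", 1:6)))
  expr <- expression_matrix(v, setNames(rep("all", 6), paste0("s", 1:6)))
  res <- eqtl_scan(list(snp_id = "rsX", chrom = "c1", pos = 1e6),
                   c(0, 0, 1, 1, 2, 2), expr, genes, window_bp = 1e6)
  expect_equal(res$gene_id, "near")
})

test_that("differential expression reports exact planted fold changes", {
  sim <- simulate_expression(n_genes = 50, n_de = 10, log2_fc = 2.203,
                             noise_sd = 0, seed = 111)
  de <- differential_expression(sim$expr, "KO", "WT")
  m <- match(sim$truth$gene_id, de$gene_id)
  expect_equal(de$log2_fc[m], sim$truth$true_log2_fc, tolerance = 1e-12)
  # a gene planted at the magnitude reported for the strongest platelet
  # glycoprotein hit passes the 1.5-fold linear cut
  expect_true(all(de$passes_fc[m][sim$truth$true_log2_fc != 0]))
  expect_false(any(de$passes_fc[m][sim$truth$true_log2_fc == 0]))
})

test_that("fold-change threshold scales are applied as documented", {
  sim <- simulate_expression(n_genes = 20, n_de = 20, log2_fc = 0.996,
                             noise_sd = 0, seed = 112)
  lin <- differential_expression(sim$expr, "KO", "WT", fc_min = 1.5)
  log2s <- differential_expression(sim$expr, "KO", "WT", fc_min = 1.5,
                                   fc_scale = "log2")
  # |log2 FC| = 0.996 >= log2(1.5) but < 1.5
  expect_true(all(lin$passes_fc))
  expect_false(any(log2s$passes_fc))
})

test_that("two-group ANOVA equals the squared equal-variance t statistic", {
  withr::with_seed(113, {
    v <- matrix(rnorm(60), 10, 6,
                dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:6)))
    groups <- rep(c("A", "B"), each = 3)
    av <- fairechip:::row_anova(v, groups)
    for (i in 1:10) {
      tt <- t.test(v[i, 1:3], v[i, 4:6], var.equal = TRUE)
      expect_equal(av$f[[i]], unname(tt$statistic)^2, tolerance = 1e-10)
      expect_equal(av$p[[i]], tt$p.value, tolerance = 1e-10)
      ref <- oneway.test(v[i, ] ~ groups, var.equal = TRUE)
      expect_equal(av$p[[i]], ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("three-group row ANOVA matches oneway.test", {
  withr::with_seed(114, {
    v <- matrix(rnorm(45), 5, 9)
    groups <- rep(c("A", "B", "C"), each = 3)
    av <- fairechip:::row_anova(v, groups)
    for (i in 1:5) {
      ref <- oneway.test(v[i, ] ~ groups, var.equal = TRUE)
      expect_equal(av$p[[i]], ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("the DE screen is antisymmetric under group swap", {
  sim <- simulate_expression(n_genes = 40, n_de = 10, seed = 115)
  ab <- differential_expression(sim$expr, "KO", "WT")
  ba <- differential_expression(sim$expr, "WT", "KO")
  expect_equal(ab$log2_fc, -ba$log2_fc, tolerance = 1e-12)
  expect_equal(ab$anova_p, ba$anova_p, tolerance = 1e-12)
  expect_identical(ab$passes_fc, ba$passes_fc)
})

test_that("over-representation P equals exhaustive enumeration", {
  universe <- letters[1:9]
  gene_set <- letters[1:4]
  hits <- letters[c(1, 2, 6)]
  res <- overrepresentation_test(hits, gene_set, universe)
  expect_equal(res$overlap, 2)
  # enumerate all C(9, 3) hit draws and count overlaps >= k
  draws <- combn(9, 3)
  ov <- apply(draws, 2, function(ii) sum(universe[ii] %in% gene_set))
  expect_equal(res$p_value, mean(ov >= 2))
  # boundary cases
  expect_equal(overrepresentation_test(universe, gene_set,
                                       universe)$p_value, 1)
  expect_equal(overrepresentation_test(letters[6:9], letters[1:4],
                                       universe)$overlap, 0)
  expect_equal(overrepresentation_test(letters[6:9], letters[1:4],
                                       universe)$p_value, 1)
  expect_error(overrepresentation_test("a", "a", character(0)), "universe")
  expect_error(overrepresentation_test("z", "a", universe), "subsets")
})
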