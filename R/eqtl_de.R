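#' Spearman rank-correlation eQTL test
#'
#' Association between a SNP genotype (allele dosage 0/1/2) and one
#' gene's expression across samples: Spearman's rho computed on mid-ranks
#' (so ties are handled definitionally as rank-then-Pearson) with a
#' nominal P-value from the t-distribution approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param genotypes integer dosages per sample.
#' @param expression numeric expression per sample (log2 scale).
#' @param snp_id,gene_id identifiers carried into the result.
#' @return list: `snp_id`, `gene_id`, `rho`, `nominal_p`, `n_samples`.
#' @export
spearman_eqtl <- function(genotypes, expression, snp_id = NA, gene_id = NA) {
  n <- length(genotypes)
  if (n != length(expression)) stop("length mismatch")
  if (n < 3) stop("need at least 3 samples")
  if (length(unique(genotypes)) < 2) stop("degenerate: constant genotype")
  if (length(unique(expression)) < 2) stop("degenerate: constant expression")
  rho <- cor(rank(genotypes), rank(expression))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(snp_id = snp_id, gene_id = gene_id, rho = rho, nominal_p = p,
       n_samples = n)
}

#' Cis eQTL scan around a SNP
#'
#' Runs [spearman_eqtl()] for every gene whose TSS lies within
#' `window_bp` of the SNP position (the +-1 Mb cis window by default).
#'
#' @param snp one-row SNP record (`snp_id`, `chrom`, `pos` 0-based).
#' @param genotypes dosages per sample for that SNP.
#' @param expr an [expression_matrix()] whose rows are genes.
#' @param genes gene models with `tss` (rows matching `expr` by gene_id).
#' @param window_bp half-width of the cis window.
#' @return data.frame of eQTL results, one row per tested gene.
#' @export
eqtl_scan <- function(snp, genotypes, expr, genes, window_bp = 1e6) {
  cis <- genes[genes$chrom == snp$chrom &
                 abs(genes$tss - snp$pos) <= window_bp, , drop = FALSE]
  cis <- cis[cis$gene_id %in% rownames(expr$values), , drop = FALSE]
  rows <- lapply(cis$gene_id, function(g) {
    as.data.frame(spearman_eqtl(genotypes, expr$values[g, ],
                                snp_id = snp$snp_id, gene_id = g),
                  stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      rho = numeric(0), nominal_p = numeric(0),
                      n_samples = integer(0)))
  do.call(rbind, rows)
}

# Row-wise one-way ANOVA across group labels; vectorized over genes.
# Returns the F statistic and P per row.  Verified in the test suite
# against stats::oneway.test(var.equal = TRUE) and the two-group t^2
# identity.
row_anova <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- ncol(values)
  if (k < 2) stop("need >= 2 groups")
  grand <- rowMeans(values)
  ss_between <- 0
  ss_within <- 0
  for (g in levels(groups)) {
    sel <- groups == g
    m_g <- rowMeans(values[, sel, drop = FALSE])
    ss_between <- ss_between + sum(sel) * (m_g - grand)^2
    ss_within <- ss_within +
      rowSums((values[, sel, drop = FALSE] - m_g)^2)
  }
  df1 <- k - 1
  df2 <- n - k
  f <- (ss_between / df1) / (ss_within / df2)
  p <- pf_upper(f, df1, df2)
  list(f = f, p = p, df1 = df1, df2 = df2)
}

pf_upper <- function(f, df1, df2) stats::pf(f, df1, df2, lower.tail = FALSE)

#' Knockout vs wild-type differential-expression screen
#'
#' For every gene: `log2_fc` is the difference of group means of the
#' (already replicate-averaged, log2-scale) expression values
#' (`group_a - group_b`); the P-value comes from a one-way ANOVA across
#' the two groups; and `passes_fc` flags genes whose absolute fold change
#' reaches the cut-off.  With `fc_scale = "linear"` (default) the cut-off
#' `fc_min = 1.5` is applied as `|log2_fc| >= log2(1.5)`; with
#' `"log2"` it is applied to `log2_fc` directly.
#'
#' @param expr an [expression_matrix()].
#' @param group_a,group_b group labels (e.g. `"KO"`, `"WT"`); each needs
#'   at least 2 samples.
#' @param fc_min fold-change cut-off (linear scale by default).
#' @param fc_scale `"linear"` or `"log2"`.
#' @return data.frame: gene_id, log2_fc, anova_p, passes_fc.
#' @export
differential_expression <- function(expr, group_a, group_b, fc_min = 1.5,
                                    fc_scale = c("linear", "log2")) {
  fc_scale <- match.arg(fc_scale)
  g <- expr$sample_groups
  sel <- g %in% c(group_a, group_b)
  if (sum(g == group_a) < 2 || sum(g == group_b) < 2)
    stop("each group needs at least 2 samples")
  values <- expr$values[, sel, drop = FALSE]
  groups <- g[sel]
  fc <- rowMeans(values[, groups == group_a, drop = FALSE]) -
    rowMeans(values[, groups == group_b, drop = FALSE])
  av <- row_anova(values, groups)
  cut <- if (fc_scale == "linear") log2(fc_min) else fc_min
  data.frame(gene_id = rownames(values), log2_fc = fc, anova_p = av$p,
             passes_fc = abs(fc) >= cut, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Gene-set over-representation test
#'
#' Hypergeometric upper-tail probability of observing at least the seen
#' overlap between a hit list and a gene set drawn from a common universe:
#' `P = P[X >= k]`, `X ~ Hypergeom(|universe|, |gene_set|, |hit_genes|)`.
#'
#' @param hit_genes,gene_set,universe character vectors;
#'   `hit_genes` and `gene_set` must be subsets of `universe`.
#' @return list: `overlap` (k) and `p_value`.
#' @export
overrepresentation_test <- function(hit_genes, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  hit_genes <- unique(hit_genes); gene_set <- unique(gene_set)
  if (!all(hit_genes %in% universe) || !all(gene_set %in% universe))
    stop("hit genes and gene set must be subsets of the universe")
  k <- length(intersect(hit_genes, gene_set))
  p <- phyper(k - 1, length(gene_set), length(universe) - length(gene_set),
              length(hit_genes), lower.tail = FALSE)
  list(overlap = k, p_value = p)
}
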