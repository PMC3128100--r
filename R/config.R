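#' Pipeline configuration
#'
#' Bundles every tunable parameter of the pipeline with the defaults used
#' throughout: the peak-caller block (300 bp sliding window, at least 4
#' probes above the cut-off per peak, at most 2 tolerated consecutive
#' below-cut-off probes inside a peak, cut-off series from 90% down to 15%
#' of the hypothetical maximum in 0.5 steps, hypothetical maximum = mean +
#' 6 SD per chromosome), the LD block (r2 >= 0.8, MAF >= 0.05), annotation
#' windows, the eQTL cis window (+-1 Mb), the differential-expression
#' fold-change cut-off (1.5 on the linear scale) and the network
#' expression-detection threshold (P <= 0.01).
#'
#' @param seed integer seed used to derive all simulation substreams.
#' @param window_bp sliding-window width in bp.
#' @param min_probes minimum number of above-cut-off probes for a window to
#'   qualify and for a peak to be emitted.
#' @param gap_probes maximum run of consecutive below-cut-off probes
#'   tolerated inside a peak before it splits.
#' @param p_start,p_end,p_step cut-off series as percentages of the
#'   hypothetical maximum, descending from `p_start` to `p_end` by `p_step`.
#' @param max_steps optional cap on the number of cut-off steps
#'   (`NULL` = no cap; the full 90->15 by 0.5 series has 151 values).
#' @param sd_mult multiplier of the per-chromosome SD in the hypothetical
#'   maximum.
#' @param r2_min,maf_min LD-proxy expansion thresholds.
#' @param tss_window_bp window around the TSS for proximity summaries.
#' @param gene_flank_bp flank added to gene bodies for lineage peak counts.
#' @param promoter_bp upstream promoter window used in peak classification.
#' @param eqtl_window_bp cis window (bp) centred on a SNP for eQTL scans.
#' @param fc_min differential-expression fold-change cut-off on the linear
#'   scale; the screen requires `|log2 FC| >= log2(fc_min)`.
#' @param fc_scale `"linear"` (cut at `log2(fc_min)`) or `"log2"` (cut at
#'   `fc_min` directly).
#' @param detection_p_max detection P-value above which interactors are
#'   considered not expressed and dropped from the network.
#'
#' @return A list of class `"pipeline_config"`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$window_bp
#' @export
pipeline_config <- function(seed = 1L,
                            window_bp = 300,
                            min_probes = 4L,
                            gap_probes = 2L,
                            p_start = 90,
                            p_end = 15,
                            p_step = 0.5,
                            max_steps = NULL,
                            sd_mult = 6,
                            r2_min = 0.8,
                            maf_min = 0.05,
                            tss_window_bp = 20000,
                            gene_flank_bp = 2000,
                            promoter_bp = 2000,
                            eqtl_window_bp = 1e6,
                            fc_min = 1.5,
                            fc_scale = c("linear", "log2"),
                            detection_p_max = 0.01) {
  fc_scale <- match.arg(fc_scale)
  cfg <- list(seed = as.integer(seed), window_bp = window_bp,
              min_probes = as.integer(min_probes),
              gap_probes = as.integer(gap_probes),
              p_start = p_start, p_end = p_end, p_step = p_step,
              max_steps = if (is.null(max_steps)) NULL else as.integer(max_steps),
              sd_mult = sd_mult, r2_min = r2_min, maf_min = maf_min,
              tss_window_bp = tss_window_bp, gene_flank_bp = gene_flank_bp,
              promoter_bp = promoter_bp, eqtl_window_bp = eqtl_window_bp,
              fc_min = fc_min, fc_scale = fc_scale,
              detection_p_max = detection_p_max)
  if (cfg$p_end > cfg$p_start)
    stop("p_end must not exceed p_start")
  pos <- c("window_bp", "min_probes", "p_step", "sd_mult", "r2_min",
           "maf_min", "tss_window_bp", "gene_flank_bp", "promoter_bp",
           "eqtl_window_bp", "fc_min", "detection_p_max")
  bad <- pos[vapply(cfg[pos], function(x) !is.numeric(x) || x <= 0, logical(1))]
  if (length(bad))
    stop("config values must be positive: ", paste(bad, collapse = ", "))
  if (cfg$gap_probes < 0) stop("gap_probes must be >= 0")
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("FAIRE pipeline configuration\n")
  cat(sprintf("  peak calling: window %g bp, min %d probes, gap <= %d, %g%%..%g%% by %g (mean + %g SD)\n",
              x$window_bp, x$min_probes, x$gap_probes,
              x$p_start, x$p_end, x$p_step, x$sd_mult))
  cat(sprintf("  LD: r2 >= %g, MAF >= %g; eQTL window +-%g bp\n",
              x$r2_min, x$maf_min, x$eqtl_window_bp))
  cat(sprintf("  DE: fold-change >= %g (%s scale); network detection P <= %g\n",
              x$fc_min, x$fc_scale, x$detection_p_max))
  invisible(x)
}

# Derive a bounded per-module substream seed from the global seed so that
# every generator sees an independent, reproducible stream.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}
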