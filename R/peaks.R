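#' Cut-off series for iterative-threshold peak calling
#'
#' For one chromosome's scaled log2 ratios, the hypothetical maximum is
#' `mean + sd_mult * SD` (default mean + 6 SD).  The peak finder is run
#' repeatedly at a descending series of cut-offs taken as percentages of
#' this maximum, from `p_start` (90%) down to `p_end` (15%) in `p_step`
#' (0.5) decrements; with the defaults the series has 151 values.  An
#' optional `max_steps` caps the series length (off by default).
#'
#' @param values scaled log2 ratios of one chromosome (>= 2 probes).
#' @param config a [pipeline_config()].
#' @return list of class `"cutoff_series"`: `hypothetical_max`,
#'   `percentages` (descending), `cutoffs` (absolute log2-ratio values).
#' @examples
#' s <- make_cutoff_series(c(rnorm(100)), pipeline_config())
#' length(s$cutoffs)
#' @export
make_cutoff_series <- function(values, config = pipeline_config()) {
  values <- values[is.finite(values)]
  if (length(values) < 2)
    stop("cutoff series needs >= 2 probes on the chromosome")
  s <- sd(values)
  if (s == 0) stop("degenerate chromosome: zero standard deviation")
  hyp_max <- mean(values) + config$sd_mult * s
  pct <- seq(config$p_start, config$p_end, by = -config$p_step)
  if (!is.null(config$max_steps)) pct <- head(pct, config$max_steps)
  out <- list(hypothetical_max = hyp_max, percentages = pct,
              cutoffs = pct / 100 * hyp_max)
  class(out) <- "cutoff_series"
  out
}

# Peak calling at a single absolute cut-off on one chromosome.
# starts ascending; above = logical per probe.  A window_bp window anchored
# at each probe qualifies if >= min_probes probes (by start position) in
# [start_i, start_i + window_bp) are above the cut-off.  Overlapping
# qualifying windows merge; inside a merged region runs of more than
# gap_probes consecutive below-cutoff probes split it; each part spanning
# from its first to its last above-cutoff probe is kept if it holds
# >= min_probes above-cutoff probes.
call_at_cutoff <- function(starts, lens, above, window_bp, min_probes,
                           gap_probes) {
  n <- length(starts)
  cum <- cumsum(above)
  hi <- findInterval(starts + window_bp - 0.5, starts)
  cnt <- cum[hi] - c(0, cum)[seq_len(n)]
  qi <- which(cnt >= min_probes)
  if (!length(qi))
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_probes = integer(0)))
  ws <- starts[qi]
  brk <- c(TRUE, ws[-1] >= ws[-length(ws)] + window_bp)
  region_id <- cumsum(brk)
  out_start <- numeric(0); out_end <- numeric(0)
  for (r in seq_len(max(region_id))) {
    sel <- region_id == r
    r_lo <- qi[which(sel)[1]]
    r_end <- ws[max(which(sel))] + window_bp
    r_hi <- findInterval(r_end - 0.5, starts)
    idx <- (r_lo:r_hi)[above[r_lo:r_hi]]
    if (!length(idx)) next
    grp <- cumsum(c(TRUE, diff(idx) - 1 > gap_probes))
    for (g in seq_len(max(grp))) {
      m <- idx[grp == g]
      if (length(m) >= min_probes) {
        out_start <- c(out_start, starts[m[1]])
        out_end <- c(out_end, starts[m[length(m)]] + lens[m[length(m)]])
      }
    }
  }
  if (!length(out_start))
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_probes = integer(0)))
  # a long probe's overhang can make split groups yield overlapping
  # intervals; merge those and recount the above-cutoff probes inside
  # the merged boundaries
  o <- order(out_start, out_end)
  out_start <- out_start[o]; out_end <- out_end[o]
  keep_s <- out_start[1]; keep_e <- out_end[1]
  for (i in seq_along(out_start)[-1]) {
    last <- length(keep_s)
    if (out_start[i] < keep_e[last]) {
      keep_e[last] <- max(keep_e[last], out_end[i])
    } else {
      keep_s <- c(keep_s, out_start[i]); keep_e <- c(keep_e, out_end[i])
    }
  }
  n_above <- vapply(seq_along(keep_s), function(i)
    sum(above & starts >= keep_s[i] & starts < keep_e[i]), numeric(1))
  data.frame(start = keep_s, end = keep_e, n_probes = as.integer(n_above))
}

#' Call nucleosome-depleted regions on a scaled probe track
#'
#' Sliding-window peak calling with an iterative threshold: for each
#' cut-off in the per-chromosome series (see [make_cutoff_series()]), a
#' `window_bp` window anchored at each probe qualifies when at least
#' `min_probes` probes inside it exceed the cut-off; overlapping
#' qualifying windows merge, a merged region splits where more than
#' `gap_probes` consecutive probes fall below the cut-off, and peak
#' boundaries run from the first above-cut-off probe start to the end of
#' the last above-cut-off probe.  The final peak set is the union over the
#' whole cut-off series (equivalently, the peaks at the most permissive
#' cut-off), and each peak is annotated with `score_pct`, the highest
#' percentage of the hypothetical maximum at which any part of it was
#' detected.  `n_probes` counts the probes above the most permissive
#' cut-off inside the final peak boundaries.
#'
#' @param track a scaled [probe_track()] (see [scale_track()]); calling an
#'   unscaled track is an error.
#' @param config a [pipeline_config()].
#' @param condition condition label to call on (default: the only one).
#' @return data.frame of class `"peak_set"`: chrom, start, end (0-based
#'   half-open), score_pct, n_probes, source; sorted and non-overlapping.
#'   Chromosome cut-off series are attached as attribute `"series"`.
#' @export
call_peaks <- function(track, config = pipeline_config(), condition = NULL) {
  if (!isTRUE(attr(track, "scaled")))
    stop("call_peaks expects a scaled track; run scale_track() first")
  if (!is.null(condition)) track <- track[track$condition == condition, ]
  conds <- unique(track$condition)
  if (length(conds) != 1)
    stop("track has several conditions; pick one with `condition`")
  res <- list()
  series_log <- list()
  for (chr in unique(track$chrom)) {
    sub <- track[track$chrom == chr, , drop = FALSE]
    if (nrow(sub) < max(2L, config$min_probes)) next
    ord <- order(sub$start)
    starts <- sub$start[ord]; lens <- sub$length[ord]
    vals <- sub$log2_ratio[ord]
    series <- make_cutoff_series(vals, config)
    series_log[[chr]] <- c(hypothetical_max = series$hypothetical_max,
                           n_cutoffs = length(series$cutoffs))
    k_low <- length(series$cutoffs)
    final <- call_at_cutoff(starts, lens, vals > series$cutoffs[k_low],
                            config$window_bp, config$min_probes,
                            config$gap_probes)
    if (!nrow(final)) next
    score <- rep(NA_real_, nrow(final))
    for (k in seq_len(k_low)) {
      pk <- call_at_cutoff(starts, lens, vals > series$cutoffs[k],
                           config$window_bp, config$min_probes,
                           config$gap_probes)
      if (!nrow(pk)) next
      tgt <- findInterval(pk$start, final$start)
      hit <- unique(tgt[tgt >= 1 & pk$start < final$end[pmax(tgt, 1)]])
      upd <- hit[is.na(score[hit])]
      score[upd] <- series$percentages[k]
      if (!anyNA(score)) break
    }
    res[[chr]] <- data.frame(chrom = chr, start = final$start,
                             end = final$end, score_pct = score,
                             n_probes = final$n_probes,
                             source = conds,
                             stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               score_pct = numeric(0), n_probes = integer(0),
               source = character(0), stringsAsFactors = FALSE)
  out <- sort_intervals(out)
  rownames(out) <- NULL
  attr(out, "series") <- series_log
  class(out) <- c("peak_set", "data.frame")
  out
}
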