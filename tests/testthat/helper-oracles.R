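# Independent oracles used across the suite.  These deliberately use
# different algorithmic structure from the package code (quadratic
# enumeration, fix-point merging, BFS) so agreement is evidence of
# correctness rather than shared bugs.

# Exhaustive sliding-window/cutoff peak-calling oracle for one
# chromosome.  Enumerates a window at every probe at every cutoff with a
# dense probe-in-window matrix, merges overlapping qualifying windows by
# repeated pairwise merging until a fixed point, splits merged regions at
# runs of more than gap_probes below-cutoff probes, and finally unions
# peaks across all cutoffs as connected components.
oracle_call_peaks <- function(starts, lens, vals, config) {
  n <- length(starts)
  hyp <- mean(vals) + config$sd_mult * stats::sd(vals)
  pcts <- seq(config$p_start, config$p_end, by = -config$p_step)
  if (!is.null(config$max_steps)) pcts <- head(pcts, config$max_steps)
  in_window <- outer(starts, starts,
                     function(w, s) s >= w & s < w + config$window_bp)
  peaks_at <- function(cut) {
    above <- vals > cut
    counts <- as.vector(in_window %*% above)
    qual <- which(counts >= config$min_probes)
    if (!length(qual)) return(NULL)
    regs <- cbind(starts[qual], starts[qual] + config$window_bp)
    repeat {
      changed <- FALSE
      out <- regs[1, , drop = FALSE]
      for (i in seq_len(nrow(regs))[-1]) {
        last <- nrow(out)
        if (regs[i, 1] < out[last, 2]) {
          out[last, 2] <- max(out[last, 2], regs[i, 2]); changed <- TRUE
        } else out <- rbind(out, regs[i, , drop = FALSE])
      }
      regs <- out
      if (!changed) break
    }
    res <- NULL
    for (r in seq_len(nrow(regs))) {
      memb <- which(starts >= regs[r, 1] & starts < regs[r, 2])
      ab <- memb[above[memb]]
      if (!length(ab)) next
      grp <- split(ab, cumsum(c(1, as.integer(diff(ab) - 1 > config$gap_probes))))
      for (g in grp) {
        if (length(g) >= config$min_probes) {
          res <- rbind(res, c(starts[g[1]],
                              starts[g[length(g)]] + lens[g[length(g)]]))
        }
      }
    }
    res
  }
  all_peaks <- NULL
  for (k in seq_along(pcts)) {
    pk <- peaks_at(pcts[k] / 100 * hyp)
    if (!is.null(pk))
      all_peaks <- rbind(all_peaks, cbind(pk, pcts[k]))
  }
  if (is.null(all_peaks))
    return(data.frame(start = numeric(0), end = numeric(0),
                      score_pct = numeric(0), n_probes = integer(0)))
  # union across cutoffs: connected components of >= 1 bp overlap
  ord <- order(all_peaks[, 1], all_peaks[, 2])
  ap <- all_peaks[ord, , drop = FALSE]
  comp <- integer(nrow(ap)); comp[1] <- 1; cur_end <- ap[1, 2]
  for (i in seq_len(nrow(ap))[-1]) {
    if (ap[i, 1] < cur_end) comp[i] <- comp[i - 1]
    else comp[i] <- comp[i - 1] + 1
    cur_end <- max(cur_end, ap[i, 2])
  }
  lowest_cut <- pcts[length(pcts)] / 100 * hyp
  out <- do.call(rbind, lapply(split(seq_len(nrow(ap)), comp), function(ii) {
    s <- min(ap[ii, 1]); e <- max(ap[ii, 2])
    data.frame(start = s, end = e, score_pct = max(ap[ii, 3]),
               n_probes = sum(starts >= s & starts < e &
                                vals > lowest_cut))
  }))
  rownames(out) <- NULL
  out
}

# Random single-chromosome probe layout for peak-caller tests.
random_track_fixture <- function(n_probes = 500, seed = 1) {
  withr::with_seed(seed, {
    starts <- cumsum(sample(13:33, n_probes, replace = TRUE))
    lens <- sample(50:75, n_probes, replace = TRUE)
    vals <- rnorm(n_probes)
    list(starts = starts, lens = lens, vals = vals)
  })
}

# Wrap a fixture as a scaled probe_track without re-centring, so the
# oracle sees exactly the same values.
as_scaled_track <- function(fx, chrom = "chrT", condition = "12min") {
  tr <- probe_track(rep(chrom, length(fx$starts)), fx$starts, fx$lens,
                    fx$vals, condition = condition)
  attr(tr, "scaled") <- TRUE
  tr
}

# Quadratic any-overlap oracle.
oracle_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & a$start[i] < b$end)
  }, logical(1))
}

# Exhaustive connected components of >= 1 bp overlaps over two interval
# sets, via repeated label propagation on the full overlap matrix.
oracle_components <- function(a, b) {
  all <- rbind(a[, c("chrom", "start", "end")],
               b[, c("chrom", "start", "end")])
  n <- nrow(all)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    all$chrom[i] == all$chrom[j] & all$start[i] < all$end[j] &
      all$start[j] < all$end[i]
  })
  lab <- seq_len(n)
  repeat {
    new_lab <- vapply(seq_len(n), function(i) min(lab[adj[i, ]]), numeric(1))
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  from_a <- rep(c(TRUE, FALSE), c(nrow(a), nrow(b)))
  list(lab = lab, from_a = from_a, all = all)
}

# Random non-degenerate interval set on a couple of chromosomes.
random_intervals <- function(n, seed, chroms = c("c1", "c2"),
                             span = 20000, width_max = 800) {
  withr::with_seed(seed, {
    s <- sample(span, n, replace = TRUE)
    w <- sample(width_max, n, replace = TRUE)
    df <- data.frame(chrom = sample(chroms, n, replace = TRUE),
                     start = s, end = s + w,
                     score_pct = round(runif(n, 15, 90), 1),
                     n_probes = sample(4:30, n, replace = TRUE),
                     stringsAsFactors = FALSE)
    fairechip:::sort_intervals(df)
  })
}

# BFS largest-connected-component oracle on an edge list, replicating the
# tie rules (size, then edge count, then lexicographically smallest node
# set).
oracle_lcc <- function(edges) {
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  unseen <- nodes
  comps <- list()
  while (length(unseen)) {
    queue <- unseen[1]
    comp <- character(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      nb <- c(edges$protein_b[edges$protein_a == v],
              edges$protein_a[edges$protein_b == v])
      queue <- c(queue, setdiff(nb, comp))
    }
    comps[[length(comps) + 1]] <- sort(comp)
    unseen <- setdiff(unseen, comp)
  }
  n_edge <- vapply(comps, function(cc)
    sum(edges$protein_a %in% cc & edges$protein_b %in% cc), numeric(1))
  sizes <- lengths(comps)
  best <- which(sizes == max(sizes))
  best <- best[n_edge[best] == max(n_edge[best])]
  keys <- vapply(comps[best], paste, "", collapse = "\r")
  comps[[best[order(keys)[1]]]]
}

# Fixed-point biweight oracle: solves m = sum(w(m) x)/sum(w(m)) by direct
# damped iteration from the mean (not the median), independently of the
# package's iteration.
oracle_biweight <- function(x, c = 5) {
  s <- median(abs(x - median(x)))
  if (s == 0) return(median(x))
  m <- mean(x)
  for (i in 1:2000) {
    u <- (x - m) / (c * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    m_new <- 0.5 * m + 0.5 * sum(w * x) / sum(w)
    if (abs(m_new - m) < 1e-12) break
    m <- m_new
  }
  m
}
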