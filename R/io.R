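#' Construct a probe track
#'
#' A probe track is the raw signal object of a two-channel tiling array:
#' per-chromosome sorted probe start positions (0-based), probe lengths and
#' one log2 ratio per probe for a given condition label (e.g. a
#' formaldehyde cross-linking time).  Tracks for several conditions are
#' stored in long format and subset by `condition` downstream.
#'
#' @param chrom,start,length,log2_ratio parallel probe vectors.
#' @param condition condition label (recycled).
#' @param scaled has the track been between-channel scaled already?
#' @return data.frame of class `"probe_track"` with attribute `"scaled"`.
#' @export
probe_track <- function(chrom, start, length, log2_ratio,
                        condition = "cond1", scaled = FALSE) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   length = as.numeric(length),
                   log2_ratio = as.numeric(log2_ratio),
                   condition = rep_len(as.character(condition),
                                       base::length(chrom)),
                   stringsAsFactors = FALSE)
  validate_probe_track(df)
  attr(df, "scaled") <- isTRUE(scaled)
  class(df) <- c("probe_track", "data.frame")
  df
}

validate_probe_track <- function(df) {
  if (!nrow(df)) stop("probe track is empty")
  if (any(!is.finite(df$log2_ratio))) stop("probe track: non-finite log2 ratio")
  if (any(df$length <= 0)) stop("probe track: non-positive probe length")
  by <- split(df$start, list(df$chrom, df$condition), drop = TRUE)
  for (key in names(by)) {
    s <- by[[key]]
    if (anyDuplicated(s)) {
      dup <- s[duplicated(s)][1]
      stop("probe track: duplicated probe start at ", key, ":", dup)
    }
  }
  invisible(df)
}

#' Read a probe table (TSV) into a probe track
#'
#' Expects tab-delimited columns `chrom`, `start`, `length`, `log2_ratio`
#' (one condition per file).  Probes are sorted per chromosome if needed
#' (with a warning); a duplicated probe start is an error naming the
#' position.
#'
#' @param path file path.
#' @param condition_label condition to attach to every probe.
#' @return a [probe_track()] (unscaled).
#' @export
read_probe_track <- function(path, condition_label = "cond1") {
  df <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse probe table ", path, ": ",
                             conditionMessage(e)))
  need <- c("chrom", "start", "length", "log2_ratio")
  if (!all(need %in% names(df)))
    stop("probe table ", path, " must have columns ",
         paste(need, collapse = ", "))
  bad <- which(is.na(df$start) | is.na(df$log2_ratio) | is.na(df$length))
  if (length(bad))
    stop("malformed probe row at line ", bad[1] + 1L, " of ", path)
  ord <- order(df$chrom, df$start)
  if (is.unsorted(ord)) {
    warning("probe table ", path, " was not sorted; sorting")
  }
  df <- df[ord, , drop = FALSE]
  probe_track(df$chrom, df$start, df$length, df$log2_ratio,
              condition = condition_label)
}

#' Write a probe track to TSV
#'
#' Writes the columns `chrom`, `start`, `length`, `log2_ratio` of one
#' condition; inverse of [read_probe_track()].
#'
#' @param track a probe track.
#' @param path output path.
#' @param condition which condition to write (default: the only one).
#' @export
write_probe_track <- function(track, path, condition = NULL) {
  if (!is.null(condition)) track <- track[track$condition == condition, ]
  if (length(unique(track$condition)) > 1)
    stop("track has several conditions; pick one with `condition`")
  write.table(track[, c("chrom", "start", "length", "log2_ratio")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' BED is 0-based half-open, matching the internal convention, so
#' coordinates are taken verbatim.  Optional columns 4-6 become `name`,
#' `score` and `strand`.  Rows with `start >= end` are rejected with an
#' error naming the line.
#'
#' @param path BED file path.
#' @return data.frame of intervals (plus name/score/strand when present).
#' @export
read_intervals_bed <- function(path) {
  raw <- read.delim(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
  df <- data.frame(chrom = as.character(raw[[1]]),
                   start = as.numeric(raw[[2]]),
                   end = as.numeric(raw[[3]]),
                   stringsAsFactors = FALSE)
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("BED ", path, ": start >= end at line ", bad[1])
  if (ncol(raw) >= 4) df$name <- as.character(raw[[4]])
  if (ncol(raw) >= 5) df$score <- as.numeric(raw[[5]])
  df$strand <- if (ncol(raw) >= 6) as.character(raw[[6]]) else "."
  validate_intervals(df, what = paste0("BED ", path))
  df
}

#' Write peaks as BED / GFF3
#'
#' BED emits 0-based half-open coordinates with the detection score
#' (`score_pct`, a percentage of the hypothetical maximum) rescaled to the
#' BED score range 0-1000.  GFF3 emits 1-based inclusive coordinates with
#' `score_pct` and `n_probes` verbatim in the attributes column.
#'
#' @param peaks a peak table (see [call_peaks()]); any interval table with
#'   optional `score_pct`/`n_probes`/`source` columns works.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  score <- if ("score_pct" %in% names(peaks))
    round(peaks$score_pct * 10) else 0
  name <- if ("source" %in% names(peaks) && !is.null(peaks$source))
    peaks$source else sprintf("peak_%d", seq_len(nrow(peaks)))
  strand <- if ("strand" %in% names(peaks)) peaks$strand else "."
  out <- data.frame(peaks$chrom, format_bp(peaks$start), format_bp(peaks$end),
                    name, score, strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' @rdname write_peaks_bed
#' @export
write_peaks_gff3 <- function(peaks, path) {
  n <- nrow(peaks)
  score_pct <- if ("score_pct" %in% names(peaks)) peaks$score_pct else NA
  n_probes <- if ("n_probes" %in% names(peaks)) peaks$n_probes else NA
  src <- if ("source" %in% names(peaks)) peaks$source else "fairechip"
  attrs <- sprintf("ID=peak_%d;score_pct=%s;n_probes=%s",
                   seq_len(n), score_pct, n_probes)
  out <- data.frame(peaks$chrom, src, "open_chromatin_region",
                    format_bp(peaks$start + 1), format_bp(peaks$end),
                    ".", if ("strand" %in% names(peaks)) peaks$strand else ".",
                    ".", attrs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(out, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read peaks back from a GFF3 file written by [write_peaks_gff3()]
#'
#' Converts 1-based inclusive GFF3 coordinates back to the internal
#' 0-based half-open convention and recovers `score_pct`/`n_probes` from
#' the attributes.
#'
#' @param path GFF3 file path.
#' @return peak data.frame.
#' @export
read_peaks_gff3 <- function(path) {
  raw <- read.delim(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0(key, "=[^;]*"), attrs))
    val <- sub(paste0(key, "="), "", m)
    suppressWarnings(as.numeric(val))
  }
  df <- data.frame(chrom = as.character(raw[[1]]),
                   start = as.numeric(raw[[4]]) - 1,
                   end = as.numeric(raw[[5]]),
                   strand = as.character(raw[[7]]),
                   score_pct = get_attr(raw[[9]], "score_pct"),
                   n_probes = get_attr(raw[[9]], "n_probes"),
                   source = as.character(raw[[2]]),
                   stringsAsFactors = FALSE)
  validate_intervals(df, what = paste0("GFF3 ", path))
  df
}

#' Read a SNP panel
#'
#' Tab-delimited columns `snp_id`, `chrom`, `pos` (1-based, converted to
#' the internal 0-based convention), `ref`, `alt`, `maf`.
#'
#' @param path TSV path.
#' @return data.frame with 0-based `pos`.
#' @export
read_snp_panel <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "maf")
  if (!all(need %in% names(df)))
    stop("SNP panel must have columns ", paste(need, collapse = ", "))
  if (any(df$maf < 0 | df$maf > 0.5))
    stop("MAF outside [0, 0.5]")
  df$pos <- df$pos - 1
  df
}

#' @rdname read_snp_panel
#' @param snps data.frame with 0-based `pos` (written back as 1-based).
#' @export
write_snp_panel <- function(snps, path) {
  out <- snps
  out$pos <- out$pos + 1
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an LD table, canonicalized and mirrored
#'
#' Input columns `snp_a`, `snp_b`, `r2`.  Pairs are undirected: each pair
#' is stored once in lexicographic order, duplicates (in either direction)
#' collapse, and lookups treat the table as symmetric.  Self pairs are
#' kept but must have r2 = 1.
#'
#' @param path TSV path.
#' @return data.frame snp_a, snp_b, r2 with snp_a < snp_b.
#' @export
read_ld_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  canonicalize_ld(df)
}

canonicalize_ld <- function(df) {
  need <- c("snp_a", "snp_b", "r2")
  if (!all(need %in% names(df)))
    stop("LD table must have columns ", paste(need, collapse = ", "))
  if (any(df$r2 < 0 | df$r2 > 1)) stop("r2 outside [0, 1]")
  a <- pmin(df$snp_a, df$snp_b)
  b <- pmax(df$snp_a, df$snp_b)
  if (any(a == b & df$r2 != 1))
    stop("self LD pair with r2 != 1 for ", a[a == b & df$r2 != 1][1])
  out <- data.frame(snp_a = a, snp_b = b, r2 = df$r2,
                    stringsAsFactors = FALSE)
  dup <- duplicated(out[, c("snp_a", "snp_b")])
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an expression matrix with detection P-values and sample groups
#'
#' The expression file is a TSV with a `gene_id` column followed by one
#' log2-scale column per sample.  `groups` assigns a group label to every
#' sample column.  An optional detection file of identical shape carries
#' per-cell detection P-values in `[0, 1]`.
#'
#' @param path expression TSV.
#' @param groups named character vector or data.frame(sample, group).
#' @param detection_path optional detection-P TSV of the same shape.
#' @return list of class `"expression_matrix"`: `values` (genes x samples
#'   matrix), `detection_p` (matrix or NULL), `sample_groups`.
#' @export
read_expression_matrix <- function(path, groups, detection_path = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene_id
  detection <- NULL
  if (!is.null(detection_path)) {
    dd <- read.delim(detection_path, stringsAsFactors = FALSE,
                     check.names = FALSE)
    detection <- as.matrix(dd[, -1, drop = FALSE])
    rownames(detection) <- dd$gene_id
    if (any(detection < 0 | detection > 1))
      stop("detection P outside [0, 1]")
  }
  expression_matrix(values, groups, detection)
}

#' @rdname read_expression_matrix
#' @param values genes x samples numeric matrix (log2 scale).
#' @param detection_p optional matching matrix of detection P-values.
#' @export
expression_matrix <- function(values, groups, detection_p = NULL) {
  if (is.data.frame(groups)) groups <- setNames(groups$group, groups$sample)
  if (is.null(names(groups)) && length(groups) == ncol(values))
    names(groups) <- colnames(values)
  if (!all(colnames(values) %in% names(groups)))
    stop("every sample needs a group label")
  g <- groups[colnames(values)]
  if (any(is.na(g))) stop("missing group labels")
  if (!is.null(detection_p) &&
      any(detection_p < 0 | detection_p > 1, na.rm = TRUE))
    stop("detection P outside [0, 1]")
  structure(list(values = values, detection_p = detection_p,
                 sample_groups = g),
            class = "expression_matrix")
}

#' Read a protein-interaction table
#'
#' Two columns of protein ids, unordered pairs.  Pairs are canonicalized
#' (lexicographic), deduplicated, and self pairs are removed.
#'
#' @param path TSV with columns `protein_a`, `protein_b`.
#' @return data.frame protein_a, protein_b with protein_a < protein_b.
#' @export
read_interaction_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  canonicalize_interactions(df)
}

canonicalize_interactions <- function(df) {
  need <- c("protein_a", "protein_b")
  if (!all(need %in% names(df)))
    stop("interaction table must have columns ", paste(need, collapse = ", "))
  a <- pmin(df$protein_a, df$protein_b)
  b <- pmax(df$protein_a, df$protein_b)
  keep <- a != b
  out <- unique(data.frame(protein_a = a[keep], protein_b = b[keep],
                           stringsAsFactors = FALSE))
  out
}

#' Read / write gene models
#'
#' Gene models are stored as a TSV with columns `gene_id`, `chrom`,
#' `start`, `end`, `strand`, `tss` (all coordinates 0-based half-open; the
#' TSS is the 0-based position of the first transcribed base),
#' comma-separated `exon_starts`/`exon_ends`, optional
#' `utr5_start`/`utr5_end`/`utr3_start`/`utr3_end` (NA when absent) and an
#' optional `lineage` label (`MK`, `EB`, `MONO` or `none`).
#'
#' @param path TSV path.
#' @return data.frame of gene models with list columns `exon_starts`,
#'   `exon_ends`.
#' @export
read_gene_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$exon_starts <- lapply(strsplit(as.character(df$exon_starts), ","),
                           as.numeric)
  df$exon_ends <- lapply(strsplit(as.character(df$exon_ends), ","),
                         as.numeric)
  validate_genes(df)
}

#' @rdname read_gene_table
#' @param genes gene-model data.frame as returned by [read_gene_table()]
#'   or [simulate_locus_panel()].
#' @export
write_gene_table <- function(genes, path) {
  out <- genes
  out$exon_starts <- vapply(genes$exon_starts, paste, "", collapse = ",")
  out$exon_ends <- vapply(genes$exon_ends, paste, "", collapse = ",")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_genes <- function(df) {
  validate_intervals(df, what = "gene model")
  ok_tss <- df$tss >= df$start & df$tss <= df$end
  if (any(!ok_tss)) stop("gene model: TSS outside gene interval")
  for (i in seq_len(nrow(df))) {
    es <- df$exon_starts[[i]]; ee <- df$exon_ends[[i]]
    if (length(es) != length(ee) || any(es >= ee))
      stop("gene model: malformed exons for ", df$gene_id[i])
    if (any(es < df$start[i]) || any(ee > df$end[i]))
      stop("gene model: exon outside gene for ", df$gene_id[i])
    if (length(es) > 1) {
      o <- order(es)
      if (any(ee[o][-length(ee)] > es[o][-1]))
        stop("gene model: overlapping exons for ", df$gene_id[i])
    }
  }
  df
}
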