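#' Filter chromatin loops on read support and significance
#'
#' Keeps a loop iff it has at least `min_reads` supporting reads AND an FDR
#' strictly below `max_fdr`; loops with fewer than 3 reads or FDR >= 0.05
#' are removed under the defaults.
#'
#' @param loops loop data.frame (see [read_loops()])
#' @param min_reads minimum read support (inclusive)
#' @param max_fdr FDR bound (exclusive)
#' @return the retained rows
#' @export
filter_loops <- function(loops, min_reads = 3, max_fdr = 0.05) {
  keep <- loops$reads >= min_reads & loops$fdr < max_fdr
  out <- loops[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Define promoter regions around TSSs
#'
#' Promoters are `width` bp regions centered on the TSS:
#' `[TSS - width/2, TSS + width/2)`, clipped at coordinate 0 (a clipped
#' promoter is reported with its clipped width).
#'
#' @param genes annotation data.frame with gene_id, chrom, tss
#' @param width promoter width in bp (default 500)
#' @return data.frame of regions named by gene id
#' @export
define_promoters <- function(genes, width = 500) {
  half <- width / 2
  region(genes$chrom, pmax(0, genes$tss - half), genes$tss + half,
         name = genes$gene_id)
}

#' Assign enhancers to genes through filtered loops
#'
#' For each gene, loops with >= 1 bp anchor overlap with the promoter are
#' collected; the gene's enhancers are the H3K27ac peaks with >= 1 bp
#' overlap with the partner anchor of each such loop. Peaks reachable via
#' several loops are counted once, and peaks overlapping the gene's own
#' promoter are excluded. If `er_peaks` is supplied each enhancer is
#' flagged for >= 1 bp overlap with an ER binding peak.
#'
#' @param promoters regions from [define_promoters()] (names = gene ids)
#' @param filtered_loops loops that already passed [filter_loops()]
#' @param h3k27ac_peaks BED-style peak data.frame with a `name` column
#' @param er_peaks optional ER ChIP-seq peak data.frame
#' @return an object of class `regulatory_map`: per-gene list with elements
#'   `promoter`, `enhancers` (peak data.frame) and `er_overlap` (logical)
#' @export
assign_enhancers <- function(promoters, filtered_loops, h3k27ac_peaks,
                             er_peaks = NULL) {
  a1 <- data.frame(chrom = filtered_loops$chrom1,
                   start = filtered_loops$start1, end = filtered_loops$end1)
  a2 <- data.frame(chrom = filtered_loops$chrom2,
                   start = filtered_loops$start2, end = filtered_loops$end2)
  # promoter-anchor hits for either anchor orientation
  h1 <- overlap_pairs(promoters, a1)
  h2 <- overlap_pairs(promoters, a2)
  # peak hits on each anchor
  p1 <- overlap_pairs(h3k27ac_peaks, a1)
  p2 <- overlap_pairs(h3k27ac_peaks, a2)
  peaks_by_anchor <- function(hits) split(hits$query, hits$subject)
  pk1 <- peaks_by_anchor(p1); pk2 <- peaks_by_anchor(p2)

  er_flag <- rep(FALSE, nrow(h3k27ac_peaks))
  if (!is.null(er_peaks) && nrow(er_peaks) > 0) {
    er_flag[unique(overlap_pairs(h3k27ac_peaks, er_peaks)$query)] <- TRUE
  }

  out <- vector("list", nrow(promoters))
  names(out) <- promoters$name
  for (i in seq_len(nrow(promoters))) {
    # partner anchors: anchor2 of loops hit via anchor1, and vice versa
    loops_a <- h1$subject[h1$query == i]
    loops_b <- h2$subject[h2$query == i]
    cand <- unique(c(unlist(pk2[as.character(loops_a)], use.names = FALSE),
                     unlist(pk1[as.character(loops_b)], use.names = FALSE)))
    if (length(cand)) {
      own <- overlap_pairs(h3k27ac_peaks[cand, , drop = FALSE],
                           promoters[i, , drop = FALSE])$query
      if (length(own)) cand <- cand[-own]
    }
    cand <- sort(cand)
    out[[i]] <- list(promoter = promoters[i, , drop = FALSE],
                     enhancers = h3k27ac_peaks[cand, , drop = FALSE],
                     er_overlap = er_flag[cand])
  }
  structure(out, class = "regulatory_map")
}

#' @export
print.regulatory_map <- function(x, ...) {
  n_enh <- vapply(x, function(g) nrow(g$enhancers), 1L)
  cat("regulatory_map:", length(x), "genes;",
      sum(n_enh), "enhancer assignments (median/gene ",
      stats::median(n_enh), ")\n", sep = " ")
  invisible(x)
}

#' Z-score a signal column across regions
#'
#' Standardizes integrated signal across the given standardization universe
#' (all regions of one role) using the sample standard deviation.
#'
#' @param signal_table data.frame of region x assay signal
#' @param assay assay (column) name
#' @return named numeric vector of Z-scores
#' @export
zscore <- function(signal_table, assay) {
  if (!assay %in% names(signal_table)) stop("unknown assay: ", assay)
  x <- signal_table[[assay]]
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot Z-score assay '", assay, "': zero variance")
  }
  z <- (x - mean(x)) / s
  names(z) <- rownames(signal_table)
  z
}

#' Aggregate enhancer score
#'
#' The combined strength of a gene's enhancers for one assay:
#' `sum_i log2(s_i + 1)` over the gene's `n` linked enhancers, where `s_i`
#' is the Z-scored integrated signal at enhancer i. Because log2(s+1) is
#' undefined for s <= -1, Z-scores are clamped from below at `floor`
#' (default -0.99, a contribution floor of about -6.64). The empty-set
#' score is 0.
#'
#' @param z_values numeric vector of enhancer Z-scores (may be empty)
#' @param floor lower clamp applied to each Z-score
#' @return scalar score
#' @export
enhancer_score <- function(z_values, floor = -0.99) {
  if (length(z_values) == 0L) return(0)
  sum(log2(pmax(z_values, floor) + 1))
}

#' Count ER-bound enhancers per gene
#'
#' Number of a gene's linked enhancers that overlap (>= 1 bp) an ER
#' ChIP-seq peak. With `er_peaks = NULL` the flags stored on the map are
#' tallied.
#'
#' @param reg_map a `regulatory_map`
#' @param er_peaks optional ER peak data.frame to (re)compute overlap flags
#' @return named integer vector (gene id -> ERBS count)
#' @export
count_erbs <- function(reg_map, er_peaks = NULL) {
  vapply(reg_map, function(g) {
    if (is.null(er_peaks)) return(sum(g$er_overlap))
    if (nrow(g$enhancers) == 0L || nrow(er_peaks) == 0L) return(0L)
    length(unique(overlap_pairs(g$enhancers, er_peaks)$query))
  }, integer(1))
}

#' Build the per-gene feature table
#'
#' For every gene and assay, emits the promoter signal Z-score
#' (`<assay>_promoter`, standardized across all promoters) and the
#' aggregate enhancer score (`<assay>_enh_score`, from Z-scores
#' standardized across all enhancer peaks), plus `n_enhancers`, `n_ERBS`
#' and `gene_length`. Rows are tagged with a context label so tables from
#' several cell contexts can be pooled.
#'
#' @param reg_map a `regulatory_map` covering the genes
#' @param signal_table region x assay signal with rownames
#'   `prom:<gene_id>` for promoters and peak names for enhancers
#' @param genes annotation data.frame (provides gene_length)
#' @param context_label context tag stored in the `context` column
#' @param score_floor clamp passed to [enhancer_score()]
#' @return data.frame, one row per gene, with a `context` column
#' @export
build_feature_table <- function(reg_map, signal_table, genes,
                                context_label = "default",
                                score_floor = -0.99) {
  prom_ids <- paste0("prom:", genes$gene_id)
  missing <- genes$gene_id[!prom_ids %in% rownames(signal_table)]
  if (length(missing)) {
    stop("genes missing from signal table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  all_enh <- unique(unlist(lapply(reg_map, function(g) g$enhancers$name),
                           use.names = FALSE))
  missing_enh <- setdiff(all_enh, rownames(signal_table))
  if (length(missing_enh)) {
    stop("enhancer peaks missing from signal table: ",
         paste(utils::head(missing_enh, 5), collapse = ", "))
  }
  is_prom <- startsWith(rownames(signal_table), "prom:")
  prom_tab <- signal_table[is_prom, , drop = FALSE]
  enh_tab <- signal_table[!is_prom, , drop = FALSE]
  assays <- names(signal_table)

  out <- data.frame(gene_id = genes$gene_id, context = context_label,
                    stringsAsFactors = FALSE)
  for (a in assays) {
    zp <- zscore(prom_tab, a)
    out[[paste0(a, "_promoter")]] <- as.numeric(zp[prom_ids])
    ze <- if (nrow(enh_tab) >= 2 && stats::sd(enh_tab[[a]]) > 0) {
      zscore(enh_tab, a)
    } else {
      stats::setNames(rep(0, nrow(enh_tab)), rownames(enh_tab))
    }
    out[[paste0(a, "_enh_score")]] <- vapply(genes$gene_id, function(g) {
      enhancer_score(as.numeric(ze[reg_map[[g]]$enhancers$name]),
                     floor = score_floor)
    }, numeric(1), USE.NAMES = FALSE)
  }
  out$n_enhancers <- vapply(reg_map[genes$gene_id],
                            function(g) nrow(g$enhancers), 1L)
  out$n_ERBS <- as.integer(count_erbs(reg_map[genes$gene_id]))
  out$gene_length <- genes$length
  stopifnot(!anyNA(out))
  out
}

# subset method keeping the class
#' @export
`[.regulatory_map` <- function(x, i) {
  structure(NextMethod(), class = "regulatory_map")
}

#' Average promoter and enhancer axes for confirmed features
#'
#' For each label class, averages the per-gene mean of the confirmed
#' promoter features (columns `*_promoter`) and, separately, of the
#' confirmed enhancer-score features (columns `*_enh_score`), with 95%
#' normal-approximation confidence intervals. Count features
#' (`n_enhancers`, `n_ERBS`) and `gene_length` are never part of either
#' axis.
#'
#' @param feature_table from [build_feature_table()]
#' @param confirmed_features character vector of confirmed column names
#' @param labels factor/character vector of per-row class labels
#' @return data.frame (class, axis, mean, ci_lo, ci_hi, n)
#' @export
aggregate_axes <- function(feature_table, confirmed_features, labels) {
  excluded <- c("n_enhancers", "n_ERBS", "gene_length")
  confirmed_features <- setdiff(confirmed_features, excluded)
  prom <- grep("_promoter$", confirmed_features, value = TRUE)
  enh <- grep("_enh_score$", confirmed_features, value = TRUE)
  if (!length(prom) || !length(enh)) {
    stop("need at least one confirmed promoter and one confirmed enhancer feature")
  }
  labels <- as.factor(labels)
  if (any(table(labels) < 2)) {
    stop("every class needs >= 2 genes: ",
         paste(names(which(table(labels) < 2)), collapse = ", "))
  }
  axis_means <- function(cols) rowMeans(feature_table[, cols, drop = FALSE])
  per_gene <- list(promoter = axis_means(prom), enhancer = axis_means(enh))
  out <- do.call(rbind, lapply(names(per_gene), function(ax) {
    v <- per_gene[[ax]]
    do.call(rbind, lapply(levels(labels), function(cl) {
      x <- v[labels == cl]
      se <- stats::sd(x) / sqrt(length(x))
      data.frame(class = cl, axis = ax, mean = mean(x),
                 ci_lo = mean(x) - 1.96 * se, ci_hi = mean(x) + 1.96 * se,
                 n = length(x), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
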