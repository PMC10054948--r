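#' Single-cell expression time course container
#'
#' Holds a genes x cells count matrix (sparse or dense), per-cell metadata
#' with timepoint labels, and, after [normalize_counts()], a log-normalized
#' layer.
#'
#' @param counts genes x cells matrix of non-negative integer counts with
#'   dimnames
#' @param cell_meta data.frame with columns `cell_id` and `timepoint`
#'   (hours); optional `pct_mito`, `context`
#' @return object of class `expression_timecourse`
#' @export
expression_timecourse <- function(counts, cell_meta) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene and cell names")
  }
  if (!all(c("cell_id", "timepoint") %in% names(cell_meta))) {
    stop("cell_meta needs cell_id and timepoint columns")
  }
  if (!identical(colnames(counts), cell_meta$cell_id)) {
    stop("cell_meta rows must match counts columns")
  }
  structure(list(counts = counts, cell_meta = cell_meta, normalized = NULL),
            class = "expression_timecourse")
}

#' @export
print.expression_timecourse <- function(x, ...) {
  cat("expression_timecourse:", nrow(x$counts), "genes x", ncol(x$counts),
      "cells;", "timepoints", paste(sort(unique(x$cell_meta$timepoint)),
                                    collapse = "/"), "h;",
      if (is.null(x$normalized)) "raw counts only" else "normalized layer present",
      "\n")
  invisible(x)
}

#' Per-cell QC statistics
#'
#' Total counts, number of detected genes and percent mitochondrial counts
#' (genes whose name starts with "MT-"; 0 when none exist, unless
#' `cell_meta$pct_mito` is supplied, which takes precedence).
#'
#' @param tc an `expression_timecourse`
#' @return data.frame (cell_id, total_counts, n_genes, pct_mito)
#' @export
cell_qc <- function(tc) {
  total <- Matrix::colSums(tc$counts)
  ngene <- Matrix::colSums(tc$counts > 0)
  if (!is.null(tc$cell_meta$pct_mito)) {
    mito <- tc$cell_meta$pct_mito
  } else {
    mt <- startsWith(rownames(tc$counts), "MT-")
    mito <- if (any(mt)) {
      100 * Matrix::colSums(tc$counts[mt, , drop = FALSE]) / pmax(total, 1)
    } else rep(0, ncol(tc$counts))
  }
  data.frame(cell_id = colnames(tc$counts), total_counts = as.numeric(total),
             n_genes = as.numeric(ngene), pct_mito = as.numeric(mito),
             stringsAsFactors = FALSE)
}

#' Filter cells on QC bounds
#'
#' Keeps cells satisfying all supplied bounds: total counts and detected
#' genes within inclusive `[min, max]` ranges and percent mitochondrial
#' strictly below `max_pct_mito`. `NULL` bounds are not applied.
#'
#' @param tc an `expression_timecourse`
#' @param min_counts,max_counts inclusive bounds on total counts per cell
#' @param min_genes,max_genes inclusive bounds on detected genes per cell
#' @param max_pct_mito exclusive upper bound on percent mitochondrial
#' @return the filtered `expression_timecourse`
#' @export
filter_cells <- function(tc, min_counts = NULL, max_counts = NULL,
                         min_genes = NULL, max_genes = NULL,
                         max_pct_mito = NULL) {
  qc <- cell_qc(tc)
  keep <- rep(TRUE, nrow(qc))
  if (!is.null(min_counts)) keep <- keep & qc$total_counts >= min_counts
  if (!is.null(max_counts)) keep <- keep & qc$total_counts <= max_counts
  if (!is.null(min_genes)) keep <- keep & qc$n_genes >= min_genes
  if (!is.null(max_genes)) keep <- keep & qc$n_genes <= max_genes
  if (!is.null(max_pct_mito)) keep <- keep & qc$pct_mito < max_pct_mito
  if (!any(keep)) stop("cell filtering removed all cells")
  out <- tc
  out$counts <- tc$counts[, keep, drop = FALSE]
  out$cell_meta <- tc$cell_meta[keep, , drop = FALSE]
  if (!is.null(tc$normalized)) {
    out$normalized <- tc$normalized[, keep, drop = FALSE]
  }
  out
}

#' Log-normalize counts
#'
#' Per cell: `x -> ln(1 + scale * x / total)`, the standard log
#' normalization of scRNA-seq counts.
#'
#' @param tc an `expression_timecourse`
#' @param scale size-factor target (default 10,000)
#' @return `tc` with the `normalized` layer filled in
#' @export
normalize_counts <- function(tc, scale = 1e4) {
  totals <- Matrix::colSums(tc$counts)
  if (any(totals == 0)) {
    stop("cells with zero counts cannot be normalized: ",
         paste(utils::head(colnames(tc$counts)[totals == 0], 3), collapse = ", "))
  }
  tc$normalized <- log1p(tc$counts %*% Matrix::Diagonal(x = scale / totals))
  dimnames(tc$normalized) <- dimnames(tc$counts)
  tc
}

#' Filter genes on minimum expression at every timepoint
#'
#' A gene is kept iff its mean normalized expression exceeds `min_mean`
#' within every timepoint ("across all timepoints" read per-timepoint; set
#' `per_timepoint = FALSE` for a pooled mean).
#'
#' @param tc a normalized `expression_timecourse`
#' @param min_mean threshold (exclusive)
#' @param per_timepoint require the threshold within every timepoint
#' @return the filtered `expression_timecourse`
#' @export
filter_genes <- function(tc, min_mean = 0.01, per_timepoint = TRUE) {
  if (is.null(tc$normalized)) stop("normalize_counts() first")
  if (per_timepoint) {
    keep <- rep(TRUE, nrow(tc$normalized))
    for (t in unique(tc$cell_meta$timepoint)) {
      m <- Matrix::rowMeans(tc$normalized[, tc$cell_meta$timepoint == t,
                                          drop = FALSE])
      keep <- keep & m > min_mean
    }
  } else {
    keep <- Matrix::rowMeans(tc$normalized) > min_mean
  }
  tc$counts <- tc$counts[keep, , drop = FALSE]
  tc$normalized <- tc$normalized[keep, , drop = FALSE]
  tc
}

# Vectorized two-sided Wilcoxon rank-sum with tie correction and continuity
# correction; agrees with stats::wilcox.test(exact = FALSE, correct = TRUE).
rank_sum_test <- function(mat_a, mat_b) {
  n1 <- ncol(mat_a); n2 <- ncol(mat_b)
  p <- numeric(nrow(mat_a)); w <- numeric(nrow(mat_a))
  for (i in seq_len(nrow(mat_a))) {
    x <- c(mat_a[i, ], mat_b[i, ])
    r <- rank(x)
    stat <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    nt <- table(x)
    tie_term <- sum(nt^3 - nt)
    sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term /
                                ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 <= 0) { p[i] <- 1; w[i] <- stat; next }
    z <- stat - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p[i] <- min(1, 2 * stats::pnorm(-abs(z)))
    w[i] <- stat
  }
  list(p = p, statistic = w)
}

#' Per-gene differential test between two timepoints
#'
#' Two-sided Wilcoxon rank-sum test on normalized expression of each gene,
#' cells at timepoint `t` vs cells at `t_ref`, with no fold-change cutoff.
#' Direction is the sign of the mean difference. Degenerate genes (all
#' values tied) get p = 1 and direction 0.
#'
#' @param tc a normalized `expression_timecourse`
#' @param t test timepoint (hours)
#' @param t_ref reference timepoint (default 0)
#' @return data.frame (gene_id, p, direction, mean_t, mean_ref)
#' @export
call_differential <- function(tc, t, t_ref = 0) {
  if (is.null(tc$normalized)) stop("normalize_counts() first")
  ia <- tc$cell_meta$timepoint == t
  ib <- tc$cell_meta$timepoint == t_ref
  if (sum(ia) < 2 || sum(ib) < 2) stop("need >= 2 cells at both timepoints")
  a <- as.matrix(tc$normalized[, ia, drop = FALSE])
  b <- as.matrix(tc$normalized[, ib, drop = FALSE])
  res <- rank_sum_test(a, b)
  mt <- rowMeans(a); mr <- rowMeans(b)
  dir <- sign(mt - mr)
  dir[res$p >= 1 & mt == mr] <- 0
  data.frame(gene_id = rownames(tc$normalized), p = res$p, direction = dir,
             mean_t = mt, mean_ref = mr, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify temporal response trajectories
#'
#' Genes significantly changed at 2 h (after multiple-testing correction
#' across genes, per timepoint) are Early, with direction from the 2 h
#' sign; genes first significant at 4 or 8 h are Late, with direction from
#' the first significant timepoint; everything else is Unlabeled.
#'
#' @param de_results named list of [call_differential()] outputs with names
#'   "2", "4", "8" (hours vs 0 h)
#' @param alpha significance level on corrected p-values
#' @param correction p-value adjustment method (see [stats::p.adjust()])
#' @return data.frame (gene_id, trajectory, p2, p4, p8, dir2, dir4, dir8)
#'   with corrected p-values
#' @export
assign_trajectories <- function(de_results, alpha = 0.05,
                                correction = "BH") {
  need <- c("2", "4", "8")
  if (!all(need %in% names(de_results))) {
    stop("de_results must contain timepoints 2, 4 and 8")
  }
  gid <- de_results[["2"]]$gene_id
  padj <- lapply(de_results[need], function(d) {
    stopifnot(identical(d$gene_id, gid))
    stats::p.adjust(d$p, method = correction)
  })
  dirs <- lapply(de_results[need], function(d) d$direction)
  sig <- lapply(padj, function(p) p < alpha)
  traj <- rep("Unlabeled", length(gid))
  early <- sig[["2"]]
  traj[early & dirs[["2"]] > 0] <- "EarlyUp"
  traj[early & dirs[["2"]] <= 0] <- "EarlyDown"
  late <- !early & (sig[["4"]] | sig[["8"]])
  first_dir <- ifelse(sig[["4"]], dirs[["4"]], dirs[["8"]])
  traj[late & first_dir > 0] <- "LateUp"
  traj[late & first_dir <= 0] <- "LateDown"
  data.frame(gene_id = gid, trajectory = traj,
             p2 = padj[["2"]], p4 = padj[["4"]], p8 = padj[["8"]],
             dir2 = dirs[["2"]], dir4 = dirs[["4"]], dir8 = dirs[["8"]],
             stringsAsFactors = FALSE)
}

#' Select mean-matched control genes by stratified sampling
#'
#' Samples unregulated (Unlabeled) genes so that their mean-expression
#' decile counts match those of the regulated genes, giving a control set
#' with the same mean distribution.
#'
#' @param labels trajectory data.frame from [assign_trajectories()]
#' @param means named per-gene mean expression (0 h), covering all genes in
#'   `labels`
#' @param n_bins number of mean bins (default 10)
#' @param seed RNG seed
#' @return character vector of control gene ids
#' @export
select_controls <- function(labels, means, n_bins = 10, seed = 1) {
  set.seed(seed)
  means <- means[labels$gene_id]
  bins <- mean_bins(means, n_bins)
  regulated <- labels$trajectory != "Unlabeled"
  controls <- character(0)
  for (b in seq_len(n_bins)) {
    need <- sum(regulated & bins == b)
    if (need == 0) next
    pool <- labels$gene_id[!regulated & bins == b]
    if (length(pool) < need) {
      stop("not enough unregulated genes in mean bin ", b, ": need ", need,
           ", have ", length(pool))
    }
    controls <- c(controls, sample(pool, need))
  }
  controls
}

# equal-frequency bins; ties broken by stable (input) order
mean_bins <- function(means, n_bins) {
  ord <- order(means, seq_along(means))
  bins <- integer(length(means))
  bins[ord] <- ceiling(seq_along(means) / (length(means) / n_bins))
  pmin(bins, n_bins)
}

#' Classify genes into Low/Mid/High mean-expression levels
#'
#' Bottom 20% of genes by mean are Low, top 20% High, the middle 60% Mid.
#' Ties are broken by stable gene order so the split is deterministic.
#'
#' @param means named numeric vector of per-gene means
#' @param q tail fraction (default 0.2)
#' @return factor (levels Low, Mid, High) named by gene
#' @export
classify_mean_levels <- function(means, q = 0.2) {
  if (length(means) < 5) stop("need >= 5 genes")
  if (max(means) == min(means)) {
    stop("degenerate mean distribution: all means equal")
  }
  n <- length(means)
  ord <- order(means, seq_along(means))
  k <- floor(q * n)
  lab <- rep("Mid", n)
  lab[ord[seq_len(k)]] <- "Low"
  lab[ord[(n - k + 1):n]] <- "High"
  stats::setNames(factor(lab, levels = c("Low", "Mid", "High")), names(means))
}

#' Per-gene mean and CV at one timepoint
#'
#' @param tc a normalized `expression_timecourse`
#' @param timepoint hours (default 0)
#' @return data.frame (gene_id, mean, cv)
#' @export
noise_stats <- function(tc, timepoint = 0) {
  if (is.null(tc$normalized)) stop("normalize_counts() first")
  m <- as.matrix(tc$normalized[, tc$cell_meta$timepoint == timepoint,
                               drop = FALSE])
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  data.frame(gene_id = rownames(m), mean = mu,
             cv = ifelse(mu > 0, s / mu, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mean-corrected transcriptional noise (GAM-adjusted CV)
#'
#' Fits a penalized cubic-spline GAM of `log2(CV + 1)` on mean expression
#' (`y ~ s(x, bs = "cs")`) and back-transforms the residuals to the CV
#' scale: adjusted CV = `2^(y - yhat) - 1` (multiplicative form; set
#' `backtransform = "subtract"` for CV minus fitted CV).
#'
#' @param means per-gene mean expression
#' @param cvs per-gene coefficient of variation
#' @param backtransform "multiplicative" (default) or "subtract"
#' @return numeric vector of adjusted CV values
#' @export
adjusted_cv <- function(means, cvs,
                        backtransform = c("multiplicative", "subtract")) {
  backtransform <- match.arg(backtransform)
  if (length(means) < 30) stop("need >= 30 genes for a stable GAM fit")
  ok <- is.finite(means) & is.finite(cvs)
  if (!all(ok)) stop("means and cvs must be finite")
  y <- log2(cvs + 1)
  fit <- mgcv::gam(y ~ s(x, bs = "cs"), data = data.frame(x = means, y = y))
  r <- y - as.numeric(stats::predict(fit))
  if (backtransform == "multiplicative") 2^r - 1
  else cvs - (2^as.numeric(stats::predict(fit)) - 1)
}

#' Label noise levels within mean bins
#'
#' Genes are cut into `n_bins` equal-frequency mean bins; within each bin
#' the top `q` fraction by adjusted CV is labeled High, the bottom `q`
#' fraction Low, the rest Mid.
#'
#' @param noise_table data.frame with gene_id, mean and adjusted_cv
#' @param n_bins number of mean bins (default 10)
#' @param q tail fraction per bin (default 0.2)
#' @return `noise_table` with `mean_bin` and `noise_level` columns
#' @export
assign_noise_levels <- function(noise_table, n_bins = 10, q = 0.2) {
  bins <- mean_bins(noise_table$mean, n_bins)
  if (any(table(bins) < 5)) stop("a mean bin has < 5 genes")
  lab <- rep("Mid", nrow(noise_table))
  for (b in seq_len(n_bins)) {
    idx <- which(bins == b)
    k <- floor(q * length(idx))
    if (k == 0) next
    ord <- idx[order(noise_table$adjusted_cv[idx], idx)]
    lab[ord[seq_len(k)]] <- "Low"
    lab[ord[(length(ord) - k + 1):length(ord)]] <- "High"
  }
  noise_table$mean_bin <- bins
  noise_table$noise_level <- factor(lab, levels = c("High", "Mid", "Low"))
  noise_table
}

#' Compare a gene-level covariate between a class and its controls
#'
#' Two-sample Kolmogorov-Smirnov test plus the standardized shift
#' `(mean(group) - mean(control)) / sd(control)`; used e.g. to compare
#' mRNA half-lives of a trajectory class against control genes.
#'
#' @param covariate named numeric vector (gene -> value)
#' @param group_ids gene ids of the class
#' @param control_ids gene ids of the control set
#' @return list(p, shift, n_group, n_control)
#' @export
compare_covariate <- function(covariate, group_ids, control_ids) {
  g <- covariate[group_ids]; ctl <- covariate[control_ids]
  if (mean(is.na(g)) > 0.5 || mean(is.na(ctl)) > 0.5) {
    stop("covariate missing for more than half of a group")
  }
  g <- g[!is.na(g)]; ctl <- ctl[!is.na(ctl)]
  if (length(g) < 5 || length(ctl) < 5) stop("need >= 5 genes per group")
  ks <- suppressWarnings(stats::ks.test(g, ctl))
  list(p = ks$p.value, shift = (mean(g) - mean(ctl)) / stats::sd(ctl),
       n_group = length(g), n_control = length(ctl))
}
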