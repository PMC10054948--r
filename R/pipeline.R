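#' Read a single-cell count matrix from MTX + sidecar TSVs
#'
#' @param mtx MatrixMarket file of genes x cells counts
#' @param features text file of gene ids (one per line)
#' @param barcodes text file of cell ids (one per line)
#' @param cells cell-metadata TSV with cell_id and timepoint columns
#' @return an `expression_timecourse`
#' @export
read_counts_mtx <- function(mtx, features, barcodes, cells) {
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  rownames(m) <- readLines(features)
  colnames(m) <- readLines(barcodes)
  meta <- utils::read.table(cells, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  meta <- meta[match(colnames(m), meta$cell_id), ]
  expression_timecourse(m, meta)
}

#' Build the feature table from files on disk
#'
#' Reads annotation, loops, peak BEDs and the signal table, applies the
#' loop filter, assigns enhancers, and writes/returns the per-gene feature
#' table.
#'
#' @param annotation,loops,h3k27ac,er,signal input file paths
#' @param out optional output TSV path
#' @param context_label context tag for the rows
#' @return the feature table (invisibly if `out` is given)
#' @export
run_features <- function(annotation, loops, h3k27ac, er, signal,
                         out = NULL, context_label = "default") {
  genes <- read_annotation(annotation)
  lp <- filter_loops(read_loops(loops))
  peaks <- read_bed(h3k27ac)
  erp <- read_bed(er)
  sig <- read_signal(signal)
  prom <- define_promoters(genes)
  reg <- assign_enhancers(prom, lp, peaks, er_peaks = erp)
  ft <- build_feature_table(reg, sig, genes, context_label = context_label)
  if (!is.null(out)) {
    write_tsv(ft, out)
    return(invisible(ft))
  }
  ft
}

#' Run QC, normalization, trajectory and noise labelling from files
#'
#' @param mtx,features,barcodes,cells count-matrix files (see
#'   [read_counts_mtx()])
#' @param out optional output TSV path
#' @param alpha significance level for trajectory calls
#' @param correction multiple-testing method
#' @param min_mean gene-filter threshold
#' @param n_bins mean bins for noise labelling
#' @param seed RNG seed (control-gene sampling)
#' @return data.frame with per-gene trajectory, mean-level and noise labels
#' @export
run_dynamics <- function(mtx, features, barcodes, cells, out = NULL,
                         alpha = 0.05, correction = "BH", min_mean = 0.01,
                         n_bins = 10, seed = 1) {
  tc <- read_counts_mtx(mtx, features, barcodes, cells)
  tc <- normalize_counts(tc)
  tc <- filter_genes(tc, min_mean = min_mean)
  labels <- label_timecourse(tc, alpha = alpha, correction = correction,
                             n_bins = n_bins, seed = seed)
  if (!is.null(out)) {
    write_tsv(labels, out)
    return(invisible(labels))
  }
  labels
}

#' Label a normalized time course: trajectories, mean levels, noise
#'
#' Runs the per-timepoint Wilcoxon differential calls against 0 h,
#' classifies trajectories, selects mean-matched controls, classifies
#' 0-h mean levels, and computes the GAM-adjusted CV with binned noise
#' labels.
#'
#' @param tc a normalized, gene-filtered `expression_timecourse`
#' @param alpha,correction trajectory-call settings
#' @param n_bins mean bins for noise labels and control sampling
#' @param seed RNG seed for control sampling
#' @return per-gene data.frame (gene_id, trajectory, mean_level,
#'   noise_level, mean, cv, adjusted_cv, mean_bin, p2, p4, p8); control
#'   genes carry trajectory "Control"
#' @export
label_timecourse <- function(tc, alpha = 0.05, correction = "BH",
                             n_bins = 10, seed = 1) {
  tps <- setdiff(sort(unique(tc$cell_meta$timepoint)), 0)
  de <- lapply(tps, function(t) call_differential(tc, t))
  names(de) <- tps
  traj <- assign_trajectories(de, alpha = alpha, correction = correction)

  ns <- noise_stats(tc, timepoint = 0)
  means <- stats::setNames(ns$mean, ns$gene_id)
  ctrl <- tryCatch(
    select_controls(traj, means, n_bins = n_bins, seed = seed),
    error = function(e) character(0))
  traj$trajectory[traj$gene_id %in% ctrl] <- "Control"

  mean_level <- classify_mean_levels(means)
  ok <- is.finite(ns$cv)
  ns$adjusted_cv <- NA_real_
  ns$adjusted_cv[ok] <- adjusted_cv(ns$mean[ok], ns$cv[ok])
  nt <- assign_noise_levels(ns[ok, ], n_bins = n_bins)
  out <- merge(traj, nt[, c("gene_id", "mean", "cv", "adjusted_cv",
                            "mean_bin", "noise_level")],
               by = "gene_id", all.x = TRUE, sort = FALSE)
  out$mean_level <- as.character(mean_level[out$gene_id])
  out <- out[match(traj$gene_id, out$gene_id),
             c("gene_id", "trajectory", "mean_level", "noise_level",
               "mean", "cv", "adjusted_cv", "mean_bin",
               "p2", "p4", "p8", "dir2", "dir4", "dir8")]
  rownames(out) <- NULL
  out
}
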