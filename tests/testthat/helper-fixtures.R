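# Small shared fixtures, built in code at test time.

# tiny expression_timecourse with known counts; genes x cells
toy_timecourse <- function(counts, timepoints, pct_mito = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  }
  colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  meta <- data.frame(cell_id = colnames(counts), timepoint = timepoints,
                     stringsAsFactors = FALSE)
  if (!is.null(pct_mito)) meta$pct_mito <- pct_mito
  expression_timecourse(Matrix::Matrix(counts, sparse = TRUE), meta)
}

# quadratic brute-force interval intersector (0-based half-open)
brute_overlap <- function(query, subject) {
  out <- list()
  k <- 0L
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(subject))) {
      if (query$chrom[i] == subject$chrom[j] &&
          max(query$start[i], subject$start[j]) <
          min(query$end[i], subject$end[j])) {
        k <- k + 1L
        out[[k]] <- c(i, j)
      }
    }
  }
  if (!k) return(data.frame(query = integer(0), subject = integer(0)))
  m <- do.call(rbind, out)
  data.frame(query = m[, 1], subject = m[, 2])
}

# small default simulation shared by several tests
small_sim <- function(seed = 101, n_genes = 80, cells = 50, ...) {
  cfg <- sim_config(n_genes = n_genes, n_cells_per_timepoint = cells, ...)
  genes <- generate_annotation(cfg$n_genes, seed = seed)
  arch <- generate_architecture(genes, cfg, seed = seed + 1)
  tc <- generate_expression(genes, arch$truth, cfg, seed = seed + 2)
  list(cfg = cfg, genes = genes, arch = arch, tc = tc)
}
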