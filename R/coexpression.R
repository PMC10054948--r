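canonical_pairs <- function(gene_a, gene_b, pair_class) {
  a <- pmin(gene_a, gene_b); b <- pmax(gene_a, gene_b)
  keep <- a != b
  df <- unique(data.frame(gene_a = a[keep], gene_b = b[keep],
                          stringsAsFactors = FALSE))
  df$pair_class <- pair_class
  rownames(df) <- NULL
  df
}

#' Gene pairs whose promoters loop to one another
#'
#' Loops (already filtered) whose two anchors overlap the promoters of two
#' distinct genes define PromoterLooped pairs; unordered duplicates are
#' removed.
#'
#' @param promoters promoter regions (names = gene ids)
#' @param filtered_loops loops passing [filter_loops()]
#' @return data.frame (gene_a, gene_b, pair_class)
#' @export
promoter_looped_pairs <- function(promoters, filtered_loops) {
  a1 <- data.frame(chrom = filtered_loops$chrom1,
                   start = filtered_loops$start1, end = filtered_loops$end1)
  a2 <- data.frame(chrom = filtered_loops$chrom2,
                   start = filtered_loops$start2, end = filtered_loops$end2)
  h1 <- overlap_pairs(promoters, a1)
  h2 <- overlap_pairs(promoters, a2)
  g1 <- split(promoters$name[h1$query], h1$subject)
  g2 <- split(promoters$name[h2$query], h2$subject)
  pairs <- list()
  for (lp in intersect(names(g1), names(g2))) {
    combos <- expand.grid(a = g1[[lp]], b = g2[[lp]],
                          stringsAsFactors = FALSE)
    pairs[[lp]] <- combos
  }
  if (!length(pairs)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      pair_class = character(0)))
  }
  all <- do.call(rbind, pairs)
  canonical_pairs(all$a, all$b, "PromoterLooped")
}

#' Gene pairs sharing an enhancer
#'
#' Pairs of genes whose enhancer sets share at least one peak (by peak
#' id); a group of k genes on one shared enhancer yields all C(k,2) pairs.
#'
#' @param reg_map a `regulatory_map`
#' @return data.frame (gene_a, gene_b, pair_class)
#' @export
shared_enhancer_pairs <- function(reg_map) {
  genes_by_peak <- list()
  for (g in names(reg_map)) {
    for (pk in reg_map[[g]]$enhancers$name) {
      genes_by_peak[[pk]] <- c(genes_by_peak[[pk]], g)
    }
  }
  pairs <- list()
  for (pk in names(genes_by_peak)) {
    gs <- unique(genes_by_peak[[pk]])
    if (length(gs) < 2) next
    cmb <- utils::combn(gs, 2)
    pairs[[pk]] <- data.frame(a = cmb[1, ], b = cmb[2, ],
                              stringsAsFactors = FALSE)
  }
  if (!length(pairs)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      pair_class = character(0)))
  }
  all <- do.call(rbind, pairs)
  canonical_pairs(all$a, all$b, "SharedEnhancer")
}

#' Shuffled-pair null control
#'
#' Re-pairs the genes by permuting the second elements, rejecting
#' permutations that create self-pairs or reproduce an original pair;
#' preserves each gene's pair multiplicity and the set cardinality.
#'
#' @param pair_set data.frame from a pair constructor (>= 2 pairs)
#' @param seed RNG seed
#' @param max_tries rejection-sampling budget
#' @return data.frame of shuffled pairs (pair_class "ShuffledControl")
#' @export
shuffled_pairs <- function(pair_set, seed = 1, max_tries = 10000) {
  n <- nrow(pair_set)
  if (n < 2) stop("need >= 2 pairs to shuffle")
  orig <- paste(pmin(pair_set$gene_a, pair_set$gene_b),
                pmax(pair_set$gene_a, pair_set$gene_b))
  set.seed(seed)
  for (i in seq_len(max_tries)) {
    b <- sample(pair_set$gene_b)
    key <- paste(pmin(pair_set$gene_a, b), pmax(pair_set$gene_a, b))
    if (any(pair_set$gene_a == b) || any(key %in% orig) ||
        anyDuplicated(key)) next
    out <- data.frame(gene_a = pmin(pair_set$gene_a, b),
                      gene_b = pmax(pair_set$gene_a, b),
                      pair_class = "ShuffledControl",
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }
  stop("no valid shuffled pairing found in ", max_tries,
       " tries (degenerate pair set)")
}

#' Pairwise Spearman correlation over cells
#'
#' Spearman rho (average ranks for ties) for each gene pair over the given
#' cells. Pairs involving a zero-variance gene are dropped; the number
#' dropped is attached as attribute `n_dropped` and reported in a warning.
#'
#' @param expr_matrix genes x cells matrix of normalized expression
#' @param pair_set data.frame with gene_a/gene_b columns
#' @param cells optional cell subset (column names or indices)
#' @param min_cells minimum cells required (default 10)
#' @return numeric vector of rho values, one per retained pair
#' @export
pairwise_spearman <- function(expr_matrix, pair_set, cells = NULL,
                              min_cells = 10) {
  m <- as.matrix(expr_matrix)
  if (!is.null(cells)) m <- m[, cells, drop = FALSE]
  if (ncol(m) < min_cells) stop("need >= ", min_cells, " cells")
  miss <- setdiff(unique(c(pair_set$gene_a, pair_set$gene_b)), rownames(m))
  if (length(miss)) {
    stop("genes absent from matrix: ", paste(utils::head(miss, 3),
                                             collapse = ", "))
  }
  rho <- mapply(function(a, b) {
    x <- m[a, ]; y <- m[b, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }, pair_set$gene_a, pair_set$gene_b, USE.NAMES = FALSE)
  n_dropped <- sum(is.na(rho))
  if (n_dropped > 0) {
    warning(n_dropped, " pair(s) dropped for zero-variance genes")
  }
  out <- rho[!is.na(rho)]
  attr(out, "n_dropped") <- n_dropped
  attr(out, "kept") <- which(!is.na(rho))
  out
}

#' Compare correlation distributions of two pair groups
#'
#' Two-sided Wilcoxon rank-sum test on the rho distributions with a
#' Bonferroni correction for the size of the comparison family.
#'
#' @param rho_a,rho_b numeric rho vectors
#' @param family_size number of comparisons in the family (default 1)
#' @return list(p_raw, p_adj, median_a, median_b)
#' @export
compare_pair_groups <- function(rho_a, rho_b, family_size = 1) {
  if (!length(rho_a) || !length(rho_b)) stop("both groups must be non-empty")
  p <- suppressWarnings(stats::wilcox.test(rho_a, rho_b)$p.value)
  list(p_raw = p, p_adj = min(1, p * family_size),
       median_a = stats::median(rho_a), median_b = stats::median(rho_b))
}

#' Within-group co-expression over the time course
#'
#' All-pairs Spearman correlations among the genes of one group, computed
#' separately at each timepoint using only that timepoint's cells.
#'
#' @param tc a normalized `expression_timecourse`
#' @param group_genes character vector (>= 2 genes)
#' @param min_cells minimum cells per timepoint
#' @return named list: timepoint -> rho vector
#' @export
correlation_by_group_over_time <- function(tc, group_genes, min_cells = 10) {
  if (length(group_genes) < 2) stop("group needs >= 2 genes")
  if (is.null(tc$normalized)) stop("normalize_counts() first")
  cmb <- utils::combn(sort(group_genes), 2)
  pairs <- data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                      stringsAsFactors = FALSE)
  tps <- sort(unique(tc$cell_meta$timepoint))
  out <- lapply(tps, function(t) {
    suppressWarnings(pairwise_spearman(
      tc$normalized, pairs,
      cells = which(tc$cell_meta$timepoint == t), min_cells = min_cells))
  })
  names(out) <- tps
  out
}

#' Composition of correlation quantiles by noise level
#'
#' Pools the rho values of High-noise and Low-noise gene pairs, cuts the
#' pool into equal-frequency quantile bins, and reports the High/Low
#' composition of each bin. Broader High-noise correlation distributions
#' show up as High enrichment in the extreme bins.
#'
#' @param rho_high,rho_low rho vectors for pairs of High / Low noise genes
#' @param n_quantiles number of bins (default 10)
#' @return data.frame (quantile, prop_high, prop_low, n)
#' @export
correlation_extremes_by_noise <- function(rho_high, rho_low,
                                          n_quantiles = 10) {
  if (!length(rho_high) || !length(rho_low)) {
    stop("both rho sets must be non-empty")
  }
  pool <- c(rho_high, rho_low)
  grp <- rep(c("High", "Low"), c(length(rho_high), length(rho_low)))
  bins <- mean_bins(pool, n_quantiles)
  out <- do.call(rbind, lapply(seq_len(n_quantiles), function(b) {
    g <- grp[bins == b]
    data.frame(quantile = b, prop_high = mean(g == "High"),
               prop_low = mean(g == "Low"), n = length(g))
  }))
  rownames(out) <- NULL
  out
}
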