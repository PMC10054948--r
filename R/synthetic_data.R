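#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generators: the E2-style
#' time course (hours), per-timepoint cell numbers, planted fold changes for
#' Early and Late responders, negative-binomial dispersions for the noise
#' classes, and the coupling strength that ties regulatory architecture to
#' the planted expression classes.
#'
#' Defaults describe the study conditions the generators emulate: a 0/2/4/8 h
#' hormone induction, pulse-like Early responders reaching a
#' `effect_size_early`-fold change at 2 h, delayed Late responders reaching
#' `effect_size_late`-fold by 8 h, and 20/20/60 High/Low/Mid noise classes
#' with NB dispersions 2, 0.1 and 0.5.
#'
#' @param n_genes number of genes to simulate
#' @param n_cells_per_timepoint cells captured at each timepoint
#' @param timepoints hours, strictly increasing, must include 0
#' @param effect_size_early peak fold change of Early genes at 2 h (> 1)
#' @param effect_size_late fold change of Late genes at 8 h (> 1)
#' @param dispersion_low,dispersion_mid,dispersion_high NB dispersion phi
#'   (variance = mu + mu^2 * phi) for the Low/Mid/High noise classes
#' @param coupling_strength in `[0, 1]`; 0 means architecture is independent
#'   of the planted classes, 1 means fully coupled
#' @param library_size_sd sd of per-cell log-normal library-size factors
#' @param fraction_failing_loops fraction of enhancer loops emitted with
#'   reads < 3 or FDR >= 0.05 so that the loop filter removes them
#' @param class_props named proportions for trajectory classes
#' @param noise_props named proportions for noise classes
#' @param mean_meanlog,mean_sdlog log-normal parameters of baseline mean
#'   expression (expected counts/cell at 0 h)
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_genes = 200,
                       n_cells_per_timepoint = 100,
                       timepoints = c(0, 2, 4, 8),
                       effect_size_early = 2,
                       effect_size_late = 2,
                       dispersion_low = 0.1,
                       dispersion_mid = 0.5,
                       dispersion_high = 2,
                       coupling_strength = 1,
                       library_size_sd = 0.3,
                       fraction_failing_loops = 0.3,
                       class_props = c(EarlyUp = 0.025, EarlyDown = 0.025,
                                       LateUp = 0.025, LateDown = 0.025,
                                       Null = 0.9),
                       noise_props = c(High = 0.2, Low = 0.2, Mid = 0.6),
                       mean_meanlog = 0,
                       mean_sdlog = 1) {
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  if (!0 %in% timepoints) stop("timepoints must include 0")
  if (any(c(dispersion_low, dispersion_mid, dispersion_high) <= 0)) {
    stop("all dispersions must be > 0")
  }
  if (effect_size_early < 1 || effect_size_late < 1) {
    stop("fold changes must be >= 1")
  }
  if (coupling_strength < 0 || coupling_strength > 1) {
    stop("coupling_strength must lie in [0, 1]")
  }
  if (abs(sum(class_props) - 1) > 1e-8 || abs(sum(noise_props) - 1) > 1e-8) {
    stop("class proportions must sum to 1")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,", x$n_cells_per_timepoint,
      "cells/timepoint at", paste(x$timepoints, collapse = "/"), "h\n")
  cat("  effect sizes: early", x$effect_size_early, "late", x$effect_size_late,
      "| dispersions (lo/mid/hi):", x$dispersion_low, x$dispersion_mid,
      x$dispersion_high, "| coupling:", x$coupling_strength, "\n")
  invisible(x)
}

TRAJECTORY_CLASSES <- c("EarlyUp", "EarlyDown", "LateUp", "LateDown", "Null")
NOISE_CLASSES <- c("High", "Low", "Mid")

#' Generate a synthetic gene annotation
#'
#' Places one TSS per gene on a single synthetic chromosome with at least
#' `min_spacing` bp between neighbouring TSSs (so 500 bp promoters never
#' overlap), draws gene lengths from a log-normal, and assigns random
#' strands.
#'
#' @param n_genes number of genes (>= 1)
#' @param genome_size chromosome length in bp
#' @param seed RNG seed
#' @param min_spacing minimum TSS-to-TSS distance in bp
#' @return data.frame with columns gene_id, chrom, tss, strand, length,
#'   sorted by tss
#' @export
generate_annotation <- function(n_genes, genome_size = 2.5e8, seed = 1,
                                min_spacing = 1e4) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  needed <- (n_genes - 1) * min_spacing + 1
  if (genome_size < needed) {
    stop("genome_size ", format(genome_size, scientific = FALSE),
         " too small for ", n_genes, " genes at ", min_spacing,
         " bp spacing; need at least ", format(needed, scientific = FALSE))
  }
  set.seed(seed)
  slack <- genome_size - needed
  tss <- floor(sort(stats::runif(n_genes, 0, slack))) +
    (seq_len(n_genes) - 1) * min_spacing
  data.frame(
    gene_id = sprintf("g%05d", seq_len(n_genes)),
    chrom = "chrS",
    tss = tss,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    length = pmax(200, round(stats::rlnorm(n_genes, log(2e4), 0.8))),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic regulatory architecture with planted ground truth
#'
#' Assigns each gene a trajectory class, a noise class and a baseline mean,
#' then builds a regulatory architecture statistically coupled to those
#' classes: EarlyUp genes receive more enhancers and more ER-overlapping
#' enhancers (Poisson rate and Bernoulli probability scaled by
#' `coupling_strength`), LateUp genes receive elevated SIN3A promoter
#' signal, and promoter H3K27ac/POLR2A signal tracks baseline expression.
#' Every enhancer peak sits inside a loop anchor whose partner anchor
#' overlaps the gene's promoter; a configurable fraction of loops is
#' emitted with reads < 3 or FDR >= 0.05 so the loop filter removes them.
#' A sprinkling of promoter-promoter loops and enhancers shared between
#' neighbouring genes feeds the co-expression pair constructors.
#'
#' @param genes annotation from [generate_annotation()]
#' @param config a [sim_config()]
#' @param seed RNG seed
#' @return list with elements `loops` (BEDPE-like data.frame), `h3k27ac` and
#'   `er_peaks` (BED-style data.frames), `signal` (region x assay
#'   data.frame), `truth` (per-gene ground truth incl. post-filter
#'   n_enhancers_true / n_erbs_true) and `informative_features`
#' @export
generate_architecture <- function(genes, config = sim_config(), seed = 1) {
  if (nrow(genes) == 0L) stop("genes must be non-empty")
  set.seed(seed)
  n <- nrow(genes)
  cpl <- config$coupling_strength

  traj <- sample(names(config$class_props), n, replace = TRUE,
                 prob = config$class_props)
  noise <- sample(names(config$noise_props), n, replace = TRUE,
                  prob = config$noise_props)
  base_mean <- stats::rlnorm(n, config$mean_meanlog, config$mean_sdlog)

  lambda <- 2 + 3 * cpl * (traj == "EarlyUp")
  n_enh <- stats::rpois(n, lambda)
  p_er <- pmin(0.95, 0.2 + 0.6 * cpl * (traj == "EarlyUp"))

  enh_rows <- list(); loop_rows <- list(); er_rows <- list()
  n_true <- integer(n); n_erbs_true <- integer(n)
  enh_gene <- integer(0)
  eid <- 0L
  anchor_pad <- 2000
  for (i in seq_len(n)) {
    k <- n_enh[i]
    if (k == 0L) { n_true[i] <- 0L; next }
    off <- sample(c(-1, 1), k, TRUE) * round(stats::runif(k, 5e3, 2e5))
    w <- round(stats::runif(k, 500, 2000))
    s <- pmax(0, genes$tss[i] + off)
    e <- s + w
    ids <- sprintf("enh%06d", eid + seq_len(k)); eid <- eid + k
    failing <- stats::runif(k) < config$fraction_failing_loops
    reads <- ifelse(failing & stats::runif(k) < 0.5,
                    sample(0:2, k, TRUE), 3L + stats::rpois(k, 5))
    fdr <- ifelse(failing & reads >= 3, stats::runif(k, 0.05, 1),
                  stats::runif(k, 0, 0.049))
    er <- stats::runif(k) < p_er[i]
    keep <- reads >= 3 & fdr < 0.05
    n_true[i] <- sum(keep)
    n_erbs_true[i] <- sum(keep & er)
    enh_rows[[i]] <- data.frame(chrom = genes$chrom[i], start = s, end = e,
                                name = ids, stringsAsFactors = FALSE)
    enh_gene <- c(enh_gene, rep(i, k))
    loop_rows[[i]] <- data.frame(
      chrom1 = genes$chrom[i],
      start1 = pmax(0, genes$tss[i] - 2500), end1 = genes$tss[i] + 2500,
      chrom2 = genes$chrom[i],
      start2 = pmax(0, s - anchor_pad), end2 = e + anchor_pad,
      reads = as.integer(reads), fdr = fdr, stringsAsFactors = FALSE)
    if (any(er)) {
      er_rows[[i]] <- data.frame(
        chrom = genes$chrom[i],
        start = s[er] + pmax(1, round(w[er] * 0.25)),
        end = s[er] + pmax(2, round(w[er] * 0.75)),
        name = paste0("er_", ids[er]), stringsAsFactors = FALSE)
    }
  }
  enh <- do.call(rbind, enh_rows)
  if (is.null(enh)) {
    enh <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0))
  }
  loops <- do.call(rbind, loop_rows)
  er_peaks <- do.call(rbind, er_rows)
  if (is.null(er_peaks)) {
    er_peaks <- data.frame(chrom = character(0), start = numeric(0),
                           end = numeric(0), name = character(0))
  }

  # promoter-promoter loops between adjacent genes, and shared enhancers:
  # an enhancer of gene i also looped to gene i+1 (class-agnostic plumbing
  # for the co-expression pair constructors)
  if (n >= 2) {
    pp <- sample(seq_len(n - 1), max(1L, round(0.1 * n)))
    loops <- rbind(loops, data.frame(
      chrom1 = genes$chrom[pp],
      start1 = pmax(0, genes$tss[pp] - 2500), end1 = genes$tss[pp] + 2500,
      chrom2 = genes$chrom[pp + 1],
      start2 = pmax(0, genes$tss[pp + 1] - 2500),
      end2 = genes$tss[pp + 1] + 2500,
      reads = 3L + stats::rpois(length(pp), 5),
      fdr = stats::runif(length(pp), 0, 0.049), stringsAsFactors = FALSE))
    if (nrow(enh) > 0) {
      sh <- which(stats::runif(nrow(enh)) < 0.1 & enh_gene < n)
      if (length(sh)) {
        tgt <- enh_gene[sh] + 1L
        sh_fail <- stats::runif(length(sh)) < config$fraction_failing_loops
        sh_reads <- ifelse(sh_fail, sample(0:2, length(sh), TRUE),
                           3L + stats::rpois(length(sh), 5))
        loops <- rbind(loops, data.frame(
          chrom1 = genes$chrom[tgt],
          start1 = pmax(0, genes$tss[tgt] - 2500),
          end1 = genes$tss[tgt] + 2500,
          chrom2 = enh$chrom[sh],
          start2 = pmax(0, enh$start[sh] - anchor_pad),
          end2 = enh$end[sh] + anchor_pad,
          reads = as.integer(sh_reads),
          fdr = stats::runif(length(sh), 0, 0.049), stringsAsFactors = FALSE))
      }
    }
  }
  rownames(loops) <- NULL

  # integrated signal: promoters then enhancer peaks, one column per assay
  assays <- c("H3K27ac", "POLR2A", "SIN3A", "MAX", "ER", "FOXA1")
  mean_z <- if (n >= 2) as.numeric(scale(log(base_mean))) else 0
  prom_ids <- paste0("prom:", genes$gene_id)
  sig <- matrix(0, nrow = n + nrow(enh), ncol = length(assays),
                dimnames = list(c(prom_ids, enh$name), assays))
  early <- traj %in% c("EarlyUp", "EarlyDown")
  for (a in assays) {
    shift_prom <- switch(a,
      H3K27ac = 0.8 * cpl * mean_z,
      POLR2A = 0.8 * cpl * mean_z,
      SIN3A = 1.0 * cpl * (traj == "LateUp"),
      MAX = 0.6 * cpl * (traj == "LateUp"),
      ER = 0.3 * cpl * (traj == "EarlyUp"),
      FOXA1 = 0.3 * cpl * early)
    sig[seq_len(n), a] <- round(exp(stats::rnorm(n, 4 + shift_prom, 0.8)))
    if (nrow(enh) > 0) {
      g <- enh_gene
      shift_enh <- switch(a,
        H3K27ac = 0.4 * cpl * mean_z[g],
        POLR2A = 0,
        SIN3A = 0,
        MAX = 0,
        ER = 1.0 * cpl * (traj[g] == "EarlyUp"),
        FOXA1 = 0.5 * cpl * early[g])
      sig[n + seq_len(nrow(enh)), a] <-
        round(exp(stats::rnorm(nrow(enh), 4 + shift_enh, 0.8)))
    }
  }

  truth <- data.frame(
    gene_id = genes$gene_id,
    true_trajectory = factor(traj, levels = TRAJECTORY_CLASSES),
    true_noise = factor(noise, levels = NOISE_CLASSES),
    true_mean_level = base_mean,
    n_enhancers_true = n_true,
    n_erbs_true = n_erbs_true,
    stringsAsFactors = FALSE
  )
  list(loops = loops, h3k27ac = enh, er_peaks = er_peaks,
       signal = as.data.frame(sig), truth = truth,
       informative_features = c("SIN3A_promoter", "MAX_promoter",
                                "ER_enh_score", "H3K27ac_promoter",
                                "POLR2A_promoter", "n_enhancers", "n_ERBS"))
}

# planted mean multiplier at time t for one trajectory class.
# Early: piecewise log-linear pulse peaking at 2 h with 50% decay of the
# log-fold-change by 8 h. Late: flat through 2 h, then log-linear to the
# 8 h fold change (first detectable change after 2 h, as the class requires).
trajectory_multiplier <- function(trajectory, t, effect_early, effect_late) {
  w_early <- stats::approx(x = c(0, 2, 8), y = c(0, 1, 0.5), xout = t,
                           rule = 2)$y
  w_late <- pmax(0, (t - 2) / 6)
  switch(trajectory,
         EarlyUp = exp(log(effect_early) * w_early),
         EarlyDown = exp(-log(effect_early) * w_early),
         LateUp = exp(log(effect_late) * w_late),
         LateDown = exp(-log(effect_late) * w_late),
         Null = rep(1, length(t)))
}

#' Generate a synthetic single-cell expression time course
#'
#' Draws negative-binomial counts for every gene and cell: gene g at
#' timepoint t has mean `true_mean_level * m(trajectory, t) * lib_c` where
#' `m` is the planted trajectory multiplier (pulse for Early, delayed rise
#' for Late, mirrored for Down, flat for Null), `lib_c` is a per-cell
#' log-normal library-size factor, and the NB dispersion is set by the
#' gene's planted noise class.
#'
#' @param genes annotation data.frame
#' @param truth ground-truth data.frame from [generate_architecture()]
#' @param config a [sim_config()]
#' @param seed RNG seed
#' @return an [expression_timecourse()] with a sparse counts matrix
#'   (genes x cells) and cell metadata carrying timepoint labels
#' @export
generate_expression <- function(genes, truth, config = sim_config(),
                                seed = 1) {
  if (!all(genes$gene_id %in% truth$gene_id)) {
    stop("truth must cover all genes")
  }
  set.seed(seed)
  truth <- truth[match(genes$gene_id, truth$gene_id), ]
  tps <- config$timepoints
  ncell <- config$n_cells_per_timepoint
  n_cells <- length(tps) * ncell
  n <- nrow(genes)

  timepoint <- rep(tps, each = ncell)
  lib <- stats::rlnorm(n_cells, 0, config$library_size_sd)
  phi <- c(High = config$dispersion_high, Low = config$dispersion_low,
           Mid = config$dispersion_mid)[as.character(truth$true_noise)]

  counts <- matrix(0L, nrow = n, ncol = n_cells)
  for (tr in TRAJECTORY_CLASSES) {
    gi <- which(truth$true_trajectory == tr)
    if (!length(gi)) next
    mult <- trajectory_multiplier(tr, tps, config$effect_size_early,
                                  config$effect_size_late)
    mult_cell <- rep(mult, each = ncell) * lib
    mu <- outer(truth$true_mean_level[gi], mult_cell)
    counts[gi, ] <- stats::rnbinom(length(mu), mu = mu,
                                   size = rep(1 / phi[gi], ncol(mu)))
  }
  dimnames(counts) <- list(genes$gene_id,
                           sprintf("cell%05d", seq_len(n_cells)))
  cell_meta <- data.frame(cell_id = colnames(counts), timepoint = timepoint,
                          context = "synthetic", stringsAsFactors = FALSE)
  expression_timecourse(Matrix::Matrix(counts, sparse = TRUE), cell_meta)
}

#' Generate a synthetic qPCR Ct table
#'
#' Emits Ct values for a target gene and a reference gene under several
#' conditions such that the delta-delta-Ct method recovers, in expectation,
#' the supplied relative-expression curves (relative to the control
#' condition at 0 h). Gaussian noise with sd `noise_sd` is added to every
#' Ct measurement independently.
#'
#' @param curves named list of functions `f(hours) -> relative expression`,
#'   one per condition; must contain `control_condition`, and the control
#'   curve should equal 1 at 0 h for the relative scale to be anchored
#' @param timepoints hours at which Ct is measured (must include 0)
#' @param n_reps replicates per condition/timepoint
#' @param noise_sd Gaussian sd on each Ct value (cycles)
#' @param seed RNG seed
#' @param target_gene,reference_gene gene labels in the output
#' @param control_condition name of the control curve
#' @param reference_ct true Ct of the reference gene
#' @param baseline_dct true delta-Ct (target - reference) of the control at
#'   0 h
#' @return data.frame (condition, replicate, hours, gene, ct)
#' @export
generate_qpcr <- function(curves, timepoints = c(0, 1, 2, 4, 6, 8),
                          n_reps = 2, noise_sd = 0, seed = 1,
                          target_gene = "TARGET", reference_gene = "CTCF",
                          control_condition = "control",
                          reference_ct = 15, baseline_dct = 5) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!control_condition %in% names(curves)) {
    stop("curves must include the control condition '", control_condition, "'")
  }
  if (!0 %in% timepoints) stop("timepoints must include 0")
  set.seed(seed)
  grid <- expand.grid(condition = names(curves), replicate = seq_len(n_reps),
                      hours = timepoints, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  y <- mapply(function(cond, t) curves[[cond]](t), grid$condition, grid$hours)
  if (any(y <= 0)) stop("relative-expression curves must be positive")
  ct_target <- reference_ct + baseline_dct - log2(y) +
    stats::rnorm(nrow(grid), 0, noise_sd)
  ct_ref <- reference_ct + stats::rnorm(nrow(grid), 0, noise_sd)
  out <- rbind(
    data.frame(grid, gene = target_gene, ct = ct_target,
               stringsAsFactors = FALSE),
    data.frame(grid, gene = reference_gene, ct = ct_ref,
               stringsAsFactors = FALSE)
  )
  out <- out[order(out$condition, out$replicate, out$hours, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Generate normalized-scale expression with planted pairwise correlation
#'
#' Builds a Gaussian matrix on the normalized-expression scale in which
#' genes `2k-1` and `2k` of the first `n_pairs` pairs load on a shared
#' latent factor with loading `loading` (so their expected Pearson/Spearman
#' correlation is about `loading^2`), followed by `n_null_genes`
#' independent genes. Used to test co-expression statistics against a
#' planted truth and an architecture-free null.
#'
#' @param n_pairs number of correlated gene pairs
#' @param n_cells number of cells
#' @param loading latent-factor loading in `[0, 1)`
#' @param n_null_genes additional independent genes
#' @param seed RNG seed
#' @return matrix (genes x cells) with gene names `p<k>a/p<k>b` for pair
#'   members and `null<j>` for independent genes
#' @export
generate_correlated_expression <- function(n_pairs, n_cells, loading = 0.5,
                                           n_null_genes = 0, seed = 1) {
  if (loading < 0 || loading >= 1) stop("loading must lie in [0, 1)")
  set.seed(seed)
  if (n_pairs > 0) {
    f <- matrix(stats::rnorm(n_pairs * n_cells), n_pairs, n_cells)
    a <- loading * f + sqrt(1 - loading^2) *
      matrix(stats::rnorm(n_pairs * n_cells), n_pairs, n_cells)
    b <- loading * f + sqrt(1 - loading^2) *
      matrix(stats::rnorm(n_pairs * n_cells), n_pairs, n_cells)
    m <- rbind(a, b)
    idx <- as.vector(rbind(seq_len(n_pairs), n_pairs + seq_len(n_pairs)))
    m <- m[idx, , drop = FALSE]
    rownames(m) <- as.vector(rbind(paste0("p", seq_len(n_pairs), "a"),
                                   paste0("p", seq_len(n_pairs), "b")))
  } else {
    m <- matrix(numeric(0), nrow = 0, ncol = n_cells)
  }
  if (n_null_genes > 0) {
    nulls <- matrix(stats::rnorm(n_null_genes * n_cells), n_null_genes,
                    n_cells, dimnames = list(paste0("null", seq_len(n_null_genes)), NULL))
    m <- rbind(m, nulls)
  }
  colnames(m) <- sprintf("cell%05d", seq_len(n_cells))
  m
}

#' Write synthetic inputs to disk in their standard formats
#'
#' Writes the annotation TSV, H3K27ac and ER peak BEDs, loop TSV, signal
#' TSV, ground-truth TSV, and the count matrix as MatrixMarket MTX with
#' features/barcodes TSVs plus a cell-metadata TSV with timepoint labels.
#'
#' @param genes,arch,tc outputs of the generators
#' @param dir output directory (created if missing)
#' @return invisibly, the named vector of file paths written
#' @export
write_synthetic_inputs <- function(genes, arch, tc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(annotation = file.path(dir, "annotation.tsv"),
         h3k27ac = file.path(dir, "h3k27ac.bed"),
         er = file.path(dir, "er_peaks.bed"),
         loops = file.path(dir, "loops.tsv"),
         signal = file.path(dir, "signal.tsv"),
         truth = file.path(dir, "truth.tsv"),
         mtx = file.path(dir, "counts.mtx"),
         features = file.path(dir, "features.tsv"),
         barcodes = file.path(dir, "barcodes.tsv"),
         cells = file.path(dir, "cells.tsv"))
  write_tsv(genes, p["annotation"])
  write_bed(arch$h3k27ac, p["h3k27ac"])
  write_bed(arch$er_peaks, p["er"])
  write_tsv(arch$loops, p["loops"])
  sig <- data.frame(region_id = rownames(arch$signal), arch$signal,
                    check.names = FALSE)
  write_tsv(sig, p["signal"])
  write_tsv(arch$truth, p["truth"])
  Matrix::writeMM(tc$counts, p["mtx"])
  writeLines(rownames(tc$counts), p["features"])
  writeLines(colnames(tc$counts), p["barcodes"])
  write_tsv(tc$cell_meta, p["cells"])
  invisible(p)
}
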