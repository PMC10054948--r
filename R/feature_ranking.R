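#' Shadow-feature (Boruta-style) feature ranking
#'
#' Iteratively compares each real feature against shuffled "shadow" copies:
#' every iteration appends a permuted copy of each remaining feature, fits
#' a seeded random forest (permutation importance via ranger), and scores a
#' "hit" for a real feature whose importance exceeds the maximum shadow
#' importance. After each iteration a two-sided binomial test of the hit
#' count against Binomial(n_iter, 0.5), Bonferroni-corrected over the
#' still-undecided features, promotes features to Confirmed (significantly
#' more hits) or Rejected (significantly fewer); Rejected features and
#' their shadows are removed. Iteration stops at `max_iter` or when no
#' feature is left Tentative.
#'
#' @param feature_table data.frame/matrix of numeric features (no missing
#'   values); non-feature columns `gene_id` and `context` are dropped
#'   automatically
#' @param labels class labels (>= 2 classes, each with >= 10 instances
#'   recommended; < 2 per class is an error)
#' @param max_iter maximum iterations (default 100)
#' @param p_threshold familywise significance level of the binomial tests
#' @param num_trees trees per random forest
#' @param seed RNG seed (drives both shadow shuffles and forests)
#' @param analysis optional tag ("mean", "trajectory", "noise", ...)
#' @return object of class `boruta_result`: `decision` (factor Confirmed/
#'   Tentative/Rejected per feature), `hits`, `n_iter`, `mean_importance`,
#'   `importance_history` (iteration x feature, NA once removed),
#'   `analysis`
#' @export
boruta_rank <- function(feature_table, labels, max_iter = 100,
                        p_threshold = 0.01, num_trees = 100, seed = 1,
                        analysis = NA_character_) {
  x <- as.data.frame(feature_table)
  x <- x[, !(names(x) %in% c("gene_id", "context")), drop = FALSE]
  if (anyNA(x)) stop("feature table contains missing values")
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need >= 2 classes")
  if (any(table(y) < 2)) stop("every class needs >= 2 instances")
  feats <- names(x)
  p <- length(feats)

  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max, max_iter)

  active <- rep(TRUE, p)
  decision <- rep("Tentative", p)
  hits <- integer(p)
  history <- matrix(NA_real_, nrow = 0, ncol = p,
                    dimnames = list(NULL, feats))
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    set.seed(iter_seeds[it])
    act <- which(active)
    # at least 5 shadows, duplicating permuted copies when few features
    # remain, so the max-shadow bar never collapses in the end-game
    src <- act
    while (length(src) < 5) src <- c(src, act)
    shadow <- x[, src, drop = FALSE]
    shadow[] <- lapply(shadow, sample)
    names(shadow) <- paste0("shadow_", seq_along(src))
    dat <- cbind(x[, act, drop = FALSE], shadow, .class = y)
    fit <- ranger::ranger(
      dependent.variable.name = ".class", data = dat,
      num.trees = num_trees, importance = "permutation",
      scale.permutation.importance = TRUE,
      seed = iter_seeds[it], num.threads = 1,
      respect.unordered.factors = "order")
    imp <- fit$variable.importance
    shadow_max <- max(imp[startsWith(names(imp), "shadow_")])
    real_imp <- imp[feats[act]]
    hits[act] <- hits[act] + as.integer(real_imp > shadow_max)
    row <- rep(NA_real_, p); row[act] <- real_imp
    history <- rbind(history, row)

    und <- which(decision == "Tentative")
    p_two <- vapply(und, function(j) {
      min(1, 2 * min(stats::pbinom(hits[j], it, 0.5),
                     stats::pbinom(hits[j] - 1L, it, 0.5,
                                   lower.tail = FALSE)))
    }, numeric(1))
    # Bonferroni over the full starting feature set (as the reference
    # Boruta implementation does); correcting only over the shrinking
    # undecided set lets lone survivors random-walk into false confirms
    p_adj <- pmin(1, p_two * p)
    decision[und[p_adj < p_threshold & hits[und] > it / 2]] <- "Confirmed"
    newly_rej <- und[p_adj < p_threshold & hits[und] < it / 2]
    decision[newly_rej] <- "Rejected"
    active[newly_rej] <- FALSE
    if (!any(decision == "Tentative")) break
  }
  rownames(history) <- NULL
  structure(list(
    decision = stats::setNames(
      factor(decision, levels = c("Confirmed", "Tentative", "Rejected")),
      feats),
    hits = stats::setNames(hits, feats),
    n_iter = n_iter,
    mean_importance = colMeans(history, na.rm = TRUE),
    importance_history = history,
    analysis = analysis
  ), class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(x$decision)
  cat("boruta_result (", if (is.na(x$analysis)) "untagged" else x$analysis,
      "): ", x$n_iter, " iterations; ", tab[["Confirmed"]], " confirmed, ",
      tab[["Tentative"]], " tentative, ", tab[["Rejected"]], " rejected\n",
      sep = "")
  conf <- names(sort(x$mean_importance[x$decision == "Confirmed"],
                     decreasing = TRUE))
  if (length(conf)) cat("  confirmed:", paste(conf, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.boruta_result <- function(object, ...) {
  data.frame(feature = names(object$decision),
             decision = as.character(object$decision),
             mean_importance = as.numeric(object$mean_importance),
             n_hits = as.integer(object$hits),
             n_iter = object$n_iter,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-class mean signal and argmax class per feature
#'
#' Group-by-class means of each feature plus the class with the maximum
#' mean; ties are broken by a fixed class order (the factor level order of
#' `labels`).
#'
#' @param feature_table numeric feature data.frame (gene_id/context columns
#'   dropped)
#' @param labels class labels, one per row
#' @return list(means = feature x class matrix, argmax = named character)
#' @export
group_signal_summary <- function(feature_table, labels) {
  x <- as.data.frame(feature_table)
  x <- x[, !(names(x) %in% c("gene_id", "context")), drop = FALSE]
  y <- as.factor(labels)
  m <- t(vapply(x, function(col) tapply(col, y, mean),
                numeric(nlevels(y))))
  colnames(m) <- levels(y)
  argmax <- colnames(m)[apply(m, 1, which.max)]  # which.max: first = class order
  list(means = m, argmax = stats::setNames(argmax, rownames(m)))
}

#' Fit an illustrative decision tree
#'
#' CART (Gini impurity) via rpart with minimum leaf size `min_leaf` and
#' complexity parameter `complexity`; the printed report is truncated to
#' `max_depth_report` levels. Data that admit no split under these
#' constraints give a single-leaf tree.
#'
#' @param feature_table numeric feature data.frame
#' @param labels class labels
#' @param min_leaf minimum observations in any leaf (rpart minbucket)
#' @param complexity rpart complexity parameter cp
#' @param max_depth_report depth shown in the report
#' @return list(tree = rpart object, report = character lines, n_leaves)
#' @export
fit_tree <- function(feature_table, labels, min_leaf = 50,
                     complexity = 0.007, max_depth_report = 4) {
  x <- as.data.frame(feature_table)
  x <- x[, !(names(x) %in% c("gene_id", "context")), drop = FALSE]
  # min_leaf > n/2 admits no split and yields a single-leaf tree
  dat <- cbind(x, .class = factor(labels))
  fit <- rpart::rpart(.class ~ ., data = dat, method = "class",
                      control = rpart::rpart.control(
                        minbucket = min_leaf, cp = complexity,
                        xval = 0))
  depth <- floor(log2(as.numeric(rownames(fit$frame))))
  show <- fit
  if (any(depth >= max_depth_report) && nrow(fit$frame) > 1) {
    keep_internal <- as.numeric(rownames(fit$frame))[
      depth == max_depth_report - 1 & fit$frame$var != "<leaf>"]
    if (length(keep_internal)) {
      show <- rpart::snip.rpart(fit, toss = keep_internal)
    }
  }
  list(tree = fit,
       report = utils::capture.output(print(show)),
       n_leaves = sum(fit$frame$var == "<leaf>"))
}

#' Compare importance profiles across analyses
#'
#' Pearson correlations between the mean-importance vectors of several
#' ranking runs over their shared features, plus a PCA of the
#' feature x analysis importance matrix.
#'
#' @param results list of `boruta_result` objects (named, ideally)
#' @return list(correlations, scores = feature PCA coordinates,
#'   explained_variance, features)
#' @export
compare_profiles <- function(results) {
  if (length(results) < 2) stop("need >= 2 importance results")
  feat_sets <- lapply(results, function(r) names(r$mean_importance))
  shared <- Reduce(intersect, feat_sets)
  if (length(shared) < 2) stop("results share fewer than 2 features")
  m <- vapply(results, function(r) r$mean_importance[shared],
              numeric(length(shared)))
  rownames(m) <- shared
  if (is.null(colnames(m))) {
    colnames(m) <- paste0("analysis", seq_along(results))
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(correlations = stats::cor(m),
       scores = pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE],
       explained_variance = ev[seq_len(min(2, length(ev)))],
       features = shared)
}
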