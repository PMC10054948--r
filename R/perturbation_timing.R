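#' Relative expression by the delta-delta-Ct method
#'
#' For each (condition, replicate, timepoint): `dCt = Ct_target - Ct_ref`,
#' `ddCt = dCt - dCt0` where `dCt0` is the mean delta-Ct of the control
#' condition at 0 h, and fold change = `2^-ddCt`. Expression is therefore
#' relative to the control condition's 0-hour level.
#'
#' @param ct_table data.frame (condition, replicate, hours, gene, ct)
#' @param target_gene gene whose expression is quantified
#' @param reference_gene housekeeping reference (e.g. "CTCF")
#' @param control_condition condition anchoring the 0-h baseline
#' @return data.frame (condition, replicate, hours, rel_expr)
#' @export
relative_expression <- function(ct_table, target_gene,
                                reference_gene = "CTCF",
                                control_condition = "control") {
  tgt <- ct_table[ct_table$gene == target_gene, ]
  ref <- ct_table[ct_table$gene == reference_gene, ]
  if (nrow(tgt) == 0) stop("no rows for target gene ", target_gene)
  key <- function(d) paste(d$condition, d$replicate, d$hours)
  ref_ct <- stats::setNames(ref$ct, key(ref))
  miss <- !(key(tgt) %in% names(ref_ct))
  if (any(miss)) {
    stop("missing reference Ct for ", key(tgt)[which(miss)[1]])
  }
  dct <- tgt$ct - as.numeric(ref_ct[key(tgt)])
  base_idx <- tgt$condition == control_condition & tgt$hours == 0
  if (!any(base_idx)) {
    stop("control condition '", control_condition, "' has no 0-h rows")
  }
  ddct <- dct - mean(dct[base_idx])
  data.frame(condition = tgt$condition, replicate = tgt$replicate,
             hours = tgt$hours, rel_expr = 2^(-ddct),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Loess fit of a relative-expression time course
#'
#' Local quadratic regression (tricube weights, `y ~ x`) through all
#' replicate points, evaluated on a 0.1-h grid over the observed time
#' range. A singular fit is retried once with span 1 before failing.
#'
#' @param hours observation times (>= 4 distinct values)
#' @param values relative expression at those times (replicates as
#'   separate points)
#' @param span loess span (default 0.75)
#' @param grid_step evaluation grid step in hours
#' @return object of class `trajectory_fit`: grid, fitted, points, span
#' @export
fit_trajectory <- function(hours, values, span = 0.75, grid_step = 0.1) {
  if (length(unique(hours)) < 4) stop("need >= 4 distinct timepoints")
  dat <- data.frame(x = hours, y = values)
  fit <- tryCatch(
    stats::loess(y ~ x, data = dat, span = span, degree = 2,
                 family = "gaussian"),
    error = function(e) NULL, warning = function(w) NULL)
  used_span <- span
  if (is.null(fit)) {
    used_span <- 1
    fit <- stats::loess(y ~ x, data = dat, span = 1, degree = 2)
  }
  grid <- seq(min(hours), max(hours), by = grid_step)
  fitted <- as.numeric(stats::predict(fit, newdata = data.frame(x = grid)))
  if (anyNA(fitted)) stop("loess prediction failed on the time grid")
  structure(list(grid = grid, fitted = fitted, points = dat,
                 span = used_span, grid_step = grid_step),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("trajectory_fit: ", nrow(x$points), " points over [",
      min(x$grid), ", ", max(x$grid), "] h (span ", x$span,
      "); half-max at ", half_max_time(x), " h\n", sep = "")
  invisible(x)
}

#' Time to half-maximal response
#'
#' The first grid time at which the fitted curve reaches half of its
#' maximum fitted value (maximum over the whole grid, no baseline
#' subtraction; set `subtract_baseline = TRUE` to measure half-rise above
#' the fitted 0-h level instead).
#'
#' @param fit a `trajectory_fit`
#' @param subtract_baseline measure relative to the fitted value at the
#'   first grid point
#' @return hours (scalar)
#' @export
half_max_time <- function(fit, subtract_baseline = FALSE) {
  f <- fit$fitted
  if (subtract_baseline) f <- f - f[1]
  m <- max(f)
  fit$grid[which(f >= m / 2)[1]]
}

#' Slope of the fitted trajectory
#'
#' Central differences of the fitted curve on the grid (one-sided at the
#' ends), in expression units per hour.
#'
#' @param fit a `trajectory_fit`
#' @return numeric vector, one slope per grid time
#' @export
slope_series <- function(fit) {
  f <- fit$fitted; h <- fit$grid_step; n <- length(f)
  if (n < 2) stop("grid too short for slopes")
  s <- numeric(n)
  s[1] <- (f[2] - f[1]) / h
  s[n] <- (f[n] - f[n - 1]) / h
  if (n > 2) s[2:(n - 1)] <- (f[3:n] - f[1:(n - 2)]) / (2 * h)
  s
}

#' Aggregate slope trajectories for targeted vs control conditions
#'
#' Mean slope per grid time within each group with a 95%
#' normal-approximation confidence interval; single-fit groups get a
#' zero-width CI flagged by `df = 0`.
#'
#' @param fits named list of `trajectory_fit` objects on identical grids
#' @param group_labels "targeted"/"control" (or any two labels), one per
#'   fit
#' @return data.frame (group, hours, mean_slope, ci_lo, ci_hi, n)
#' @export
aggregate_slopes <- function(fits, group_labels) {
  if (length(fits) != length(group_labels)) {
    stop("one group label per fit required")
  }
  grids <- lapply(fits, function(f) f$grid)
  if (!all(vapply(grids, identical, TRUE, grids[[1]]))) {
    stop("fits must share a common time grid")
  }
  slopes <- vapply(fits, slope_series, numeric(length(grids[[1]])))
  out <- list()
  for (g in unique(group_labels)) {
    cols <- which(group_labels == g)
    if (!length(cols)) stop("empty group ", g)
    s <- slopes[, cols, drop = FALSE]
    mu <- rowMeans(s)
    se <- if (ncol(s) > 1) apply(s, 1, stats::sd) / sqrt(ncol(s)) else 0
    out[[g]] <- data.frame(group = g, hours = grids[[1]], mean_slope = mu,
                           ci_lo = mu - 1.96 * se, ci_hi = mu + 1.96 * se,
                           n = ncol(s), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
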