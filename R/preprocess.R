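#' Aggregate probe-level rows to gene level
#'
#' A gene measured by several probes (alternative transcripts or promoters)
#' receives, in every sample, the arithmetic mean of its probes' values.
#' Probes without a mapping are dropped (the count is reported).
#'
#' @param probe_matrix An [ExpressionMatrix] with probe-level rows.
#' @param map Data frame with columns `probe_id`, `gene_id`
#'   (see [read_probe_map()]).
#' @return An [ExpressionMatrix] with one row per mapped gene, rows ordered by
#'   gene identifier.
#' @export
aggregate_probes <- function(probe_matrix, map) {
  stopifnot(inherits(probe_matrix, "ExpressionMatrix"))
  idx <- match(feature_ids(probe_matrix), map$probe_id)
  unmapped <- is.na(idx)
  if (any(unmapped))
    message(sum(unmapped), " unmapped probes dropped")
  if (all(unmapped))
    stop("no probe in the matrix has a gene mapping")
  values <- probe_matrix$values[!unmapped, , drop = FALSE]
  genes <- map$gene_id[idx[!unmapped]]
  sums <- rowsum(values, genes)
  counts <- as.vector(table(genes)[rownames(sums)])
  ExpressionMatrix(sums / counts, probe_matrix$feature_kind,
                   condition = probe_matrix$condition,
                   group = probe_matrix$group)
}

#' Restrict several matrices to their common feature set
#'
#' Used to harmonize datasets from different platforms once identifiers have
#' been mapped to a shared namespace: every returned matrix contains exactly
#' the features present in all inputs, in the same sorted order.
#'
#' @param matrices List of at least two [ExpressionMatrix] objects of the same
#'   feature kind.
#' @return List of [ExpressionMatrix] objects restricted to the sorted common
#'   features.
#' @export
intersect_features <- function(matrices) {
  if (length(matrices) < 2)
    stop("need at least two matrices")
  kinds <- vapply(matrices, function(m) m$feature_kind, character(1))
  if (length(unique(kinds)) != 1)
    stop("matrices must share the same feature kind")
  common <- Reduce(intersect, lapply(matrices, feature_ids))
  if (length(common) == 0)
    stop("feature intersection is empty")
  common <- sort(common)
  lapply(matrices, subset_features, ids = common)
}

#' Median normalization
#'
#' Shifts each sample (column) additively so that all column medians equal
#' the median of the original column medians. Additive shifts on the log
#' scale correspond to multiplicative scaling of raw intensities.
#'
#' @param m An [ExpressionMatrix].
#' @return The normalized [ExpressionMatrix]; shape and feature order are
#'   preserved and all column medians are equal afterwards.
#' @export
median_normalize <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (nrow(m$values) < 1) stop("matrix has no features")
  med <- apply(m$values, 2, stats::median)
  target <- stats::median(med)
  values <- sweep(m$values, 2, med - target, "-")
  ExpressionMatrix(values, m$feature_kind,
                   condition = m$condition, group = m$group)
}

#' Lowess (intensity-dependent) normalization
#'
#' Single-channel lowess normalization against a pseudo-array reference:
#' the reference is the row-wise median across samples, and for each sample
#' the difference to the reference is regressed on the mean intensity
#' `(sample + reference) / 2` with [stats::lowess()]; the fitted
#' intensity-dependent bias is subtracted. With fewer than 10 features the
#' smoother has no support and the function falls back to
#' [median_normalize()] with a warning.
#'
#' @param m An [ExpressionMatrix] (typically the miRNA matrix).
#' @param span Lowess smoother span (default 2/3).
#' @param iterations Robustness iterations for the smoother (default 3).
#' @return The normalized [ExpressionMatrix], same shape and feature order.
#' @export
lowess_normalize <- function(m, span = 2 / 3, iterations = 3) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (nrow(m$values) < 10) {
    warning("fewer than 10 features; falling back to median normalization")
    return(median_normalize(m))
  }
  reference <- apply(m$values, 1, stats::median)
  values <- m$values
  for (s in seq_len(ncol(values))) {
    a <- (values[, s] + reference) / 2
    d <- values[, s] - reference
    fit <- stats::lowess(a, d, f = span, iter = iterations)
    bias <- stats::approx(fit$x, fit$y, xout = a, rule = 2, ties = mean)$y
    values[, s] <- values[, s] - bias
  }
  ExpressionMatrix(values, m$feature_kind,
                   condition = m$condition, group = m$group)
}

# Row-wise one-way fixed-effects ANOVA. Returns per-row F p-values; rows whose
# within-group variance is (numerically) zero in every group get the
# degenerate rule p = 0 if group means differ, p = 1 otherwise.
row_anova_p <- function(values, condition) {
  condition <- droplevels(factor(condition))
  k <- nlevels(condition)
  n <- ncol(values)
  counts <- as.vector(table(condition))
  grand <- rowMeans(values)
  group_means <- vapply(levels(condition), function(g) {
    rowMeans(values[, condition == g, drop = FALSE])
  }, numeric(nrow(values)))
  ss_between <- as.vector((group_means - grand)^2 %*% counts)
  ss_total <- rowSums((values - grand)^2)
  ss_within <- pmax(ss_total - ss_between, 0)
  p <- stats::pf((ss_between / (k - 1)) / (ss_within / (n - k)),
                 k - 1, n - k, lower.tail = FALSE)
  scale_ <- pmax(ss_total, 1)
  degenerate <- ss_within < 1e-12 * scale_
  if (any(degenerate)) {
    message(sum(degenerate), " features with zero within-group variance; ",
            "degenerate p rule applied")
    p[degenerate] <- ifelse(ss_between[degenerate] > 1e-12 * scale_[degenerate],
                            0, 1)
  }
  names(p) <- rownames(values)
  p
}

#' Select differentially expressed features by one-way ANOVA
#'
#' Performs, for every feature, a one-way fixed-effects ANOVA F-test of equal
#' means across the experimental conditions (the multi-condition design is
#' treated as unordered groups) and selects features with `p <= alpha`.
#' The threshold is inclusive.
#'
#' @param m An [ExpressionMatrix] with a `condition` annotation defining at
#'   least two groups with at least two samples each.
#' @param alpha Significance level (default 0.05).
#' @return A list with `selected` (feature ids with `p <= alpha`, in input
#'   row order) and `p_values` (named vector over all features).
#' @export
anova_filter <- function(m, alpha = 0.05) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.null(m$condition))
    stop("matrix has no condition annotation")
  condition <- droplevels(m$condition)
  if (nlevels(condition) < 2)
    stop("need at least two condition groups")
  if (any(table(condition) < 2))
    stop("every condition group needs at least two samples")
  p <- row_anova_p(m$values, condition)
  list(selected = feature_ids(m)[p <= alpha], p_values = p)
}
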