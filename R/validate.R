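#' Two-cluster evaluation of a biomarker panel on a cohort
#'
#' Median-normalizes the cohort, restricts it to the panel genes (absent
#' genes are dropped with a warning), z-scores each gene across samples,
#' computes sample-sample distances and applies average-linkage agglomerative
#' clustering, cutting the dendrogram at the last merge into exactly two
#' clusters. Accuracy is the best of the two possible cluster-to-group
#' assignments, so it is at least 0.5 and invariant to cluster relabelling.
#'
#' @param cohort [ExpressionMatrix] with a two-level `group` annotation
#'   (case/control) and at least 4 samples.
#' @param panel Character vector of candidate biomarker gene ids; at least
#'   two must be present in the cohort.
#' @param distance `"euclidean"` (default) on z-scored genes, or
#'   `"correlation"` (one minus Pearson correlation between samples).
#' @return A `ClusterResult`: list with `sample_ids`, `predicted_cluster`
#'   (1/2 per sample), `true_group`, `accuracy`, `misclassified` (sample ids
#'   under the best assignment) and `panel_used`.
#' @export
cluster_samples <- function(cohort, panel,
                            distance = c("euclidean", "correlation")) {
  stopifnot(inherits(cohort, "ExpressionMatrix"))
  distance <- match.arg(distance)
  if (is.null(cohort$group) || nlevels(droplevels(cohort$group)) != 2)
    stop("cohort must have a two-level group annotation")
  if (ncol(cohort$values) < 4) stop("need at least 4 samples")
  present <- intersect(panel, feature_ids(cohort))
  if (length(present) == 0)
    stop("no panel gene is present in the cohort")
  if (length(present) < length(panel))
    warning(length(panel) - length(present),
            " panel genes absent from the cohort; dropped")
  if (length(present) < 2)
    stop("fewer than 2 panel genes present in the cohort")
  norm <- median_normalize(cohort)
  v <- norm$values[present, , drop = FALSE]
  z <- (v - rowMeans(v)) / apply(v, 1, stats::sd)
  z[!is.finite(z)] <- 0  # constant genes carry no information
  d <- if (distance == "euclidean") stats::dist(t(z))
       else stats::as.dist(1 - stats::cor(z))
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = 2)
  truth <- droplevels(cohort$group)
  acc1 <- mean((cl == 1) == (truth == levels(truth)[1]))
  flip <- acc1 < 1 - acc1
  accuracy <- max(acc1, 1 - acc1)
  assigned <- if (flip) levels(truth)[c(2, 1)][cl] else levels(truth)[cl]
  mis <- sample_ids(cohort)[assigned != as.character(truth)]
  structure(list(sample_ids = sample_ids(cohort),
                 predicted_cluster = unname(cl),
                 true_group = truth,
                 accuracy = accuracy,
                 misclassified = mis,
                 panel_used = present),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf(
    "ClusterResult: %d samples, accuracy %.3f (%d misclassified)\n",
    length(x$sample_ids), x$accuracy, length(x$misclassified)))
  invisible(x)
}

# Row-wise two-sided equal-variance two-sample t-test p-values.
row_ttest_p <- function(values, group) {
  group <- droplevels(factor(group))
  stopifnot(nlevels(group) == 2)
  i1 <- group == levels(group)[1]
  i2 <- !i1
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop("both groups need at least two samples")
  m1 <- rowMeans(values[, i1, drop = FALSE])
  m2 <- rowMeans(values[, i2, drop = FALSE])
  ss1 <- rowSums((values[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((values[, i2, drop = FALSE] - m2)^2)
  pooled <- (ss1 + ss2) / (n1 + n2 - 2)
  se <- sqrt(pooled * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
  scale_ <- pmax(rowSums((values - rowMeans(values))^2), 1)
  degenerate <- pooled < 1e-12 * scale_ / ncol(values)
  if (any(degenerate)) {
    message(sum(degenerate), " features with zero pooled variance; ",
            "degenerate p rule applied")
    p[degenerate] <- ifelse(abs(m1 - m2)[degenerate] > 1e-12, 0, 1)
  }
  names(p) <- rownames(values)
  p
}

#' Differential-expression baseline ranking
#'
#' The traditional alternative to network ranking: features are ordered by
#' ascending p-value of a per-feature group-difference test. For the
#' multi-condition training design (`contrast = "condition"`) this is the
#' one-way ANOVA F-test across conditions; for a two-group cohort
#' (`contrast = "group"`) a two-sided equal-variance t-test. Ties are broken
#' by feature id.
#'
#' @param m [ExpressionMatrix] with the relevant annotation.
#' @param contrast `"condition"` (default) or `"group"`.
#' @return Data frame `node_id`, `p_value`, `rank`, ordered by rank, usable
#'   with [select_top()].
#' @export
de_rank <- function(m, contrast = c("condition", "group")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  contrast <- match.arg(contrast)
  p <- if (contrast == "condition") {
    if (is.null(m$condition)) stop("matrix has no condition annotation")
    row_anova_p(m$values, m$condition)
  } else {
    if (is.null(m$group)) stop("matrix has no group annotation")
    row_ttest_p(m$values, m$group)
  }
  ord <- order(p, names(p))
  data.frame(node_id = names(p)[ord], p_value = unname(p)[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Per-gene two-group t-tests for a biomarker panel
#'
#' Two-sided equal-variance Student t-test of case versus control for every
#' panel gene, with the direction of dysregulation (sign of case mean minus
#' control mean).
#'
#' @param m [ExpressionMatrix] with a two-level `group` annotation.
#' @param panel Gene ids to test (must be present in the matrix).
#' @param case_level Which group level is the case group; defaults to the
#'   second factor level.
#' @return Data frame `node_id`, `p_value`, `direction` (`"Up-regulated"` if
#'   the case mean exceeds the control mean, else `"Down-regulated"`).
#' @export
two_group_ttest <- function(m, panel, case_level = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.null(m$group) || nlevels(droplevels(m$group)) != 2)
    stop("matrix must have a two-level group annotation")
  sub <- subset_features(m, panel)
  group <- droplevels(m$group)
  if (is.null(case_level)) case_level <- levels(group)[2]
  if (!case_level %in% levels(group)) stop("unknown case level")
  p <- row_ttest_p(sub$values, group)
  case_mean <- rowMeans(sub$values[, group == case_level, drop = FALSE])
  ctrl_mean <- rowMeans(sub$values[, group != case_level, drop = FALSE])
  data.frame(node_id = panel, p_value = unname(p[panel]),
             direction = ifelse(case_mean[panel] > ctrl_mean[panel],
                                "Up-regulated", "Down-regulated"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Clustering accuracy as a function of panel size for both rankings
#'
#' For each method (PageRank network ranking and the DE baseline), each panel
#' size `k` in `k_grid` and each cohort, runs [cluster_samples()] with the
#' method's top-`k` genes and records the accuracy.
#'
#' @param pagerank_ranking mRNA ranking data frame (from
#'   [rank_by_type()]`$mrna`).
#' @param de_ranking DE ranking data frame (from [de_rank()]).
#' @param cohorts Named list of cohort [ExpressionMatrix] objects.
#' @param k_grid Integer panel sizes, strictly increasing; default `2:100`.
#' @return Data frame `method` (`"pagerank"`/`"de"`), `k`, `cohort`,
#'   `accuracy`.
#' @export
accuracy_curve <- function(pagerank_ranking, de_ranking, cohorts,
                           k_grid = 2:100) {
  if (is.unsorted(k_grid, strictly = TRUE))
    stop("'k_grid' must be strictly increasing")
  rankings <- list(pagerank = pagerank_ranking, de = de_ranking)
  for (nm in names(rankings))
    if (max(k_grid) > nrow(rankings[[nm]]))
      stop("'k_grid' exceeds the ", nm, " ranking length")
  if (is.null(names(cohorts)))
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  out <- expand.grid(method = names(rankings), k = k_grid,
                     cohort = names(cohorts), stringsAsFactors = FALSE)
  out$accuracy <- mapply(function(method, k, cohort) {
    panel <- select_top(rankings[[method]], k)
    suppressWarnings(cluster_samples(cohorts[[cohort]], panel)$accuracy)
  }, out$method, out$k, out$cohort)
  out[order(out$method, out$cohort, out$k), , drop = FALSE]
}
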