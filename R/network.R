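#' Pearson correlation coefficient
#'
#' Covariance of the two vectors divided by the product of their standard
#' deviations. Returns `NA` (with a warning) when either vector has zero
#' variance; callers scanning many pairs skip and count such pairs.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return Correlation in `[-1, 1]`, or `NA` for a degenerate pair.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  xc <- x - mean(x)
  yc <- y - mean(y)
  ssx <- sum(xc^2)
  ssy <- sum(yc^2)
  if (ssx == 0 || ssy == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  r <- sum(xc * yc) / sqrt(ssx * ssy)
  min(1, max(-1, r))
}

#' Two-sided p-value for a Pearson correlation
#'
#' Transforms `r` to `t = r * sqrt(n - 2) / sqrt(1 - r^2)` and refers it to a
#' Student t distribution on `n - 2` degrees of freedom (the product-moment
#' correlation test). `|r| = 1` gives `p = 0` as the limit case.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @param n Number of paired observations (`n >= 3`).
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @export
correlation_pvalue <- function(r, n) {
  if (n < 3) stop("need at least 3 observations")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must not exceed 1")
  # keep r as the first pmin/pmax argument so matrix dims survive
  r <- pmin(pmax(r, -1), 1)
  ifelse(abs(r) >= 1, 0,
         2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2))
}

# Row-standardize a matrix so that tcrossprod / (n - 1) gives correlations.
# Rows with zero variance come back as NA rows.
.row_standardize <- function(v) {
  ctr <- v - rowMeans(v)
  sds <- sqrt(rowSums(ctr^2) / (ncol(v) - 1))
  out <- ctr / sds
  out[sds == 0, ] <- NA_real_
  list(z = out, zero_var = sds == 0)
}

#' Build the weighted miRNA-mRNA bipartite network
#'
#' Exhaustively tests every (miRNA, mRNA) pair by Pearson correlation across
#' the shared samples and retains pairs that are both significant
#' (`p <= alpha`, inclusive) and negatively correlated (`r < 0`). Each
#' retained edge is weighted by `|r|`. The mRNA matrix is normally restricted
#' to ANOVA-selected features beforehand; all available miRNAs participate.
#' Pairs in which either feature has zero variance are skipped and counted.
#'
#' @param mirna [ExpressionMatrix] of miRNAs.
#' @param mrna [ExpressionMatrix] of mRNAs; must have identical samples in
#'   identical order.
#' @param alpha Edge significance level (default 0.05, inclusive).
#' @return A `BipartiteNetwork`: list with `edges` (data frame `mirna_id`,
#'   `mrna_id`, `r`, `p`, `weight`) and `nodes` (data frame `id`, `type` for
#'   every node incident to at least one edge).
#' @export
build_network <- function(mirna, mrna, alpha = 0.05) {
  stopifnot(inherits(mirna, "ExpressionMatrix"),
            inherits(mrna, "ExpressionMatrix"))
  if (!identical(sample_ids(mirna), sample_ids(mrna)))
    stop("matrices must share identical sample ids in identical order")
  n <- ncol(mirna$values)
  if (n < 3) stop("need at least 3 shared samples")
  zm <- .row_standardize(mirna$values)
  zg <- .row_standardize(mrna$values)
  n_skipped <- sum(zm$zero_var) * nrow(mrna$values) +
    sum(!zm$zero_var) * sum(zg$zero_var)
  if (n_skipped > 0)
    message(n_skipped, " zero-variance pairs skipped")
  r_mat <- tcrossprod(zm$z, zg$z) / (n - 1)
  r_mat[] <- pmin(1, pmax(-1, r_mat))
  p_mat <- correlation_pvalue(r_mat, n)
  keep <- which(!is.na(r_mat) & r_mat < 0 & p_mat <= alpha, arr.ind = TRUE)
  if (nrow(keep) == 0)
    stop(sprintf(
      "no edge passed the thresholds (min p = %.3g, max |r| = %.3g)",
      min(p_mat, na.rm = TRUE), max(abs(r_mat), na.rm = TRUE)))
  edges <- data.frame(
    mirna_id = feature_ids(mirna)[keep[, 1]],
    mrna_id = feature_ids(mrna)[keep[, 2]],
    r = r_mat[keep],
    p = p_mat[keep],
    stringsAsFactors = FALSE)
  edges$weight <- abs(edges$r)
  edges <- edges[order(edges$mirna_id, edges$mrna_id), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- rbind(
    data.frame(id = sort(unique(edges$mirna_id)), type = "miRNA",
               stringsAsFactors = FALSE),
    data.frame(id = sort(unique(edges$mrna_id)), type = "mRNA",
               stringsAsFactors = FALSE))
  structure(list(edges = edges, nodes = nodes), class = "BipartiteNetwork")
}

#' @export
print.BipartiteNetwork <- function(x, ...) {
  cat(sprintf("BipartiteNetwork: %d edges, %d miRNAs, %d mRNAs\n",
              nrow(x$edges), sum(x$nodes$type == "miRNA"),
              sum(x$nodes$type == "mRNA")))
  invisible(x)
}

#' Write a network edge list as tab-delimited text
#'
#' Columns `mirna_id`, `mrna_id`, `r`, `p`, `weight`; loadable by standard
#' graph tooling.
#'
#' @param net A `BipartiteNetwork`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_edges <- function(net, file) {
  utils::write.table(net$edges, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a network edge list written by [write_edges()]
#'
#' @param file Path to the edge list.
#' @return A `BipartiteNetwork`.
#' @export
read_edges <- function(file) {
  edges <- utils::read.delim(file, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  required <- c("mirna_id", "mrna_id", "r", "p", "weight")
  if (!all(required %in% names(edges)))
    stop("edge list must contain columns: ", paste(required, collapse = ", "))
  nodes <- rbind(
    data.frame(id = sort(unique(edges$mirna_id)), type = "miRNA",
               stringsAsFactors = FALSE),
    data.frame(id = sort(unique(edges$mrna_id)), type = "mRNA",
               stringsAsFactors = FALSE))
  structure(list(edges = edges[required], nodes = nodes),
            class = "BipartiteNetwork")
}
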