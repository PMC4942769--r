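#' Weighted PageRank scores by power iteration
#'
#' Scores node importance on the (undirected) weighted bipartite network.
#' Every edge conducts score in both directions; the probability of stepping
#' from node `u` to neighbour `v` is `weight(u, v)` divided by the total
#' weight incident to `u` (the node strength). Starting from the uniform
#' vector, the iteration
#' \deqn{s \leftarrow (1 - d)/N + d \, P^{\top} s}
#' is repeated until the L1 change falls below `tol` or `max_iter` is
#' reached. Because every node in the network has at least one edge, there
#' are no dangling nodes and the scores sum to one after every iteration.
#'
#' @param net A `BipartiteNetwork` from [build_network()].
#' @param damping Damping factor `d` in (0, 1); default 0.85, the canonical
#'   value of the algorithm.
#' @param tol L1 convergence threshold (default 1e-10).
#' @param max_iter Iteration cap (default 1000); if reached, the current
#'   vector is returned with a warning and attribute `converged = FALSE`.
#' @return Named numeric vector of scores over all network nodes (miRNAs and
#'   mRNAs), summing to 1, with attributes `converged` and `iterations`.
#' @export
pagerank_scores <- function(net, damping = 0.85, tol = 1e-10,
                            max_iter = 1000) {
  stopifnot(inherits(net, "BipartiteNetwork"))
  if (damping <= 0 || damping >= 1)
    stop("'damping' must lie strictly between 0 and 1")
  if (nrow(net$edges) == 0) stop("network has no edges")
  ids <- net$nodes$id
  n <- length(ids)
  from <- c(match(net$edges$mirna_id, ids), match(net$edges$mrna_id, ids))
  to <- c(match(net$edges$mrna_id, ids), match(net$edges$mirna_id, ids))
  w <- rep(net$edges$weight, 2)
  strength <- as.vector(rowsum(w, from, reorder = TRUE))
  # transition matrix: column u holds w(u, v) / strength(u)
  trans <- Matrix::sparseMatrix(i = to, j = from, x = w / strength[from],
                                dims = c(n, n))
  s <- rep(1 / n, n)
  teleport <- (1 - damping) / n
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    s_new <- teleport + damping * as.vector(trans %*% s)
    if (sum(abs(s_new - s)) < tol) {
      s <- s_new
      converged <- TRUE
      break
    }
    s <- s_new
  }
  if (!converged)
    warning("power iteration did not converge within ", max_iter,
            " iterations")
  names(s) <- ids
  attr(s, "converged") <- converged
  attr(s, "iterations") <- iter
  s
}

#' Rank miRNAs and mRNAs separately by PageRank score
#'
#' Within each node type, nodes are ordered by descending score; exact ties
#' are broken by lexicographic node id so rankings are deterministic.
#'
#' @param scores Named score vector from [pagerank_scores()]; must cover all
#'   network nodes.
#' @param net The `BipartiteNetwork` the scores were computed on.
#' @return A list with data frames `mrna` and `mirna`, each with columns
#'   `node_id`, `node_type`, `score`, `rank`.
#' @export
rank_by_type <- function(scores, net) {
  stopifnot(inherits(net, "BipartiteNetwork"))
  if (!all(net$nodes$id %in% names(scores)))
    stop("scores do not cover all network nodes")
  rank_one <- function(type) {
    ids <- net$nodes$id[net$nodes$type == type]
    sc <- unname(scores[ids])
    ord <- order(-sc, ids)
    data.frame(node_id = ids[ord], node_type = type, score = sc[ord],
               rank = seq_along(ord), stringsAsFactors = FALSE)
  }
  list(mrna = rank_one("mRNA"), mirna = rank_one("miRNA"))
}

#' Select the top-ranked features of a ranking
#'
#' @param ranking One ranking data frame from [rank_by_type()] (or any data
#'   frame with `node_id` in rank order).
#' @param k Number of features, `1 <= k <= nrow(ranking)`.
#' @return Character vector of the first `k` node ids in rank order.
#' @export
select_top <- function(ranking, k) {
  if (k < 1 || k > nrow(ranking))
    stop("'k' must lie between 1 and the ranking length")
  ranking$node_id[seq_len(k)]
}

#' Write a ranking table as tab-delimited text
#'
#' @param ranking List from [rank_by_type()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_ranking <- function(ranking, file) {
  utils::write.table(rbind(ranking$mrna, ranking$mirna), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Run the full training pipeline
#'
#' Convenience wrapper chaining the training-side steps: ANOVA selection of
#' differentially expressed mRNAs, negative-correlation network construction
#' against all miRNAs, PageRank scoring, and per-type ranking.
#'
#' @param mirna [ExpressionMatrix] of miRNAs (normalized).
#' @param mrna [ExpressionMatrix] of mRNAs (normalized), with a `condition`
#'   annotation.
#' @param alpha Significance level for both the ANOVA filter and the edge
#'   test (default 0.05).
#' @param damping PageRank damping factor (default 0.85).
#' @return A list with `anova` (from [anova_filter()]), `network`, `scores`
#'   and `ranking` (from [rank_by_type()]).
#' @export
run_training_pipeline <- function(mirna, mrna, alpha = 0.05, damping = 0.85) {
  sel <- anova_filter(mrna, alpha = alpha)
  if (length(sel$selected) == 0)
    stop("ANOVA filter selected no mRNA features")
  net <- build_network(mirna, subset_features(mrna, sel$selected),
                       alpha = alpha)
  scores <- pagerank_scores(net, damping = damping)
  list(anova = sel, network = net, scores = scores,
       ranking = rank_by_type(scores, net))
}
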