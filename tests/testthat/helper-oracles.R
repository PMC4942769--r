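# Independent oracles used to verify the package's statistics: explicit
# formula recomputation and numeric quadrature of the reference densities.

oracle_pearson <- function(x, y) {
  n <- length(x)
  cov_xy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sd_x <- sqrt(sum((x - mean(x))^2) / (n - 1))
  sd_y <- sqrt(sum((y - mean(y))^2) / (n - 1))
  cov_xy / (sd_x * sd_y)
}

# two-sided correlation p by quadrature of the t density
oracle_cor_pvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tval <- abs(r) * sqrt((n - 2) / (1 - r^2))
  2 * stats::integrate(function(x) stats::dt(x, df = n - 2),
                       lower = tval, upper = Inf,
                       rel.tol = 1e-13, abs.tol = 1e-15)$value
}

# one-way ANOVA p by brute-force sum-of-squares decomposition plus
# quadrature of the F density
oracle_anova_pvalue <- function(y, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(y)
  ss_between <- 0
  ss_within <- 0
  for (g in levels(groups)) {
    yg <- y[groups == g]
    ss_between <- ss_between + length(yg) * (mean(yg) - mean(y))^2
    ss_within <- ss_within + sum((yg - mean(yg))^2)
  }
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  stats::integrate(function(x) stats::df(x, df1 = k - 1, df2 = n - k),
                   lower = f, upper = Inf,
                   rel.tol = 1e-13, abs.tol = 1e-15)$value
}

# stationary PageRank by dense linear solve: (I - d T) s = (1 - d)/N
oracle_pagerank_dense <- function(net, damping = 0.85) {
  ids <- net$nodes$id
  n <- length(ids)
  w_mat <- matrix(0, n, n, dimnames = list(ids, ids))
  for (e in seq_len(nrow(net$edges))) {
    i <- net$edges$mirna_id[e]
    j <- net$edges$mrna_id[e]
    w_mat[i, j] <- w_mat[i, j] + net$edges$weight[e]
    w_mat[j, i] <- w_mat[j, i] + net$edges$weight[e]
  }
  strength <- colSums(w_mat)
  trans <- sweep(w_mat, 2, strength, "/")  # column u -> neighbours
  s <- solve(diag(n) - damping * trans, rep((1 - damping) / n, n))
  names(s) <- ids
  s
}
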