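# Programmatic fixtures shared across test files.

make_em <- function(values, kind = "mRNA", condition = NULL, group = NULL,
                    fprefix = "g", sprefix = "s") {
  dimnames(values) <- list(sprintf("%s%03d", fprefix, seq_len(nrow(values))),
                           sprintf("%s%02d", sprefix, seq_len(ncol(values))))
  ExpressionMatrix(values, kind, condition = condition, group = group)
}

random_em <- function(n_features, n_samples, kind = "mRNA",
                      condition = NULL, group = NULL, sd = 1,
                      fprefix = if (kind == "mRNA") "g" else "m") {
  make_em(matrix(rnorm(n_features * n_samples, sd = sd),
                 n_features, n_samples),
          kind = kind, condition = condition, group = group,
          fprefix = fprefix)
}

# random weighted bipartite network via the public edge-list reader,
# guaranteeing at least one edge
random_network <- function(n_mirna, n_mrna, density = 0.3) {
  repeat {
    pairs <- expand.grid(mirna_id = sprintf("mir%02d", seq_len(n_mirna)),
                         mrna_id = sprintf("g%02d", seq_len(n_mrna)),
                         stringsAsFactors = FALSE)
    keep <- runif(nrow(pairs)) < density
    if (any(keep)) break
  }
  edges <- pairs[keep, , drop = FALSE]
  edges$r <- -runif(nrow(edges), 0.05, 1)
  edges$p <- runif(nrow(edges), 0, 0.05)
  edges$weight <- abs(edges$r)
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  read_edges(path)
}

# well-separated two-group cohort: the first n_genes are informative
# (alternately up- and down-regulated in cases, so a per-sample median is
# unaffected), followed by n_noise uninformative background genes
separable_cohort <- function(n_per_group = 10, n_genes = 3, delta = 5,
                             n_noise = 0) {
  group <- rep(c("control", "case"), each = n_per_group)
  v <- matrix(rnorm((n_genes + n_noise) * 2 * n_per_group),
              n_genes + n_noise, 2 * n_per_group)
  sign_ <- rep_len(c(1, -1), n_genes)
  v[seq_len(n_genes), group == "case"] <-
    v[seq_len(n_genes), group == "case"] + sign_ * delta
  make_em(v, group = group)
}
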