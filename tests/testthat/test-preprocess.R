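test_that("probe aggregation averages probes per gene", {
  v <- matrix(c(2, 4, 6, 1, 3, 5), 3, 2,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  em <- ExpressionMatrix(v, "mRNA")
  map <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene_id = c("G", "G", "G"))
  agg <- aggregate_probes(em, map)
  expect_equal(unname(agg$values["G", ]), c(4, 3))

  # single-probe gene passes through unchanged
  map2 <- data.frame(probe_id = "p2", gene_id = "H")
  agg2 <- suppressMessages(aggregate_probes(em, map2))
  expect_equal(unname(agg2$values["H", ]), unname(v["p2", ]))
})

test_that("probe aggregation matches a brute-force per-gene mean oracle", {
  set.seed(21)
  em <- random_em(20, 5, fprefix = "p")
  map <- data.frame(probe_id = feature_ids(em),
                    gene_id = sample(paste0("G", 1:5), 20, replace = TRUE))
  agg <- aggregate_probes(em, map)
  expect_identical(nrow(agg$values), length(unique(map$gene_id)))
  for (g in unique(map$gene_id)) {
    probes <- map$probe_id[map$gene_id == g]
    expect_equal(agg$values[g, ],
                 colMeans(em$values[probes, , drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("unmapped probes are dropped and an empty mapping is an error", {
  set.seed(22)
  em <- random_em(4, 3, fprefix = "p")
  map <- data.frame(probe_id = c("p001", "p002"), gene_id = c("A", "B"))
  expect_message(agg <- aggregate_probes(em, map), "2 unmapped")
  expect_identical(sort(feature_ids(agg)), c("A", "B"))
  expect_error(
    aggregate_probes(em, data.frame(probe_id = "zz", gene_id = "A")),
    "no probe")
})

test_that("feature intersection restricts all matrices to the common set", {
  v <- function(ids) {
    m <- matrix(rnorm(length(ids) * 2), length(ids), 2,
                dimnames = list(ids, c("s1", "s2")))
    ExpressionMatrix(m, "mRNA")
  }
  out <- intersect_features(list(v(c("A", "B", "C")), v(c("B", "C", "D"))))
  expect_identical(feature_ids(out[[1]]), c("B", "C"))
  expect_identical(feature_ids(out[[2]]), c("B", "C"))

  # identical sets: unchanged values
  a <- v(c("A", "B"))
  out2 <- intersect_features(list(a, a))
  expect_equal(out2[[1]]$values, a$values)

  # random id sets against the set-operation oracle
  set.seed(23)
  sets <- replicate(3, sample(paste0("f", 1:30), 20), simplify = FALSE)
  mats <- lapply(sets, v)
  out3 <- intersect_features(mats)
  expected <- sort(Reduce(intersect, sets))
  for (m in out3) expect_identical(feature_ids(m), expected)

  expect_error(intersect_features(list(v("A"), v("B"))), "empty")
  expect_error(intersect_features(list(a)), "at least two")
})

test_that("median normalization equalizes column medians", {
  set.seed(24)
  em <- random_em(31, 6)
  norm <- median_normalize(em)
  med <- apply(norm$values, 2, median)
  expect_lt(max(med) - min(med), 1e-12)
  expect_identical(dim(norm$values), dim(em$values))
  expect_identical(feature_ids(norm), feature_ids(em))

  # already equal medians: fixed point
  expect_equal(median_normalize(norm)$values, norm$values,
               tolerance = 1e-12)

  # shifting a column is undone
  shifted <- em
  shifted$values[, 2] <- shifted$values[, 2] + 3.7
  expect_equal(median_normalize(shifted)$values, norm$values,
               tolerance = 1e-12)
})

test_that("lowess normalization removes offsets and intensity bias", {
  set.seed(25)
  # five identical samples pin the row-median reference to the base profile
  # regardless of what the sixth (test) column contains
  base <- rnorm(200, mean = 8)
  with_test_col <- function(v) make_em(cbind(matrix(base, 200, 5), v))

  # a sample equal to the reference is untouched
  out <- lowess_normalize(with_test_col(base))
  expect_equal(unname(out$values[, 6]), base, tolerance = 1e-9)

  # constant offset removed
  out <- lowess_normalize(with_test_col(base + 2.5))
  expect_equal(unname(out$values[, 6]), base, tolerance = 1e-6)

  # intensity-proportional bias reduced by at least 90 percent
  slope <- function(v) {
    a <- (v + base) / 2
    unname(coef(lm((v - base) ~ a))[2])
  }
  biased <- base + 0.3 * (base - mean(base))
  before <- abs(slope(biased))
  after <- abs(slope(lowess_normalize(with_test_col(biased))$values[, 6]))
  expect_lt(after, 0.1 * before)

  # too few features: warning and median fallback
  tiny <- random_em(5, 3)
  expect_warning(out <- lowess_normalize(tiny), "fewer than 10")
  expect_equal(out$values, median_normalize(tiny)$values)
})

test_that("ANOVA filter agrees with aov() and handles degenerate rows", {
  set.seed(26)
  condition <- rep(paste0("c", 1:3), each = 4)
  em <- random_em(20, 12, condition = condition)
  em$values[1, ] <- em$values[1, ] + 3 * (condition == "c2")
  res <- anova_filter(em, alpha = 0.05)
  for (i in c(1, 5, 9)) {
    fit <- summary(aov(em$values[i, ] ~ factor(condition)))[[1]]
    expect_equal(unname(res$p_values[i]), fit[["Pr(>F)"]][1],
                 tolerance = 1e-10)
  }
  expect_true(feature_ids(em)[1] %in% res$selected)

  # constant feature: equal group means, degenerate rule gives p = 1
  em$values[2, ] <- 5
  res2 <- suppressMessages(anova_filter(em))
  expect_equal(unname(res2$p_values[2]), 1)
  expect_false("g002" %in% res2$selected)

  # zero within-group variance with different means gives p = 0
  em$values[3, ] <- c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3)
  res3 <- suppressMessages(anova_filter(em))
  expect_equal(unname(res3$p_values[3]), 0)
})

test_that("ANOVA selection is monotone in alpha", {
  set.seed(27)
  em <- random_em(60, 12, condition = rep(c("a", "b", "c"), each = 4))
  res <- anova_filter(em, alpha = 1)
  for (alphas in list(c(0.01, 0.05), c(0.05, 0.2), c(0.2, 1))) {
    s1 <- feature_ids(em)[res$p_values <= alphas[1]]
    s2 <- feature_ids(em)[res$p_values <= alphas[2]]
    expect_true(all(s1 %in% s2))
  }
  expect_error(anova_filter(random_em(3, 4)), "no condition")
  expect_error(
    anova_filter(random_em(3, 4, condition = c("a", "a", "a", "a"))),
    "at least two")
})
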