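test_that("well-separated groups are clustered perfectly", {
  set.seed(51)
  cohort <- separable_cohort(n_per_group = 10, n_genes = 3, delta = 5,
                             n_noise = 47)
  res <- cluster_samples(cohort, feature_ids(cohort)[1:3])
  expect_equal(res$accuracy, 1)
  expect_length(res$misclassified, 0)
  expect_identical(sort(unique(res$predicted_cluster)), 1:2)
})

test_that("accuracy is invariant to relabelling, sample order, duplication", {
  set.seed(52)
  cohort <- separable_cohort(8, 3, delta = 2, n_noise = 2)
  panel <- paste0("g", sprintf("%03d", 1:5))
  res <- suppressWarnings(cluster_samples(cohort, panel))

  # swap the group labels
  swapped <- ExpressionMatrix(cohort$values, "mRNA",
                              group = ifelse(cohort$group == "case",
                                             "control", "case"))
  expect_equal(cluster_samples(swapped, panel)$accuracy, res$accuracy)

  # permute samples
  perm <- sample(ncol(cohort$values))
  shuffled <- ExpressionMatrix(cohort$values[, perm], "mRNA",
                               group = as.character(cohort$group)[perm])
  expect_equal(cluster_samples(shuffled, panel)$accuracy, res$accuracy)

  # duplicate every sample
  dup_v <- cbind(cohort$values, cohort$values)
  colnames(dup_v) <- paste0("s", seq_len(ncol(dup_v)))
  dup <- ExpressionMatrix(dup_v, "mRNA",
                          group = rep(as.character(cohort$group), 2))
  expect_equal(cluster_samples(dup, panel)$accuracy, res$accuracy)
})

test_that("structure-free data clusters near chance level", {
  set.seed(53)
  accs <- replicate(60, {
    cohort <- random_em(30, 24, group = sample(rep(c("a", "b"), 12)))
    cluster_samples(cohort, feature_ids(cohort)[1:10])$accuracy
  })
  expect_gte(min(accs), 0.5)   # best-assignment lower bound
  expect_lt(mean(accs), 0.68)  # no better than the null baseline
})

test_that("panel genes absent from the cohort are dropped or rejected", {
  set.seed(54)
  cohort <- separable_cohort(6, 3)
  expect_warning(res <- cluster_samples(cohort, c(feature_ids(cohort), "zz")),
                 "absent")
  expect_identical(res$panel_used, feature_ids(cohort))
  expect_error(cluster_samples(cohort, c("zz", "yy")), "no panel gene")
  expect_error(suppressWarnings(
    cluster_samples(cohort, c("g001", "yy"))), "fewer than 2")
})

test_that("de_rank orders by the row-test p-value with id tie-breaks", {
  set.seed(55)
  condition <- rep(paste0("c", 1:3), each = 4)
  em <- random_em(50, 12, condition = condition)
  em$values[7, ] <- em$values[7, ] + 8 * (condition == "c1")
  ranking <- de_rank(em)
  expect_identical(ranking$node_id[1], "g007")

  # ordering equals a brute-force recomputation per feature
  p_oracle <- vapply(seq_len(50), function(i)
    oracle_anova_pvalue(em$values[i, ], condition), numeric(1))
  names(p_oracle) <- feature_ids(em)
  expect_identical(ranking$node_id,
                   names(p_oracle)[order(p_oracle, names(p_oracle))])
  expect_equal(ranking$p_value,
               unname(sort(p_oracle)[ranking$node_id]), tolerance = 1e-9)
})

test_that("de_rank p-values are uniform under the null", {
  set.seed(56)
  em <- random_em(300, 12, condition = rep(c("a", "b", "c"), each = 4))
  p <- de_rank(em)$p_value
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("two_group_ttest reports direction and matches t.test", {
  set.seed(57)
  group <- rep(c("control", "case"), each = 10)
  em <- random_em(20, 20, group = group)
  em$values[1, group == "case"] <- em$values[1, group == "case"] + 10
  em$values[2, group == "case"] <- em$values[2, group == "case"] - 10
  res <- two_group_ttest(em, c("g001", "g002", "g003"),
                         case_level = "case")
  expect_identical(res$direction[1:2], c("Up-regulated", "Down-regulated"))
  expect_lt(res$p_value[1], 1e-6)
  expect_lt(res$p_value[2], 1e-6)
  ref <- t.test(em$values[3, group == "case"],
                em$values[3, group == "control"], var.equal = TRUE)
  expect_equal(res$p_value[3], ref$p.value, tolerance = 1e-12)
})

test_that("two_group_ttest p-values are uniform when groups are equal", {
  set.seed(58)
  group <- rep(c("control", "case"), each = 12)
  em <- random_em(300, 24, group = group)
  res <- two_group_ttest(em, feature_ids(em))
  expect_gt(ks.test(res$p_value, "punif")$p.value, 0.01)
})

test_that("accuracy_curve composes cluster_samples over the k grid", {
  set.seed(59)
  cohort <- separable_cohort(8, 5, delta = 3, n_noise = 10)
  ranking_a <- data.frame(node_id = feature_ids(cohort))
  ranking_b <- data.frame(node_id = rev(feature_ids(cohort)))
  k_grid <- c(2, 4, 8)
  curve <- accuracy_curve(ranking_a, ranking_b, list(v = cohort), k_grid)
  expect_identical(nrow(curve), 6L)
  for (row in seq_len(nrow(curve))) {
    rk <- if (curve$method[row] == "pagerank") ranking_a else ranking_b
    manual <- suppressWarnings(
      cluster_samples(cohort, select_top(rk, curve$k[row]))$accuracy)
    expect_equal(curve$accuracy[row], manual)
  }
  expect_error(accuracy_curve(ranking_a, ranking_b, list(v = cohort),
                              c(4, 2)), "strictly increasing")
  expect_error(accuracy_curve(ranking_a, ranking_b, list(v = cohort),
                              c(2, 99)), "ranking length")

  # a fully informative panel at every k gives a flat curve at 1
  ideal <- separable_cohort(8, 15, delta = 6, n_noise = 30)
  informative <- data.frame(node_id = feature_ids(ideal)[1:15])
  flat <- accuracy_curve(informative, informative,
                         list(v = ideal), c(2, 5, 15))
  expect_true(all(flat$accuracy == 1))
})
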