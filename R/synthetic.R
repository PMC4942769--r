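#' Configuration for the synthetic paired-expression generator
#'
#' Describes a multi-condition paired miRNA/mRNA training experiment
#' (defaults emulate a 6-condition x 4-replicate brain design) with planted
#' negative-regulation hub structure, plus matched two-group validation
#' cohorts in which only the hub genes replicate as informative.
#'
#' Each hub mRNA is repressed by a module of `regulators_per_hub` miRNAs.
#' Module members are modelled as a co-transcribed miRNA cluster: they share
#' a module expression program (a per-condition shift of sd
#' `condition_effect` plus a per-sample factor of sd `sigma`) with
#' within-module correlation `mirna_module_cor`, and otherwise vary
#' independently; every miRNA keeps the same marginal structure (condition
#' shift sd `condition_effect`, noise sd `sigma`). A fraction
#' `frac_train_specific_de` of the non-hub mRNAs are training-specific
#' "decoy" genes: they receive their own independent condition shifts (so
#' they are differentially expressed in training) but are exchangeable
#' between the groups of any validation cohort.
#'
#' @param n_mirna Number of miRNAs (default 50).
#' @param n_mrna Number of mRNAs (default 500).
#' @param n_conditions Number of experimental conditions (default 6).
#' @param reps_per_condition Replicates per condition (default 4).
#' @param n_hubs Number of planted hub mRNAs (default 10).
#' @param regulators_per_hub miRNAs regulating each hub (default 8).
#' @param beta Regulation strength of each hub on its regulator module
#'   (default 0.8).
#' @param sigma Replicate-level noise sd (default 1.0).
#' @param condition_effect Sd of per-condition miRNA shifts (default 2.0);
#'   also used for the decoys' own condition shifts.
#' @param mirna_module_cor Within-module correlation of a hub's regulators
#'   (default 0.7); 0 gives fully independent miRNAs.
#' @param cohort_n_per_group Samples per group in a validation cohort
#'   (default 20).
#' @param cohort_hub_shift Between-group shift of hub genes in validation
#'   cohorts, in sd units (default 2.0).
#' @param frac_train_specific_de Fraction of non-hub mRNAs that are
#'   training-specific decoys (default 0.2).
#' @param seed Integer RNG seed (default 1).
#' @return A `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_mirna = 50, n_mrna = 500, n_conditions = 6,
                             reps_per_condition = 4, n_hubs = 10,
                             regulators_per_hub = 8, beta = 0.8, sigma = 1.0,
                             condition_effect = 2.0, mirna_module_cor = 0.7,
                             cohort_n_per_group = 20, cohort_hub_shift = 2.0,
                             frac_train_specific_de = 0.2, seed = 1L) {
  cfg <- list(n_mirna = n_mirna, n_mrna = n_mrna, n_conditions = n_conditions,
              reps_per_condition = reps_per_condition, n_hubs = n_hubs,
              regulators_per_hub = regulators_per_hub, beta = beta,
              sigma = sigma, condition_effect = condition_effect,
              mirna_module_cor = mirna_module_cor,
              cohort_n_per_group = cohort_n_per_group,
              cohort_hub_shift = cohort_hub_shift,
              frac_train_specific_de = frac_train_specific_de,
              seed = as.integer(seed))
  counts <- c("n_mirna", "n_mrna", "n_conditions", "reps_per_condition",
              "n_hubs", "regulators_per_hub", "cohort_n_per_group")
  for (nm in counts)
    if (cfg[[nm]] < 1) stop("'", nm, "' must be positive")
  if (cfg$regulators_per_hub > cfg$n_mirna)
    stop("'regulators_per_hub' must not exceed 'n_mirna'")
  if (cfg$n_hubs > cfg$n_mrna) stop("'n_hubs' must not exceed 'n_mrna'")
  if (cfg$frac_train_specific_de < 0 || cfg$frac_train_specific_de > 1)
    stop("'frac_train_specific_de' must lie in [0, 1]")
  if (cfg$mirna_module_cor < 0 || cfg$mirna_module_cor > 1)
    stop("'mirna_module_cor' must lie in [0, 1]")
  if (cfg$sigma < 0 || cfg$condition_effect < 0 || cfg$beta < 0)
    stop("'sigma', 'condition_effect' and 'beta' must be non-negative")
  structure(cfg, class = "SyntheticConfig")
}

.zero_pad <- function(prefix, n)
  sprintf(paste0(prefix, "%0", nchar(n), "d"), seq_len(n))

#' Generate a paired miRNA/mRNA training dataset with planted structure
#'
#' Draws, in this fixed stream order from `config$seed`: (1) hub identities,
#' regulator modules, decoy identities and per-hub cohort shift directions;
#' (2) feature baselines; (3) module programs; (4) miRNA individual
#' components; (5) mRNA noise; (6) decoy condition shifts. Identical config
#' and seed give bit-identical output.
#'
#' Values are built as: miRNA = baseline + condition shift + noise (module
#' members share their module program with correlation
#' `mirna_module_cor`); hub mRNA = baseline − `beta` * sum of its
#' regulators' centred values + noise; decoy mRNA = baseline + own condition
#' shift + noise; remaining mRNAs = baseline + noise.
#'
#' @param config A [synthetic_config()].
#' @return List with `mirna` and `mrna` ([ExpressionMatrix] objects sharing
#'   samples and condition labels) and `truth` (a `SyntheticTruth`: hub ids,
#'   regulator map, decoy ids, per-hub cohort shift signs).
#' @export
generate_training <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  n <- config$n_conditions * config$reps_per_condition
  cond_of <- rep(seq_len(config$n_conditions),
                 each = config$reps_per_condition)
  mirna_ids <- .zero_pad("mir", config$n_mirna)
  mrna_ids <- .zero_pad("gene", config$n_mrna)
  sample_names <- sprintf("cond%d_rep%d", cond_of,
                          rep(seq_len(config$reps_per_condition),
                              config$n_conditions))
  condition <- paste0("cond", cond_of)

  # (1) planted identities
  hubs <- sort(sample(mrna_ids, config$n_hubs))
  regulator_map <- stats::setNames(lapply(seq_len(config$n_hubs), function(i)
    sort(sample(mirna_ids, config$regulators_per_hub))), hubs)
  non_hub <- setdiff(mrna_ids, hubs)
  n_decoy <- round(config$frac_train_specific_de * length(non_hub))
  decoys <- sort(sample(non_hub, n_decoy))
  hub_sign <- stats::setNames(sample(c(-1, 1), config$n_hubs, replace = TRUE),
                              hubs)

  # (2) baselines
  mu_mirna <- stats::rnorm(config$n_mirna, 7, 0.5)
  mu_mrna <- stats::rnorm(config$n_mrna, 8, 0.5)

  # (3) module programs: shared condition response + shared sample factor
  prog <- matrix(stats::rnorm(config$n_hubs * config$n_conditions, 0,
                              config$condition_effect),
                 config$n_hubs, config$n_conditions)[, cond_of, drop = FALSE] +
    matrix(stats::rnorm(config$n_hubs * n, 0, config$sigma),
           config$n_hubs, n)

  # (4) miRNA individual components
  own <- matrix(stats::rnorm(config$n_mirna * config$n_conditions, 0,
                             config$condition_effect),
                config$n_mirna, config$n_conditions)[, cond_of, drop = FALSE] +
    matrix(stats::rnorm(config$n_mirna * n, 0, config$sigma),
           config$n_mirna, n)
  membership <- lapply(mirna_ids, function(id)
    which(vapply(regulator_map, function(r) id %in% r, logical(1))))
  rho <- config$mirna_module_cor
  mirna_signal <- own
  for (j in seq_len(config$n_mirna)) {
    mods <- membership[[j]]
    if (length(mods) > 0 && rho > 0) {
      shared <- colSums(prog[mods, , drop = FALSE]) / sqrt(length(mods))
      mirna_signal[j, ] <- sqrt(rho) * shared + sqrt(1 - rho) * own[j, ]
    }
  }
  mirna_values <- mu_mirna + mirna_signal
  dimnames(mirna_values) <- list(mirna_ids, sample_names)

  # (5) mRNA noise, (6) decoy shifts
  mrna_values <- mu_mrna +
    matrix(stats::rnorm(config$n_mrna * n, 0, config$sigma),
           config$n_mrna, n)
  dimnames(mrna_values) <- list(mrna_ids, sample_names)
  for (h in hubs)
    mrna_values[h, ] <- mrna_values[h, ] - config$beta *
      colSums(mirna_signal[match(regulator_map[[h]], mirna_ids), ,
                           drop = FALSE])
  if (n_decoy > 0)
    mrna_values[decoys, ] <- mrna_values[decoys, ] +
      matrix(stats::rnorm(n_decoy * config$n_conditions, 0,
                          config$condition_effect),
             n_decoy, config$n_conditions)[, cond_of, drop = FALSE]

  truth <- structure(list(hub_mrna_ids = hubs, regulator_map = regulator_map,
                          train_specific_de_ids = decoys,
                          hub_sign = hub_sign),
                     class = "SyntheticTruth")
  list(mirna = ExpressionMatrix(mirna_values, "miRNA", condition = condition),
       mrna = ExpressionMatrix(mrna_values, "mRNA", condition = condition),
       truth = truth)
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf(
    "SyntheticTruth: %d hubs (%d regulators each), %d decoy genes\n",
    length(x$hub_mrna_ids), length(x$regulator_map[[1]]),
    length(x$train_specific_de_ids)))
  invisible(x)
}

#' Generate a case/control validation cohort matched to a training dataset
#'
#' The cohort carries the training mRNA gene set. Hub genes are shifted
#' between groups by `cohort_hub_shift` (direction per hub from the planted
#' truth); decoy genes and all remaining genes are exchangeable between
#' groups (pure noise around the gene baseline), which is what makes
#' training-specific DE genes uninformative here.
#'
#' @param config The [synthetic_config()] used for training.
#' @param truth `SyntheticTruth` from [generate_training()].
#' @param seed Integer seed for this cohort (cohorts are independent of the
#'   training draw).
#' @return An [ExpressionMatrix] with a `group` annotation
#'   (`control`/`case`).
#' @export
generate_cohort <- function(config, truth, seed) {
  stopifnot(inherits(config, "SyntheticConfig"),
            inherits(truth, "SyntheticTruth"))
  set.seed(as.integer(seed))
  mrna_ids <- .zero_pad("gene", config$n_mrna)
  n_per <- config$cohort_n_per_group
  n <- 2 * n_per
  group <- rep(c("control", "case"), each = n_per)
  mu <- stats::rnorm(config$n_mrna, 8, 0.5)
  values <- mu + matrix(stats::rnorm(config$n_mrna * n, 0, config$sigma),
                        config$n_mrna, n)
  dimnames(values) <- list(mrna_ids,
                           sprintf("%s%02d", group,
                                   c(seq_len(n_per), seq_len(n_per))))
  for (h in truth$hub_mrna_ids)
    values[h, group == "case"] <- values[h, group == "case"] +
      truth$hub_sign[[h]] * config$cohort_hub_shift
  ExpressionMatrix(values, "mRNA", group = group)
}

#' Write a synthetic dataset to tab-delimited files
#'
#' Writes the training matrices, phenotype table, cohort matrices and a JSON
#' truth file in the same formats the pipeline reads.
#'
#' @param config A [synthetic_config()].
#' @param outdir Output directory (created if absent).
#' @param n_cohorts Number of validation cohorts to write (default 2);
#'   cohort `i` uses seed `config$seed + i`.
#' @return Invisibly, the list of written file paths.
#' @export
write_synthetic_dataset <- function(config, outdir, n_cohorts = 2) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  train <- generate_training(config)
  paths <- list(
    mirna = file.path(outdir, "train_mirna.tsv"),
    mrna = file.path(outdir, "train_mrna.tsv"),
    pheno = file.path(outdir, "train_pheno.tsv"))
  write_expression(train$mirna, paths$mirna)
  write_expression(train$mrna, paths$mrna)
  utils::write.table(
    data.frame(sample_id = sample_ids(train$mrna),
               condition = as.character(train$mrna$condition)),
    paths$pheno, sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_len(n_cohorts)) {
    cohort <- generate_cohort(config, train$truth, config$seed + i)
    cp <- file.path(outdir, sprintf("cohort%d.tsv", i))
    pp <- file.path(outdir, sprintf("cohort%d_pheno.tsv", i))
    write_expression(cohort, cp)
    utils::write.table(
      data.frame(sample_id = sample_ids(cohort),
                 group = as.character(cohort$group)),
      pp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[sprintf("cohort%d", i)]] <- cp
    paths[[sprintf("cohort%d_pheno", i)]] <- pp
  }
  truth_path <- file.path(outdir, "truth.json")
  truth_json <- sprintf(
    '{\n  "hub_mrna_ids": [%s],\n  "train_specific_de_ids": [%s],\n  "regulator_map": {%s},\n  "hub_sign": {%s}\n}\n',
    paste(sprintf('"%s"', train$truth$hub_mrna_ids), collapse = ", "),
    paste(sprintf('"%s"', train$truth$train_specific_de_ids), collapse = ", "),
    paste(sprintf('"%s": [%s]', names(train$truth$regulator_map),
                  vapply(train$truth$regulator_map, function(r)
                    paste(sprintf('"%s"', r), collapse = ", "), character(1))),
          collapse = ", "),
    paste(sprintf('"%s": %d', names(train$truth$hub_sign),
                  as.integer(train$truth$hub_sign)), collapse = ", "))
  writeLines(truth_json, truth_path)
  paths$truth <- truth_path
  invisible(paths)
}
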