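#' Expression matrix with feature and sample annotation
#'
#' Container for a features x samples matrix of (log-scale) expression
#' intensities together with the feature kind (`"mRNA"` or `"miRNA"`), an
#' optional per-sample experimental condition (used by [anova_filter()] and
#' [de_rank()]) and an optional per-sample case/control group (used by
#' [cluster_samples()] and [two_group_ttest()]).
#'
#' Feature identifiers are the rownames and sample identifiers the colnames;
#' both must be unique. Values are expected on a log scale; set
#' `log2_transform = TRUE` in [read_expression()] for raw intensities.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   unique rownames and colnames.
#' @param feature_kind Either `"mRNA"` or `"miRNA"`.
#' @param condition Optional character/factor of length `ncol(values)` giving
#'   the experimental condition of each sample.
#' @param group Optional character/factor of length `ncol(values)` giving the
#'   case/control group of each sample.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `feature_kind`, `condition`, `group`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- ExpressionMatrix(m, "mRNA", condition = rep(c("a", "b"), each = 2))
#' em
#' @export
ExpressionMatrix <- function(values, feature_kind = c("mRNA", "miRNA"),
                             condition = NULL, group = NULL) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have rownames (features) and colnames (samples)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (!is.null(condition)) {
    if (length(condition) != ncol(values))
      stop("'condition' must have one entry per sample")
    condition <- factor(condition)
  }
  if (!is.null(group)) {
    if (length(group) != ncol(values))
      stop("'group' must have one entry per sample")
    group <- factor(group)
  }
  structure(list(values = values, feature_kind = feature_kind,
                 condition = condition, group = group),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix (%s): %d features x %d samples\n",
              x$feature_kind, nrow(x$values), ncol(x$values)))
  if (!is.null(x$condition))
    cat("  conditions:", paste(levels(x$condition), collapse = ", "), "\n")
  if (!is.null(x$group))
    cat("  groups:", paste(levels(x$group), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Feature and sample identifiers
#'
#' @param x An [ExpressionMatrix].
#' @return Character vector of identifiers.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Restrict an ExpressionMatrix to a set of features
#'
#' @param x An [ExpressionMatrix].
#' @param ids Feature identifiers to keep, in the order given.
#' @return An [ExpressionMatrix] with only the requested features.
#' @export
subset_features <- function(x, ids) {
  missing_ids <- setdiff(ids, feature_ids(x))
  if (length(missing_ids) > 0)
    stop("features not present in matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  ExpressionMatrix(x$values[ids, , drop = FALSE], x$feature_kind,
                   condition = x$condition, group = x$group)
}

#' Read a tab-delimited expression matrix
#'
#' Expects the GEO series-matrix body convention: a header row of sample
#' identifiers and a first column of feature identifiers. Gzip-compressed
#' files are accepted transparently.
#'
#' @param file Path to a tab-delimited text file (optionally `.gz`).
#' @param feature_kind `"mRNA"` or `"miRNA"`.
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` to the values (use for
#'   raw-scale intensities; the pipeline operates on log-scale values).
#' @param drop_incomplete Drop features containing missing values (default
#'   `TRUE`; the number dropped is reported).
#' @return An [ExpressionMatrix] without condition/group annotation; attach
#'   one with [attach_phenotype()].
#' @export
read_expression <- function(file, feature_kind = c("mRNA", "miRNA"),
                            log2_transform = FALSE, drop_incomplete = TRUE) {
  feature_kind <- match.arg(feature_kind)
  tab <- utils::read.delim(file, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE, comment.char = "")
  values <- as.matrix(tab)
  storage.mode(values) <- "double"
  if (log2_transform) values <- log2(values + 1)
  if (drop_incomplete) {
    bad <- rowSums(is.na(values)) > 0
    if (any(bad)) {
      message(sum(bad), " features with missing values dropped")
      values <- values[!bad, , drop = FALSE]
    }
  }
  ExpressionMatrix(values, feature_kind)
}

#' Write an ExpressionMatrix as tab-delimited text
#'
#' @param x An [ExpressionMatrix].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_expression <- function(x, file) {
  tab <- data.frame(feature_id = feature_ids(x), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a phenotype table
#'
#' Tab-delimited with columns `sample_id`, `condition` and optionally `group`
#' (case/control label for validation cohorts).
#'
#' @param file Path to the table.
#' @return A data frame with columns `sample_id`, `condition` and, when
#'   present, `group`.
#' @export
read_phenotype <- function(file) {
  tab <- utils::read.delim(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- "sample_id"
  if (!all(required %in% names(tab)))
    stop("phenotype table must contain a 'sample_id' column")
  tab
}

#' Attach phenotype annotation to an ExpressionMatrix
#'
#' Matches phenotype rows to matrix columns by `sample_id`; every sample in
#' the matrix must be annotated.
#'
#' @param x An [ExpressionMatrix].
#' @param pheno Data frame from [read_phenotype()].
#' @return `x` with `condition` and/or `group` set.
#' @export
attach_phenotype <- function(x, pheno) {
  idx <- match(sample_ids(x), pheno$sample_id)
  if (anyNA(idx))
    stop("phenotype table is missing samples: ",
         paste(utils::head(sample_ids(x)[is.na(idx)], 5), collapse = ", "))
  ExpressionMatrix(x$values, x$feature_kind,
                   condition = if ("condition" %in% names(pheno))
                     pheno$condition[idx] else x$condition,
                   group = if ("group" %in% names(pheno))
                     pheno$group[idx] else x$group)
}

#' Read a probe-to-gene map
#'
#' Two-column tab-delimited text, `probe_id` then `gene_id`; many probes may
#' map to one gene, but a probe may map to only one gene.
#'
#' @param file Path to the map.
#' @return A data frame with columns `probe_id`, `gene_id`.
#' @export
read_probe_map <- function(file) {
  tab <- utils::read.delim(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(tab)))
    stop("probe map must contain 'probe_id' and 'gene_id' columns")
  if (anyDuplicated(tab$probe_id))
    stop("probe map assigns some probe to more than one gene")
  tab
}
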