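#' Construct a two-group expression dataset
#'
#' Container for a genes x samples matrix of log2 expression intensities
#' with a two-level group factor. Values are taken as already log2-scaled;
#' "fold change" throughout the package is the difference of group means on
#' this scale, so 0 means no change.
#'
#' @param values Numeric matrix, rows = genes (rownames = gene ids),
#'   columns = samples (colnames = sample ids).
#' @param groups Named character vector mapping every sample id to one of
#'   exactly two group labels; each group needs at least two samples.
#' @param reference Label of the reference group. Fold change is
#'   mean(case) - mean(reference), so its sign is fixed by this choice,
#'   never by alphabetical order.
#' @return An object of class `expression_dataset` with fields `values`,
#'   `gene_ids`, `sample_ids`, `groups`, `reference`, `case`.
#' @export
expression_dataset <- function(values, groups, reference) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression_dataset: 'values' must be a numeric matrix")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("expression_dataset: 'values' needs rownames (genes) and colnames (samples)")
  if (anyDuplicated(gene_ids))
    stop("expression_dataset: duplicate gene id: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("expression_dataset: duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  missing_samples <- setdiff(sample_ids, names(groups))
  if (length(missing_samples))
    stop("expression_dataset: no group assigned to sample: ",
         paste(missing_samples, collapse = ", "))
  groups <- groups[sample_ids]
  labs <- unique(unname(groups))
  if (length(labs) != 2)
    stop("expression_dataset: need exactly two group labels, got: ",
         paste(labs, collapse = ", "))
  if (!reference %in% labs)
    stop("expression_dataset: reference group '", reference,
         "' is not one of: ", paste(labs, collapse = ", "))
  counts <- table(groups)
  if (any(counts < 2))
    stop("expression_dataset: group '", names(counts)[counts < 2][1],
         "' has fewer than 2 samples")
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         groups = groups, reference = reference,
         case = setdiff(labs, reference)),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (log2 scale)\n",
              length(x$gene_ids), length(x$sample_ids)))
  cat(sprintf("  groups: %s (case) vs %s (reference), n = %d / %d\n",
              x$case, x$reference, sum(x$groups == x$case),
              sum(x$groups == x$reference)))
  invisible(x)
}

case_cols <- function(ds) which(ds$groups == ds$case)
ref_cols <- function(ds) which(ds$groups == ds$reference)

#' Load an expression dataset from delimited files
#'
#' Reads a tab-delimited genes x samples matrix (first column gene ids,
#' header row sample ids) and a two-column tab-delimited design file
#' (sample id, group label) into a validated [expression_dataset].
#'
#' @param matrix_file Path to the expression matrix file.
#' @param design_file Path to the design file. A header line is optional
#'   and detected by the first line not matching any matrix sample id.
#' @param reference_group Reference group label.
#' @return An [expression_dataset].
#' @export
load_dataset <- function(matrix_file, design_file, reference_group) {
  for (f in c(matrix_file, design_file))
    if (!file.exists(f)) stop("load_dataset: file not found: ", f)
  tab <- utils::read.table(matrix_file, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("load_dataset: matrix file needs gene id column plus samples")
  values <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(values)) stop("load_dataset: non-numeric expression values")
  rownames(values) <- as.character(tab[[1]])
  design <- utils::read.table(design_file, header = FALSE, sep = "\t",
                              stringsAsFactors = FALSE)
  if (ncol(design) < 2) stop("load_dataset: design file needs two columns")
  # tolerate an optional header row
  if (!design[1, 1] %in% colnames(values) && nrow(design) > 1)
    design <- design[-1, , drop = FALSE]
  groups <- setNames(as.character(design[[2]]), as.character(design[[1]]))
  expression_dataset(values, groups, reference_group)
}

#' Write a dataset to the delimited on-disk format
#'
#' Inverse of [load_dataset()]: writes the tab-delimited matrix and design
#' files that the loader and the command-line tools consume.
#'
#' @param ds An [expression_dataset].
#' @param matrix_file,design_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(ds, matrix_file, design_file) {
  tab <- data.frame(gene = ds$gene_ids, ds$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = ds$sample_ids, group = unname(ds$groups)),
    design_file, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(c(matrix_file, design_file))
}

#' Mean log2 fold change for a set of genes
#'
#' For each requested gene present in the dataset, the mean over case
#' samples minus the mean over reference samples, in log2 units. Genes
#' absent from the dataset map to `NA` (serialized as JSON null by the
#' service layer), never to an error: pathway gene sets routinely exceed
#' array content.
#'
#' @param ds An [expression_dataset].
#' @param genes Character vector of gene ids (may be empty).
#' @param linear If `TRUE`, report linear ratios `2^log2_fc` instead of
#'   log2 differences.
#' @return Named numeric vector, one entry per requested gene, `NA` where
#'   absent.
#' @export
mean_log2_fold_change <- function(ds, genes, linear = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!length(genes)) return(setNames(numeric(), character()))
  out <- setNames(rep(NA_real_, length(genes)), genes)
  present <- genes[genes %in% ds$gene_ids]
  if (length(present)) {
    m <- ds$values[present, , drop = FALSE]
    out[present] <- rowMeans(m[, case_cols(ds), drop = FALSE]) -
      rowMeans(m[, ref_cols(ds), drop = FALSE])
  }
  if (linear) out <- 2^out
  out
}

#' Per-sample fold change for one gene
#'
#' Each sample's log2 value minus the reference-group mean, in dataset
#' sample order — the quantity shown as a per-sample bar chart next to a
#' pathway view. The entries over reference samples average to zero by
#' construction.
#'
#' @param ds An [expression_dataset].
#' @param gene A single gene id present in the dataset.
#' @return Named numeric vector over all samples.
#' @export
per_sample_fold_change <- function(ds, gene) {
  stopifnot(inherits(ds, "expression_dataset"), length(gene) == 1)
  if (!gene %in% ds$gene_ids)
    stop("per_sample_fold_change: gene not found: ", gene)
  row <- ds$values[gene, ]
  row - mean(row[ref_cols(ds)])
}

#' Two-sample t-test on log2 expression values
#'
#' Two-sided t-test of `x` versus `y`; Welch (unequal variances, with
#' Welch-Satterthwaite degrees of freedom) by default, pooled-variance
#' Student's test with `var_equal = TRUE`. The statistic is computed for
#' `x` minus `y`, so swapping the groups negates t and preserves p.
#'
#' Zero-variance degenerate cases follow a documented convention instead of
#' returning NaN (the service must emit valid JSON numbers): both groups
#' constant with equal means gives t = 0, p = 1; both constant with
#' different means gives p = 0 with an infinite signed t.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @param var_equal Use the pooled-variance test.
#' @return List with elements `t_stat` and `p_value`.
#' @export
two_sample_t <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    stop("two_sample_t: need at least 2 values per group")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("two_sample_t: non-finite values")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    d <- mean(x) - mean(y)
    if (d == 0) return(list(t_stat = 0, p_value = 1))
    return(list(t_stat = sign(d) * Inf, p_value = 0))
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t_stat = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts raw p-values with the BH step-up rule: sort ascending, take
#' cumulative minima of p_(j) * n / j from the largest rank down, cap at 1,
#' and return in the original input order. Output is elementwise at least
#' the input and monotone along the sorted raw p-values.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values (q-values), same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Dataset-wide differential expression
#'
#' Per gene: log2 fold change (case minus reference group mean), t-test
#' statistic with raw two-sided p, and BH-adjusted q computed over all
#' genes of the dataset. Query endpoints that return statistics for a gene
#' subset always subset this table, so q-values never depend on the query.
#'
#' @param ds An [expression_dataset].
#' @param var_equal Passed to [two_sample_t()].
#' @return data.frame with columns `gene_id`, `log2_fc`, `t_stat`,
#'   `p_value`, `q_value`, one row per gene in dataset order.
#' @export
differential_expression <- function(ds, var_equal = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"))
  cs <- case_cols(ds); rs <- ref_cols(ds)
  tests <- lapply(seq_along(ds$gene_ids), function(i) {
    two_sample_t(ds$values[i, cs], ds$values[i, rs], var_equal = var_equal)
  })
  p <- vapply(tests, `[[`, 0, "p_value")
  data.frame(
    gene_id = ds$gene_ids,
    log2_fc = unname(mean_log2_fold_change(ds, ds$gene_ids)),
    t_stat = vapply(tests, `[[`, 0, "t_stat"),
    p_value = p,
    q_value = bh_adjust(p),
    stringsAsFactors = FALSE)
}

#' Raw expression rows for a set of genes
#'
#' Returns each present gene's full row with sample ids in dataset order;
#' absent genes map to `NULL` (absence is data, not an error).
#'
#' @param ds An [expression_dataset].
#' @param genes Character vector of gene ids.
#' @return Named list: per gene either a named numeric vector over samples,
#'   or `NULL`.
#' @export
raw_expression <- function(ds, genes) {
  stopifnot(inherits(ds, "expression_dataset"))
  out <- setNames(vector("list", length(genes)), genes)
  for (g in genes)
    if (g %in% ds$gene_ids) out[[g]] <- ds$values[g, ]
  out
}
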