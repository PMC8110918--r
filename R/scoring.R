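#' Per-sample cell-type scores from a marker catalog
#'
#' The score of a cell type in a sample is the arithmetic mean of the log2
#' expression values of that cell type's marker genes — a single-gene cell
#' type's score is exactly that gene's log2 value. Catalog genes absent from
#' the matrix are dropped with a warning and recorded per cell type; a cell
#' type with no present genes is excluded from the table entirely.
#'
#' @param m A log2-scale [expression_matrix()].
#' @param catalog A [gene_set_catalog()] of marker genes (typically the
#'   derived catalog from [select_markers()] or the bundled `pdac_mgic`).
#' @return An object of class `CellScoreTable`: list with `scores` (samples x
#'   cell types numeric matrix), `missing_genes` (named list, per cell type,
#'   of catalog genes absent from the matrix), `groups` (copied from `m`).
#' @examples
#' v <- matrix(c(4, 6, 2, 8), 2, dimnames = list(c("CD8A", "CD8B"),
#'                                               c("s1", "s2")))
#' m <- expression_matrix(v, scale = "log2")
#' cat8 <- gene_set_catalog(list(list(name = "CD8+ T cells",
#'                                    genes = c("CD8A", "CD8B"))))
#' cell_scores(m, cat8)$scores
#' @export
cell_scores <- function(m, catalog) {
  stopifnot(inherits(m, "ExpressionMatrix"),
            inherits(catalog, "GeneSetCatalog"))
  if (m$scale != "log2")
    stop("cell scores are means of log2 values; see log2_transform()")
  missing_genes <- list()
  cols <- list()
  for (e in catalog$entries) {
    present <- intersect(e$genes, rownames(m$values))
    absent <- setdiff(e$genes, present)
    if (length(absent)) missing_genes[[e$name]] <- absent
    if (!length(present)) {
      warning("cell type '", e$name,
              "' has no marker genes in the matrix; excluded from scores")
      next
    }
    cols[[e$name]] <- colMeans(m$values[present, , drop = FALSE])
  }
  if (!length(cols)) stop("no cell type has any marker gene in the matrix")
  scores <- do.call(cbind, cols)
  structure(list(scores = scores, missing_genes = missing_genes,
                 groups = m$groups),
            class = "CellScoreTable")
}

#' @export
print.CellScoreTable <- function(x, ...) {
  cat(sprintf("CellScoreTable: %d samples x %d cell types\n",
              nrow(x$scores), ncol(x$scores)))
  if (length(x$missing_genes))
    cat("  cell types with absent marker genes:",
        paste(names(x$missing_genes), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.CellScoreTable <- function(x, ...) {
  data.frame(sample = rownames(x$scores), x$scores, check.names = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-sample scores relative to a reference cell type
#'
#' Divides (`mode = "ratio"`) or subtracts (`mode = "log_diff"`) the
#' reference cell type's score from every cell type's score, sample by
#' sample. The usual reference is CD45+ (gene PTPRC, the pan-leukocyte
#' marker), which corrects each sample for its total immune infiltration.
#' Ratio of log2 values is the literal published normalization and the
#' default; `log_diff` (difference of log2 values, i.e. a log fold change
#' versus the reference) is the standard log-scale alternative and is
#' invariant to a global additive shift, which the ratio is not.
#'
#' @param t A [cell_scores()] table.
#' @param reference Reference cell-type label (default `"CD45+"`).
#' @param mode `"ratio"` or `"log_diff"`.
#' @return A `CellScoreTable` of relative scores with attributes `reference`
#'   and `mode`; the reference column is identically 1 (ratio) or 0
#'   (log_diff).
#' @seealso [relative_abundance()] for the group-level table.
#' @export
relative_scores <- function(t, reference = "CD45+",
                            mode = c("ratio", "log_diff")) {
  stopifnot(inherits(t, "CellScoreTable"))
  mode <- match.arg(mode)
  if (!reference %in% colnames(t$scores))
    stop("reference cell type '", reference, "' not in score table")
  ref <- t$scores[, reference]
  if (mode == "ratio" && any(ref == 0))
    stop("reference score is 0 for sample(s) ",
         paste(rownames(t$scores)[ref == 0], collapse = ", "),
         "; ratio undefined (consider mode = 'log_diff')")
  t$scores <- if (mode == "ratio") t$scores / ref else t$scores - ref
  attr(t, "reference") <- reference
  attr(t, "mode") <- mode
  t
}

#' Group-level relative abundance table
#'
#' The published group summary: for each group of samples, the group-mean
#' cell score divided by (`ratio`) or minus (`log_diff`) the group-mean
#' reference (CD45+) score.
#'
#' @param t A [cell_scores()] table (absolute scores).
#' @param groups Named character vector mapping every sample to a group
#'   label; defaults to the groups carried by the expression matrix.
#' @param reference Reference cell-type label (default `"CD45+"`).
#' @param mode `"ratio"` (default, the literal published formula) or
#'   `"log_diff"`.
#' @return An object of class `RelativeAbundanceTable`: list with `values`
#'   (groups x cell types matrix), `mode`, `reference`.
#' @export
relative_abundance <- function(t, groups = NULL, reference = "CD45+",
                               mode = c("ratio", "log_diff")) {
  stopifnot(inherits(t, "CellScoreTable"))
  mode <- match.arg(mode)
  groups <- resolve_groups(t, groups)
  if (!reference %in% colnames(t$scores))
    stop("reference cell type '", reference, "' not in score table")
  glev <- unique(groups)
  gm <- do.call(rbind, lapply(glev, function(g)
    colMeans(t$scores[groups == g, , drop = FALSE])))
  rownames(gm) <- glev
  ref <- gm[, reference]
  if (mode == "ratio" && any(ref == 0))
    stop("group-mean reference score is 0 for group(s) ",
         paste(glev[ref == 0], collapse = ", "), "; ratio undefined")
  values <- if (mode == "ratio") gm / ref else gm - ref
  structure(list(values = values, mode = mode, reference = reference),
            class = "RelativeAbundanceTable")
}

#' @export
print.RelativeAbundanceTable <- function(x, ...) {
  cat(sprintf("RelativeAbundanceTable (%s vs %s):\n", x$mode, x$reference))
  print(round(x$values, 3))
  invisible(x)
}

resolve_groups <- function(t, groups) {
  if (is.null(groups)) groups <- t$groups
  if (is.null(groups))
    stop("no group labels: supply `groups` or attach them to the matrix")
  groups <- stats::setNames(as.character(groups), names(groups))
  samples <- rownames(t$scores)
  if (is.null(names(groups))) {
    if (length(groups) != length(samples))
      stop("`groups` has length ", length(groups), " but there are ",
           length(samples), " samples")
    names(groups) <- samples
  }
  unlabelled <- setdiff(samples, names(groups))
  if (length(unlabelled))
    stop("sample(s) without a group label: ",
         paste(unlabelled, collapse = ", "))
  groups[samples]
}

#' Welch t-tests of cell scores against a baseline group
#'
#' For every cell type and every non-baseline group, a two-sided Welch
#' (unequal-variance) t-test of the per-sample scores against the baseline
#' group. Welch's form is used because compared groups are typically small
#' (n = 6 in the motivating design) with no reason to assume equal
#' variances. The t statistic is signed as `mean(group) - mean(baseline)`.
#' If both groups are constant, the test is decided by convention: equal
#' means give `t = 0, p = 1`; unequal means give `t = +/-Inf, p = 0`.
#'
#' Pass an absolute [cell_scores()] table to compare raw scores, or a
#' [relative_scores()] table to compare infiltration-corrected scores.
#'
#' @param t A `CellScoreTable` (absolute or relative per-sample scores).
#' @param groups Named character vector mapping samples to groups; defaults
#'   to the labels carried by the table.
#' @param baseline_group The reference group label (e.g. `"Surgery Only"`).
#' @param adjust `"none"` (default; raw per-test p-values) or `"BH"` for a
#'   Benjamini-Hochberg adjusted column across all tests.
#' @return A `data.frame` of class `group_comparison` with columns
#'   `cell_type`, `group`, `baseline`, `mean_group`, `mean_baseline`,
#'   `t_statistic`, `df`, `p_value` (and `p_adjusted` when `adjust = "BH"`).
#' @export
compare_groups <- function(t, groups = NULL, baseline_group,
                           adjust = c("none", "BH")) {
  stopifnot(inherits(t, "CellScoreTable"))
  adjust <- match.arg(adjust)
  groups <- resolve_groups(t, groups)
  glev <- unique(groups)
  if (!baseline_group %in% glev)
    stop("baseline group '", baseline_group, "' not among the group labels")
  counts <- table(groups)
  small <- names(counts)[counts < 2]
  if (length(small))
    stop("group(s) with fewer than 2 samples: ",
         paste(small, collapse = ", "))
  others <- setdiff(glev, baseline_group)
  if (!length(others)) stop("no non-baseline group to compare")
  rows <- list()
  for (ct in colnames(t$scores)) {
    base <- t$scores[groups == baseline_group, ct]
    for (g in others) {
      x <- t$scores[groups == g, ct]
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(cell_type = ct, group = g, baseline = baseline_group,
                   stringsAsFactors = FALSE),
        welch_row(x, base))
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  class(out) <- c("group_comparison", "data.frame")
  out
}

welch_row <- function(x, y) {
  dm <- mean(x) - mean(y)
  if (stats::var(x) + stats::var(y) == 0) {
    # degenerate: both groups constant; decided by convention
    return(data.frame(mean_group = mean(x), mean_baseline = mean(y),
                      t_statistic = if (dm == 0) 0 else sign(dm) * Inf,
                      df = length(x) + length(y) - 2,
                      p_value = if (dm == 0) 1 else 0))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  data.frame(mean_group = mean(x), mean_baseline = mean(y),
             t_statistic = unname(tt$statistic),
             df = unname(tt$parameter), p_value = tt$p.value)
}
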