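#' Gene-by-sample expression matrix
#'
#' Container for a genes x samples expression matrix together with the scale
#' the values live on (`"linear"` counts/abundances or `"log2"`), an optional
#' per-gene probe class (endogenous, housekeeping, positive/negative control),
#' and optional sample group labels. All downstream operations (similarity,
#' concordance, scoring) require the `"log2"` scale; raw linear data are
#' transformed with [log2_transform()].
#'
#' Gene symbols and sample identifiers are trimmed and gene symbols
#' uppercased; duplicates (after normalization) are an error.
#'
#' @param values Numeric matrix, genes as rows (rownames = gene symbols),
#'   samples as columns (colnames = sample identifiers).
#' @param scale Either `"linear"` (values must be >= 0) or `"log2"` (values
#'   must be finite).
#' @param gene_class Optional character vector naming, per gene, one of
#'   `"endogenous"`, `"housekeeping"`, `"positive_control"`,
#'   `"negative_control"`. Either named by gene symbol or in row order.
#'   Defaults to all-`"endogenous"`.
#' @param groups Optional character vector of group labels, named by sample
#'   identifier (or in column order).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `scale`, `gene_class`, `groups`.
#' @examples
#' v <- matrix(1:6, nrow = 3, dimnames = list(c("CD19", "CD3E", "PTPRC"),
#'                                            c("s1", "s2")))
#' m <- expression_matrix(v)
#' m
#' @export
expression_matrix <- function(values, scale = c("linear", "log2"),
                              gene_class = NULL, groups = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames (genes) and colnames (samples)")
  rownames(values) <- normalize_symbols(rownames(values))
  colnames(values) <- trimws(colnames(values))
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene symbols: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing")
  if (scale == "linear" && any(values < 0))
    stop("linear-scale expression values must be >= 0")

  gene_class <- resolve_annotation(gene_class, rownames(values),
                                   default = "endogenous", what = "gene_class")
  bad <- setdiff(unique(gene_class), gene_classes())
  if (length(bad))
    stop("unknown gene_class value(s): ", paste(bad, collapse = ", "))
  if (!is.null(groups))
    groups <- resolve_annotation(groups, colnames(values),
                                 default = NULL, what = "groups")

  structure(list(values = values, scale = scale,
                 gene_class = gene_class, groups = groups),
            class = "ExpressionMatrix")
}

gene_classes <- function()
  c("endogenous", "housekeeping", "positive_control", "negative_control")

normalize_symbols <- function(x) toupper(trimws(x))

# Align a per-gene/per-sample annotation vector with the matrix dimnames;
# unnamed vectors are taken in order, named vectors may be a superset.
resolve_annotation <- function(x, ids, default, what) {
  if (is.null(x)) {
    if (is.null(default)) return(NULL)
    x <- rep(default, length(ids))
    names(x) <- ids
    return(x)
  }
  x <- stats::setNames(as.character(x), names(x))
  if (is.null(names(x))) {
    if (length(x) != length(ids))
      stop("`", what, "` has length ", length(x), " but ", length(ids),
           " identifiers are present")
    names(x) <- ids
  } else {
    names(x) <- if (what == "gene_class") normalize_symbols(names(x))
                else trimws(names(x))
    missing <- setdiff(ids, names(x))
    if (length(missing) && !is.null(default)) {
      extra <- rep(default, length(missing))
      names(extra) <- missing
      x <- c(x, extra)
    } else if (length(missing)) {
      stop("`", what, "` is missing label(s) for: ",
           paste(missing, collapse = ", "))
    }
    x <- x[ids]
  }
  x
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  tab <- table(x$gene_class)
  cat("  gene classes:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = ", "), "\n")
  if (!is.null(x$groups)) {
    gt <- table(x$groups)
    cat("  groups:", paste(sprintf("%s(n=%d)", names(gt), gt),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read an expression matrix from delimited text
#'
#' The file must have the gene symbol in the first column, a header row of
#' sample identifiers, and a numeric body. Gene symbols are uppercased and
#' trimmed; duplicates and non-numeric cells are errors (named precisely, so
#' malformed exports fail loudly rather than silently coercing to `NA`).
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (tab-separated, default) or `"csv"`.
#' @param scale Scale the stored values are on; `"linear"` unless declared.
#' @param gene_class,groups Passed to [expression_matrix()].
#' @return An [expression_matrix()] object.
#' @seealso [write_expression()], [read_rcc()]
#' @export
read_expression <- function(path, dialect = c("tsv", "csv"),
                            scale = c("linear", "log2"),
                            gene_class = NULL, groups = NULL) {
  dialect <- match.arg(dialect)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (ncol(raw) < 2)
    stop("expected a gene column plus at least one sample column in ", path)
  genes <- normalize_symbols(raw[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene symbols in ", path, ": ", paste(dup, collapse = ", "))
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = list(genes, colnames(body))))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-numeric value %s at gene '%s' (row %d), sample '%s' in %s",
      dQuote(body[idx[1], idx[2]]), genes[idx[1]], idx[1],
      colnames(body)[idx[2]], path))
  }
  expression_matrix(num, scale = scale, gene_class = gene_class,
                    groups = groups)
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression()]: first column header is `gene`, remaining
#' headers are the sample identifiers.
#'
#' @param m An [expression_matrix()] object.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, dialect = c("tsv", "csv")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(gene = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2-transform a linear-scale expression matrix
#'
#' Replaces each value by `log2(value + offset)` and flips the scale flag to
#' `"log2"`. The default offset of 1 keeps zero counts finite
#' (`log2(0 + 1) = 0`); applying the transform to an already-log2 matrix is
#' an error so data can never be double-transformed silently.
#'
#' @param m An [expression_matrix()] on the linear scale.
#' @param offset Non-negative pseudo-value added before taking logs.
#' @return The transformed `ExpressionMatrix` (scale `"log2"`).
#' @examples
#' v <- matrix(c(0, 3, 1, 7), 2, dimnames = list(c("A", "B"), c("s1", "s2")))
#' log2_transform(expression_matrix(v))$values
#' @export
log2_transform <- function(m, offset = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale == "log2")
    stop("matrix is already on the log2 scale; refusing to double-transform")
  if (!is.numeric(offset) || length(offset) != 1 || offset < 0)
    stop("`offset` must be a single non-negative number")
  if (offset == 0 && any(m$values == 0))
    stop("offset 0 with zero values would produce -Inf; use offset > 0")
  m$values <- log2(m$values + offset)
  m$scale <- "log2"
  m
}

#' Housekeeping (geometric-mean) normalization
#'
#' Scales each sample so housekeeping content is level across samples: sample
#' `s` is multiplied by `mean_s'(geomean_hk(s')) / geomean_hk(s)`, the ratio of
#' the across-sample arithmetic mean of per-sample housekeeping geometric means
#' to that sample's own housekeeping geometric mean. This is the standard
#' content normalization for counting platforms; it is a documented
#' approximation of vendor pipelines, not a parity implementation.
#'
#' @param m A linear-scale [expression_matrix()].
#' @param hk_genes Housekeeping gene symbols; defaults to genes whose
#'   `gene_class` is `"housekeeping"`. All must be present with strictly
#'   positive values.
#' @return The normalized `ExpressionMatrix` (still linear scale).
#' @export
normalize_housekeeping <- function(m, hk_genes = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "linear")
    stop("housekeeping normalization applies to linear-scale values")
  if (is.null(hk_genes)) {
    hk_genes <- names(m$gene_class)[m$gene_class == "housekeeping"]
    if (!length(hk_genes))
      stop("no housekeeping genes: none annotated and `hk_genes` not given")
  }
  hk_genes <- normalize_symbols(hk_genes)
  missing <- setdiff(hk_genes, rownames(m$values))
  if (length(missing))
    stop("housekeeping gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  hk <- m$values[hk_genes, , drop = FALSE]
  if (any(hk <= 0))
    stop("housekeeping genes must be strictly positive in every sample")
  geo <- exp(colMeans(log(hk)))
  m$values <- sweep(m$values, 2, mean(geo) / geo, `*`)
  m
}

#' Background detection threshold from negative-control probes
#'
#' mean + 2 standard deviations of all negative-control probe values, the
#' usual background estimate for counting platforms. Requires at least one
#' gene annotated `"negative_control"`.
#'
#' @param m An [expression_matrix()].
#' @return A single numeric threshold on the scale of `m`.
#' @seealso [detection_filter()]
#' @export
detection_threshold <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  neg <- names(m$gene_class)[m$gene_class == "negative_control"]
  if (!length(neg))
    stop("no negative_control genes annotated; supply `threshold` explicitly")
  vals <- as.vector(m$values[neg, , drop = FALSE])
  mean(vals) + 2 * stats::sd(vals)
}

#' Filter genes below the detection threshold
#'
#' Keeps a gene only if its value exceeds `threshold` in at least
#' `min_fraction` of the samples (boundary inclusive: a gene detected in
#' exactly half the samples passes the default `min_fraction = 0.5`).
#'
#' @param m An [expression_matrix()].
#' @param threshold Detection threshold on the same scale as `m`; if `NULL`,
#'   derived from negative-control probes via [detection_threshold()].
#' @param min_fraction Minimum fraction of samples (in `(0, 1]`) in which a
#'   gene must exceed the threshold.
#' @return A list with `matrix` (the filtered `ExpressionMatrix`) and
#'   `dropped` (character vector of removed genes, for reporting).
#' @export
detection_filter <- function(m, threshold = NULL, min_fraction = 0.5) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!is.numeric(min_fraction) || length(min_fraction) != 1 ||
      min_fraction <= 0 || min_fraction > 1)
    stop("`min_fraction` must be in (0, 1]")
  if (is.null(threshold)) threshold <- detection_threshold(m)
  frac <- rowMeans(m$values > threshold)
  keep <- frac >= min_fraction
  dropped <- rownames(m$values)[!keep]
  if (all(!keep)) stop("detection filter would drop every gene")
  m$values <- m$values[keep, , drop = FALSE]
  m$gene_class <- m$gene_class[rownames(m$values)]
  list(matrix = m, dropped = dropped)
}
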