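#' Slope-penalizing pairwise similarity of two expression vectors
#'
#' An adaptation of Pearson's correlation that penalizes slopes away from 1:
#' \deqn{sim(x, y) = \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}
#'                        {\frac{n-1}{2}\,(var(x) + var(y))}}
#' with `var` the unbiased (n-1) sample variance. Replacing the geometric
#' mean of the variances in Pearson's denominator by their arithmetic mean
#' makes the statistic 1 exactly when `y = x + c` (unit slope), and
#' `2a / (1 + a^2) < 1` for `y = a x + b` with `a != 1`: two ideal marker
#' genes of the same cell type, which track a shared abundance with equal
#' loading, score 1, while genes merely correlated with a different slope
#' score lower. By the AM-GM inequality `|sim(x, y)| <= |cor(x, y)|` always.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` (log2 expression of
#'   two genes across the same samples).
#' @return A single number in `[-1, 1]`. If both vectors are constant
#'   (`var(x) + var(y) = 0`) the similarity is undefined; `0` is returned
#'   with a warning so a flat gene cannot abort a catalog-wide run.
#' @examples
#' x <- c(1, 2, 3, 4)
#' pairwise_similarity(x, x + 2)   # 1: unit slope
#' pairwise_similarity(x, 2 * x)   # 0.8 = 2*2/(1+4)
#' @export
pairwise_similarity <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must have the same length")
  n <- length(x)
  if (n < 3) stop("similarity needs at least 3 samples, got ", n)
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    stop("`x` and `y` must be finite and non-missing")
  vs <- stats::var(x) + stats::var(y)
  if (vs == 0) {
    warning("both vectors are constant; similarity undefined, returning 0")
    return(0)
  }
  sum((x - mean(x)) * (y - mean(y))) / ((n - 1) / 2 * vs)
}

#' Pairwise-similarity matrix over a gene set
#'
#' Computes [pairwise_similarity()] between every pair of the named genes in
#' a log2-scale expression matrix. Zero-variance (constant) genes are flagged
#' as degenerate: their off-diagonal similarities, and their diagonal, are
#' reported as 0 and their symbols are listed in the result, with a warning.
#'
#' @param m A log2-scale [expression_matrix()].
#' @param genes Character vector of `>= 2` gene symbols present in `m`
#'   (defaults to all genes).
#' @return An object of class `SimilarityMatrix`: list with `S` (symmetric
#'   p x p matrix), `genes`, `n_samples`, `degenerate` (character vector of
#'   constant genes).
#' @seealso [mean_pairwise_similarity()], [write_similarity()]
#' @export
similarity_matrix <- function(m, genes = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "log2")
    stop("similarity is computed on log2-scale data; see log2_transform()")
  if (is.null(genes)) genes <- rownames(m$values)
  genes <- normalize_symbols(genes)
  missing <- setdiff(genes, rownames(m$values))
  if (length(missing))
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  if (length(genes) < 2) stop("need at least 2 genes, got ", length(genes))
  X <- m$values[genes, , drop = FALSE]
  n <- ncol(X)
  if (n < 3) stop("similarity needs at least 3 samples, got ", n)
  v <- apply(X, 1, stats::var)
  Xc <- X - rowMeans(X)
  num <- tcrossprod(Xc)                      # sum of cross products
  den <- (n - 1) / 2 * outer(v, v, `+`)
  S <- ifelse(den > 0, num / den, 0)
  diag(S) <- ifelse(v > 0, 1, 0)
  degenerate <- genes[v == 0]
  if (length(degenerate))
    warning("zero-variance gene(s), similarity set to 0: ",
            paste(degenerate, collapse = ", "))
  dimnames(S) <- list(genes, genes)
  structure(list(S = S, genes = genes, n_samples = n,
                 degenerate = degenerate),
            class = "SimilarityMatrix")
}

#' @export
print.SimilarityMatrix <- function(x, ...) {
  cat(sprintf("SimilarityMatrix: %d genes, %d samples\n",
              length(x$genes), x$n_samples))
  off <- x$S[upper.tri(x$S)]
  if (length(off))
    cat(sprintf("  off-diagonal range [%.3f, %.3f], mean %.3f\n",
                min(off), max(off), mean(off)))
  if (length(x$degenerate))
    cat("  degenerate (constant) genes:",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Mean pairwise similarity of a gene subset
#'
#' Arithmetic mean of the off-diagonal upper-triangle similarities among the
#' given genes — the per-cell-type summary reported for a marker set.
#'
#' @param sm A [similarity_matrix()] result.
#' @param genes Subset of `sm$genes` (default: all). A single-gene set has no
#'   pairwise similarity; `NA` is returned with a warning, mirroring blank
#'   report cells for one-gene cell types.
#' @return A single number, or `NA_real_` for fewer than 2 genes.
#' @export
mean_pairwise_similarity <- function(sm, genes = NULL) {
  stopifnot(inherits(sm, "SimilarityMatrix"))
  if (is.null(genes)) genes <- sm$genes
  genes <- normalize_symbols(genes)
  missing <- setdiff(genes, sm$genes)
  if (length(missing))
    stop("gene(s) not in similarity matrix: ",
         paste(missing, collapse = ", "))
  if (length(genes) < 2) {
    warning("mean pairwise similarity undefined for fewer than 2 genes")
    return(NA_real_)
  }
  S <- sm$S[genes, genes]
  mean(S[upper.tri(S)])
}

#' Export a similarity matrix as TSV
#'
#' Square, gene-labelled layout (first column `gene`), suitable for external
#' heat-mapping tools.
#'
#' @param sm A `SimilarityMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sm, path) {
  stopifnot(inherits(sm, "SimilarityMatrix"))
  df <- data.frame(gene = sm$genes, sm$S, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
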