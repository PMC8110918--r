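#' Gene-set concordance statistic
#'
#' For a gene set's log2 expression matrix `X` (p genes x n samples) the
#' concordance is the fraction of total variance captured along the
#' equal-weights direction:
#' \deqn{concordance(X) = \frac{u^T Cov(X)\, u}{trace(Cov(X))},\quad
#'       u = (p^{-1/2}, \ldots, p^{-1/2})}
#' with `Cov(X)` the unbiased p x p sample covariance of the genes across
#' samples. As a Rayleigh quotient of a positive semi-definite matrix at a
#' unit vector, the value lies in `[0, 1]`: it is 1 when all genes are
#' perfectly correlated with slope 1 (all covariance sits on the equal-weights
#' axis) and decays to 0 as that pattern weakens; p mutually uncorrelated
#' equal-variance genes give 1/p in expectation.
#'
#' @param X Numeric matrix, `p >= 2` gene rows by `n >= 3` sample columns, of
#'   log2 expression values.
#' @return A single number in `[0, 1]`; `NA_real_` with a warning if every
#'   gene is constant (`trace(Cov(X)) = 0`).
#' @examples
#' x <- c(1, 3, 2, 5)
#' concordance_statistic(rbind(x, x + 2))        # 1: slope-1 duplicates
#' concordance_statistic(rbind(x, -x))           # 0: anti-correlated
#' @export
concordance_statistic <- function(X) {
  if (!is.matrix(X) || !is.numeric(X)) stop("`X` must be a numeric matrix")
  p <- nrow(X); n <- ncol(X)
  if (p < 2) stop("concordance needs at least 2 genes, got ", p)
  if (n < 3) stop("concordance needs at least 3 samples, got ", n)
  if (anyNA(X) || any(!is.finite(X))) stop("`X` must be finite")
  C <- stats::cov(t(X))
  tr <- sum(diag(C))
  if (tr == 0) {
    warning("all genes constant; concordance undefined, returning NA")
    return(NA_real_)
  }
  # u' C u with u = rep(1/sqrt(p), p) reduces to sum(C) / p
  val <- sum(C) / (p * tr)
  min(max(val, 0), 1)
}

# Fast equivalent used inside permutation loops:
# u' C u = var(colSums(X)) / p and trace(C) = sum of per-gene variances,
# so concordance = var(colSums(X)) / (p * sum(gene_vars)).
concordance_from_rows <- function(X, gene_vars) {
  p <- nrow(X)
  tr <- sum(gene_vars)
  if (tr == 0) return(NA_real_)
  min(max(stats::var(colSums(X)) / (p * tr), 0), 1)
}

#' Permutation p-value for a gene set's concordance
#'
#' Tests the null hypothesis that the gene set shows no more cell-type-like
#' co-expression than a random gene set of the same size: the observed
#' [concordance_statistic()] is compared against `n_permutations` random
#' size-p subsets drawn (without replacement within a draw) from a pool of
#' background genes. The p-value is the proportion of random concordances
#' strictly greater than the observed one, and is therefore a multiple of
#' `1 / n_permutations`; an optional conservative `(r + 1) / (n + 1)`
#' estimator avoids exact zeros.
#'
#' @param m A log2-scale [expression_matrix()].
#' @param genes The gene set to test (`>= 2` symbols present in `m`).
#' @param n_permutations Number of random gene sets (default 1000).
#' @param pool Background gene symbols to draw from; default: all
#'   `"endogenous"` genes of `m`. The tested genes are left in the pool (a
#'   random set of similar size may by chance include them); set
#'   `exclude_tested = TRUE` to remove them.
#' @param seed Integer seed; recorded in the result for audit.
#' @param exclude_tested Remove the tested genes from the pool first.
#' @param conservative Use the `(r + 1) / (n + 1)` estimator.
#' @param cell_type Optional cell-type label stored in the result.
#' @return An object of class `ConcordanceResult`: list with `cell_type`,
#'   `genes`, `concordance`, `p_value`, `n_permutations`, `pool_size`,
#'   `seed`.
#' @seealso [concordance_by_cell_type()]
#' @export
concordance_pvalue <- function(m, genes, n_permutations = 1000, pool = NULL,
                               seed = 1, exclude_tested = FALSE,
                               conservative = FALSE, cell_type = NA_character_) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "log2")
    stop("concordance is computed on log2-scale data; see log2_transform()")
  genes <- normalize_symbols(genes)
  p <- length(genes)
  if (p < 2) stop("gene set must contain at least 2 genes, got ", p)
  missing <- setdiff(genes, rownames(m$values))
  if (length(missing))
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  if (is.null(pool))
    pool <- names(m$gene_class)[m$gene_class == "endogenous"]
  pool <- intersect(normalize_symbols(pool), rownames(m$values))
  if (exclude_tested) pool <- setdiff(pool, genes)
  if (length(pool) < p)
    stop("pool (", length(pool), " genes) smaller than gene set (", p, ")")
  if (n_permutations < 1) stop("`n_permutations` must be >= 1")

  observed <- concordance_statistic(m$values[genes, , drop = FALSE])
  X <- m$values[pool, , drop = FALSE]
  gene_vars <- apply(X, 1, stats::var)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(as.integer(seed))
  null_vals <- vapply(seq_len(n_permutations), function(i) {
    idx <- sample.int(length(pool), p)
    concordance_from_rows(X[idx, , drop = FALSE], gene_vars[idx])
  }, numeric(1))
  r <- sum(null_vals > observed, na.rm = TRUE)
  p_value <- if (conservative) (r + 1) / (n_permutations + 1)
             else r / n_permutations
  structure(list(cell_type = cell_type, genes = genes,
                 concordance = observed, p_value = p_value,
                 n_permutations = as.integer(n_permutations),
                 pool_size = length(pool), seed = as.integer(seed)),
            class = "ConcordanceResult")
}

#' @export
print.ConcordanceResult <- function(x, ...) {
  cat(sprintf(
    "ConcordanceResult%s: %d genes, concordance %.4f, p = %.4g (%d permutations, pool %d, seed %d)\n",
    if (!is.na(x$cell_type)) paste0(" [", x$cell_type, "]") else "",
    length(x$genes), x$concordance, x$p_value, x$n_permutations,
    x$pool_size, x$seed))
  invisible(x)
}

#' Concordance test for every cell type of a catalog
#'
#' Runs [concordance_pvalue()] per catalog entry (restricted to genes present
#' in the matrix) and collects a tidy table. Cell types with fewer than two
#' present genes get an `NA` row: a single gene has no co-expression to test.
#'
#' @inheritParams concordance_pvalue
#' @param catalog A [gene_set_catalog()].
#' @return `data.frame` with columns `cell_type`, `n_genes`, `concordance`,
#'   `p_value`, `n_permutations`, `seed`.
#' @export
concordance_by_cell_type <- function(m, catalog, n_permutations = 1000,
                                     pool = NULL, seed = 1,
                                     exclude_tested = FALSE,
                                     conservative = FALSE) {
  stopifnot(inherits(catalog, "GeneSetCatalog"))
  rows <- lapply(catalog$entries, function(e) {
    present <- intersect(e$genes, rownames(m$values))
    if (length(present) < length(e$genes))
      warning("cell type '", e$name, "': gene(s) absent from matrix: ",
              paste(setdiff(e$genes, present), collapse = ", "))
    if (length(present) < 2)
      return(data.frame(cell_type = e$name, n_genes = length(present),
                        concordance = NA_real_, p_value = NA_real_,
                        n_permutations = as.integer(n_permutations),
                        seed = as.integer(seed), stringsAsFactors = FALSE))
    res <- concordance_pvalue(m, present, n_permutations = n_permutations,
                              pool = pool, seed = seed,
                              exclude_tested = exclude_tested,
                              conservative = conservative,
                              cell_type = e$name)
    data.frame(cell_type = e$name, n_genes = length(present),
               concordance = res$concordance, p_value = res$p_value,
               n_permutations = res$n_permutations, seed = res$seed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
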