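#' Select marker genes per cell type by pairwise-similarity threshold
#'
#' For each cell type of a candidate catalog, computes the pairwise-similarity
#' matrix of its candidate genes on log2 expression data and keeps the genes
#' forming a coherent co-expression block at the given threshold
#' (default 0.6). Two aggregation rules are provided, because a pairwise
#' threshold does not by itself define a per-gene keep/drop decision:
#'
#' \describe{
#'   \item{`prune_mean` (default)}{iteratively remove the candidate with the
#'     lowest mean off-diagonal similarity to the remaining candidates until
#'     every remaining gene's mean similarity is `>= threshold`, or fewer
#'     than two genes remain (then nothing is selected). This matches the
#'     visual reading of a similarity heat map: a coherent high-similarity
#'     block survives, stragglers fall away.}
#'   \item{`all_pairs`}{the largest candidate subset in which *every pair*
#'     has similarity `>= threshold` (a maximum clique in the thresholded
#'     similarity graph); ties are broken by higher mean pairwise similarity,
#'     then lexicographically by gene symbol. Stricter than `prune_mean`.}
#' }
#'
#' Cell types whose candidates are absent from the matrix are flagged
#' `empty` with a warning (not an error). A cell type with a single present
#' candidate passes through unfiltered with status `single_gene`: one gene
#' has no pairwise similarity to assess, and such one-gene definitions
#' (e.g. NK cells via NCR1, CD45+ via PTPRC) are retained but flagged as
#' lower confidence. Selection is fully deterministic.
#'
#' @param m A log2-scale [expression_matrix()].
#' @param catalog A candidate [gene_set_catalog()].
#' @param threshold Pairwise-similarity cutoff in `(0, 1]` (default 0.6).
#' @param mode `"prune_mean"` or `"all_pairs"`.
#' @return An object of class `marker_selection`: list with
#'   \describe{
#'     \item{`results`}{per cell type, a list with `cell_type`, `candidates`,
#'       `selected`, `per_gene_mean_similarity` (mean off-diagonal similarity
#'       of each candidate to the others retained at the point it was kept or
#'       dropped), `set_mean_similarity` (of the selected set; `NA` if fewer
#'       than 2 selected), and `status` in `ok` / `single_gene` / `empty` /
#'       `degenerate`.}
#'     \item{`catalog`}{the derived selected catalog (entries with at least
#'       one selected gene), ready for [cell_scores()].}
#'     \item{`threshold`, `mode`}{the parameters used.}
#'   }
#' @examples
#' sim <- simulate_expression(simulation_config(
#'   n_samples = 40, seed = 7,
#'   cell_blocks = list(list(name = "B cells", n_genes = 5)),
#'   n_noise_genes = 6))
#' cand <- candidate_catalog(sim, decoys_per_type = 6)
#' sel <- select_markers(sim$matrix, cand)
#' sel$results[["B cells"]]$selected
#' @export
select_markers <- function(m, catalog, threshold = 0.6,
                           mode = c("prune_mean", "all_pairs")) {
  stopifnot(inherits(m, "ExpressionMatrix"),
            inherits(catalog, "GeneSetCatalog"))
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1)
    stop("`threshold` must be in (0, 1]")
  if (m$scale != "log2")
    stop("marker selection runs on log2-scale data; see log2_transform()")

  results <- lapply(catalog$entries, function(e)
    select_one(m, e, threshold, mode))
  names(results) <- names(catalog$entries)

  kept <- Filter(function(r) length(r$selected) > 0, results)
  derived <- NULL
  if (length(kept)) {
    entries <- lapply(kept, function(r) {
      e <- catalog$entries[[r$cell_type]]
      keep <- e$genes %in% r$selected
      list(name = e$name, genes = e$genes[keep], parent = e$parent,
           provenance = e$provenance[keep])
    })
    # parents must still exist in the derived catalog
    nm <- vapply(entries, `[[`, "", "name")
    entries <- lapply(entries, function(e) {
      if (!is.na(e$parent) && !(e$parent %in% nm)) e$parent <- NA_character_
      e
    })
    derived <- gene_set_catalog(unname(entries),
                                catalog_name = paste0(catalog$catalog_name,
                                                      "_selected"),
                                version = catalog$version)
  }
  structure(list(results = results, catalog = derived,
                 threshold = threshold, mode = mode),
            class = "marker_selection")
}

select_one <- function(m, entry, threshold, mode) {
  candidates <- entry$genes
  present <- intersect(candidates, rownames(m$values))
  absent <- setdiff(candidates, present)
  if (length(absent))
    warning("cell type '", entry$name, "': candidate(s) absent from matrix: ",
            paste(absent, collapse = ", "))
  res <- list(cell_type = entry$name, candidates = candidates,
              selected = character(0),
              per_gene_mean_similarity = stats::setNames(numeric(0),
                                                         character(0)),
              set_mean_similarity = NA_real_, status = "empty")
  if (!length(present)) return(res)
  if (length(present) == 1) {
    res$selected <- present
    res$status <- "single_gene"
    return(res)
  }
  sm <- suppressWarnings(similarity_matrix(m, present))
  if (length(sm$degenerate) == length(present)) {
    res$status <- "degenerate"
    return(res)
  }
  sel <- switch(mode,
                prune_mean = prune_by_mean(sm$S, threshold),
                all_pairs = best_clique(sm$S, threshold))
  res$per_gene_mean_similarity <- sel$mean_sim
  if (length(sel$genes) >= 2) {
    res$selected <- sel$genes
    res$status <- "ok"
    res$set_mean_similarity <- mean_pairwise_similarity(sm, sel$genes)
  }
  res
}

# Iteratively drop the gene with the lowest mean off-diagonal similarity
# (ties: lexicographically first) until all means >= threshold or < 2 remain.
# Returns the surviving genes plus each gene's mean similarity at the point
# it was dropped or, for survivors, in the final set.
prune_by_mean <- function(S, threshold) {
  active <- rownames(S)
  recorded <- stats::setNames(numeric(0), character(0))
  while (length(active) >= 2) {
    sub <- S[active, active, drop = FALSE]
    means <- (rowSums(sub) - diag(sub)) / (length(active) - 1)
    if (all(means >= threshold)) {
      recorded[active] <- means[active]
      return(list(genes = sort(active), mean_sim = recorded))
    }
    drop <- sort(names(means)[means == min(means)])[1]
    recorded[drop] <- means[drop]
    active <- setdiff(active, drop)
  }
  if (length(active)) recorded[active] <- NA_real_
  list(genes = character(0), mean_sim = recorded)
}

# Largest subset with every pairwise similarity >= threshold: maximum clique
# in the thresholded graph. Among maximum cliques, prefer higher mean
# pairwise similarity, then the lexicographically smallest gene set.
best_clique <- function(S, threshold) {
  genes <- rownames(S)
  adj <- S >= threshold
  diag(adj) <- FALSE
  mean_sim <- stats::setNames(
    (rowSums(S) - diag(S)) / max(1, length(genes) - 1), genes)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cliques <- igraph::largest_cliques(g)
  if (!length(cliques) || length(cliques[[1]]) < 2)
    return(list(genes = character(0), mean_sim = mean_sim))
  sets <- lapply(cliques, function(cl) sort(genes[as.integer(cl)]))
  score <- vapply(sets, function(gs) mean(S[gs, gs][upper.tri(S[gs, gs])]),
                  numeric(1))
  keys <- vapply(sets, paste, "", collapse = "|")
  ord <- order(-score, keys)
  list(genes = sets[[ord[1]]], mean_sim = mean_sim)
}

#' @export
print.marker_selection <- function(x, ...) {
  cat(sprintf("marker_selection: %d cell types, threshold %.2f, mode %s\n",
              length(x$results), x$threshold, x$mode))
  print(selection_report(x), row.names = FALSE)
  invisible(x)
}

#' @export
summary.marker_selection <- function(object, ...) selection_report(object)

#' Tabular summary of a marker selection
#'
#' One row per cell type (candidate count, selected count, selected-set mean
#' similarity, status) plus a `TOTAL` row with unique-gene counts across the
#' whole catalog.
#'
#' @param results A [select_markers()] result (or its `results` list).
#' @return A `data.frame` with columns `cell_type`, `n_candidates`,
#'   `n_selected`, `set_mean_similarity`, `status`.
#' @export
selection_report <- function(results) {
  if (inherits(results, "marker_selection")) results <- results$results
  if (!length(results))
    return(data.frame(cell_type = character(0), n_candidates = integer(0),
                      n_selected = integer(0),
                      set_mean_similarity = numeric(0),
                      status = character(0), stringsAsFactors = FALSE))
  rows <- do.call(rbind, lapply(results, function(r)
    data.frame(cell_type = r$cell_type,
               n_candidates = length(r$candidates),
               n_selected = length(r$selected),
               set_mean_similarity = r$set_mean_similarity,
               status = r$status, stringsAsFactors = FALSE)))
  total <- data.frame(
    cell_type = "TOTAL",
    n_candidates = length(unique(unlist(lapply(results, `[[`,
                                               "candidates")))),
    n_selected = length(unique(unlist(lapply(results, `[[`, "selected")))),
    set_mean_similarity = NA_real_, status = "", stringsAsFactors = FALSE)
  out <- rbind(rows, total)
  rownames(out) <- NULL
  out
}
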