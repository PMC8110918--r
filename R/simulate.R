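#' Configuration for a synthetic expression dataset
#'
#' Describes a block-correlated marker-gene simulation on the log2 scale.
#' Each cell block emulates one immune cell type: a per-sample latent
#' abundance `L[k, s] ~ Normal(group shift, 1)` shared by the block's marker
#' genes, each marker `g` observed as
#' `baseline_g + loading * L[k, s] + Normal(0, noise_sd)`. With equal
#' loadings and vanishing noise, every within-block pairwise similarity is 1
#' (the unit-slope ideal); a gene with loading `a` against a loading-1 gene
#' approaches `2a / (1 + a^2)`. Noise genes are independent Gaussian draws
#' (no latent), housekeeping genes are a constant baseline plus small noise,
#' and optional group effects shift a cell type's latent mean in labelled
#' sample groups.
#'
#' @param n_samples Number of samples (>= 3).
#' @param cell_blocks List of blocks; each a list with `name` (cell-type
#'   label), `n_genes` (>= 1), optional `loading` (scalar or per-gene vector,
#'   default 1), optional `baseline` range `c(lo, hi)` on the log2 scale
#'   (default `c(4, 10)`). May be empty (pure null pool).
#' @param n_noise_genes Number of independent background genes.
#' @param noise_sd Standard deviation (log2 units) of the per-gene additive
#'   noise (>= 0).
#' @param group_effects Optional named list: group label -> named numeric
#'   vector of per-cell-type latent shifts (cell types not named shift by 0).
#'   Samples are split evenly across the groups, in order.
#' @param n_housekeeping Number of housekeeping genes (constant baseline 10
#'   plus `Normal(0, 0.05)` jitter).
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @return An object of class `simulation_config` (validated list).
#' @seealso [simulate_expression()]
#' @export
simulation_config <- function(n_samples = 50, cell_blocks = list(),
                              n_noise_genes = 0, noise_sd = 0.2,
                              group_effects = NULL, n_housekeeping = 0,
                              seed = 1) {
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(n_samples) && n_samples >= 3,
      "n_samples must be >= 3")
  chk(is.numeric(n_noise_genes) && n_noise_genes >= 0,
      "n_noise_genes must be >= 0")
  chk(is.numeric(noise_sd) && length(noise_sd) == 1 && noise_sd >= 0,
      "noise_sd must be a single number >= 0")
  chk(is.numeric(n_housekeeping) && n_housekeeping >= 0,
      "n_housekeeping must be >= 0")
  chk(is.list(cell_blocks), "cell_blocks must be a list")
  if (is.list(cell_blocks)) {
    for (i in seq_along(cell_blocks)) {
      b <- cell_blocks[[i]]
      chk(is.list(b) && !is.null(b$name) && nzchar(b$name),
          sprintf("cell_blocks[[%d]] needs a non-empty name", i))
      chk(!is.null(b$n_genes) && is.numeric(b$n_genes) && b$n_genes >= 1,
          sprintf("cell_blocks[[%d]] needs n_genes >= 1", i))
      if (!is.null(b$loading))
        chk(is.numeric(b$loading) &&
              length(b$loading) %in% c(1L, as.integer(b$n_genes)),
            sprintf("cell_blocks[[%d]]: loading must be scalar or length n_genes",
                    i))
      if (!is.null(b$baseline))
        chk(is.numeric(b$baseline) && length(b$baseline) == 2 &&
              b$baseline[1] <= b$baseline[2],
            sprintf("cell_blocks[[%d]]: baseline must be c(lo, hi)", i))
    }
    nm <- vapply(cell_blocks, function(b) as.character(b$name %||% ""), "")
    chk(!anyDuplicated(nm[nzchar(nm)]), "cell block names must be unique")
  }
  if (!is.null(group_effects)) {
    chk(is.list(group_effects) && length(names(group_effects)) ==
          length(group_effects) && all(nzchar(names(group_effects))),
        "group_effects must be a named list (group -> shifts)")
  }
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
      "seed must be a single integer")
  if (length(problems))
    stop("invalid simulation config:\n  - ",
         paste(problems, collapse = "\n  - "))
  structure(list(n_samples = as.integer(n_samples),
                 cell_blocks = cell_blocks,
                 n_noise_genes = as.integer(n_noise_genes),
                 noise_sd = noise_sd, group_effects = group_effects,
                 n_housekeeping = as.integer(n_housekeeping),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a block-correlated expression dataset
#'
#' Draws the dataset described by a [simulation_config()]: a log2-scale
#' [expression_matrix()] with planted marker blocks, independent noise
#' genes, housekeeping genes, and (if group effects are configured) sample
#' group labels. Marker genes are named `<BLOCKTAG>.M<j>`, noise genes
#' `NOISE.<i>`, housekeeping genes `HK.<i>`; the three sets partition the
#' gene list.
#'
#' @param config A [simulation_config()].
#' @return An object of class `SimulatedDataset`: list with `matrix` (the
#'   `ExpressionMatrix`), `truth` (named list, cell type -> planted marker
#'   genes), `latents` (cell types x samples matrix of latent abundances),
#'   `config`.
#' @examples
#' sim <- simulate_expression(simulation_config(
#'   n_samples = 30, seed = 1,
#'   cell_blocks = list(list(name = "T cells", n_genes = 4)),
#'   n_noise_genes = 10, n_housekeeping = 3))
#' sim$truth
#' @export
simulate_expression <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)
  n <- config$n_samples
  samples <- sprintf("S%02d", seq_len(n))

  groups <- NULL
  if (!is.null(config$group_effects)) {
    glab <- names(config$group_effects)
    # contiguous even split: first samples -> first group
    groups <- stats::setNames(glab[ceiling(seq_len(n) * length(glab) / n)],
                              samples)
  }

  blocks <- config$cell_blocks
  K <- length(blocks)
  latents <- matrix(0, nrow = K, ncol = n,
                    dimnames = list(vapply(blocks, `[[`, "", "name"),
                                    samples))
  truth <- list()
  rows <- list()
  for (k in seq_len(K)) {
    b <- blocks[[k]]
    shift <- rep(0, n)
    if (!is.null(groups)) {
      for (g in names(config$group_effects)) {
        eff <- config$group_effects[[g]]
        if (b$name %in% names(eff))
          shift[groups == g] <- eff[[b$name]]
      }
    }
    latents[k, ] <- stats::rnorm(n, mean = shift, sd = 1)
    p <- as.integer(b$n_genes)
    loading <- rep(b$loading %||% 1, length.out = p)
    rng <- b$baseline %||% c(4, 10)
    baseline <- stats::runif(p, rng[1], rng[2])
    tag <- normalize_symbols(gsub("[^A-Za-z0-9]+", "", b$name))
    gene_names <- sprintf("%s.M%d", tag, seq_len(p))
    block_rows <- baseline + outer(loading, latents[k, ]) +
      matrix(stats::rnorm(p * n, 0, config$noise_sd), p, n)
    dimnames(block_rows) <- list(gene_names, samples)
    rows[[length(rows) + 1L]] <- block_rows
    truth[[b$name]] <- gene_names
  }
  if (config$n_noise_genes > 0) {
    p <- config$n_noise_genes
    noise <- stats::runif(p, 4, 10) +
      matrix(stats::rnorm(p * n, 0, 1), p, n)
    dimnames(noise) <- list(sprintf("NOISE.%d", seq_len(p)), samples)
    rows[[length(rows) + 1L]] <- noise
  }
  hk_names <- character(0)
  if (config$n_housekeeping > 0) {
    p <- config$n_housekeeping
    hk <- matrix(10 + stats::rnorm(p * n, 0, 0.05), p, n)
    hk_names <- sprintf("HK.%d", seq_len(p))
    dimnames(hk) <- list(hk_names, samples)
    rows[[length(rows) + 1L]] <- hk
  }
  if (!length(rows)) stop("config generates no genes")
  values <- do.call(rbind, rows)
  gene_class <- stats::setNames(rep("endogenous", nrow(values)),
                                rownames(values))
  gene_class[hk_names] <- "housekeeping"
  mat <- expression_matrix(values, scale = "log2", gene_class = gene_class,
                           groups = groups)
  structure(list(matrix = mat, truth = truth, latents = latents,
                 config = config),
            class = "SimulatedDataset")
}

#' @export
print.SimulatedDataset <- function(x, ...) {
  cat(sprintf("SimulatedDataset: %d genes x %d samples, %d planted block(s), seed %d\n",
              nrow(x$matrix$values), ncol(x$matrix$values),
              length(x$truth), x$config$seed))
  invisible(x)
}

#' Candidate catalog from a simulated dataset
#'
#' Builds the catalog a marker-selection run would start from: for each
#' planted cell type, its true marker genes plus `decoys_per_type`
#' independent noise genes as false candidates (assigned deterministically,
#' in order, from the dataset's noise genes).
#'
#' @param sim A [simulate_expression()] result.
#' @param decoys_per_type Number of noise genes added to each cell type's
#'   candidate list.
#' @return A [gene_set_catalog()].
#' @export
candidate_catalog <- function(sim, decoys_per_type = 0) {
  stopifnot(inherits(sim, "SimulatedDataset"))
  if (!length(sim$truth)) stop("dataset has no planted cell types")
  noise <- grep("^NOISE\\.", rownames(sim$matrix$values), value = TRUE)
  need <- decoys_per_type * length(sim$truth)
  if (need > length(noise))
    stop("not enough noise genes for ", decoys_per_type,
         " decoys per cell type")
  i <- 0L
  entries <- lapply(names(sim$truth), function(ct) {
    decoys <- if (decoys_per_type > 0) noise[(i + 1L):(i + decoys_per_type)]
              else character(0)
    i <<- i + decoys_per_type
    list(name = ct, genes = c(sim$truth[[ct]], decoys),
         provenance = c(rep("planted", length(sim$truth[[ct]])),
                        rep("decoy", length(decoys))))
  })
  gene_set_catalog(entries, catalog_name = "simulated_candidates",
                   version = as.character(sim$config$seed))
}

#' Named simulation fixtures used across the test suite
#'
#' Four deterministic datasets covering the regimes the toolkit must handle:
#' \describe{
#'   \item{`clean_block`}{one 5-gene unit-loading marker block (noise SD 0.2)
#'     plus 6 decoy noise genes and 4 housekeeping genes over 50 samples —
#'     marker-selection recovery.}
#'   \item{`null_pool`}{500 independent noise genes, no planted block, 50
#'     samples — permutation-test calibration.}
#'   \item{`two_groups`}{three 3-gene cell types over two groups of 6
#'     samples; the latent abundance of `T cells` is shifted up by 2 in the
#'     `TREAT` group — group-comparison sanity.}
#'   \item{`degenerate`}{a 4-gene block plus 20 noise genes, with two genes
#'     (`FLAT.1`, `FLAT.2`) overwritten by constants — degenerate-input
#'     handling.}
#' }
#'
#' @param seed Base seed for the suite (fixture seeds are derived from it);
#'   the default gives the canonical fixtures.
#' @return Named list of [simulate_expression()] datasets.
#' @export
fixture_suite <- function(seed = 101) {
  seed <- as.integer(seed)
  clean_block <- simulate_expression(simulation_config(
    n_samples = 50, seed = seed,
    cell_blocks = list(list(name = "B cells", n_genes = 5, loading = 1)),
    n_noise_genes = 6, noise_sd = 0.2, n_housekeeping = 4))
  null_pool <- simulate_expression(simulation_config(
    n_samples = 50, seed = seed + 1L,
    cell_blocks = list(), n_noise_genes = 500, noise_sd = 0.2))
  two_groups <- simulate_expression(simulation_config(
    n_samples = 12, seed = seed + 2L,
    cell_blocks = list(list(name = "T cells", n_genes = 3),
                       list(name = "B cells", n_genes = 3),
                       list(name = "CD45+", n_genes = 1)),
    n_noise_genes = 20, noise_sd = 0.2,
    group_effects = list(CTRL = c(), TREAT = c("T cells" = 2))))
  degenerate <- simulate_expression(simulation_config(
    n_samples = 20, seed = seed + 3L,
    cell_blocks = list(list(name = "Mast cells", n_genes = 4)),
    n_noise_genes = 20, noise_sd = 0.2))
  flat <- degenerate$matrix$values
  flat <- rbind(flat,
                matrix(c(rep(5, ncol(flat)), rep(7.5, ncol(flat))),
                       nrow = 2, byrow = TRUE,
                       dimnames = list(c("FLAT.1", "FLAT.2"),
                                       colnames(flat))))
  degenerate$matrix <- expression_matrix(
    flat, scale = "log2",
    gene_class = c(degenerate$matrix$gene_class,
                   FLAT.1 = "endogenous", FLAT.2 = "endogenous"))
  list(clean_block = clean_block, null_pool = null_pool,
       two_groups = two_groups, degenerate = degenerate)
}
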