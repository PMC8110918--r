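#' Gene-set catalog of cell-type marker definitions
#'
#' An ordered collection of cell-type definitions, each with a name, a set of
#' candidate (or selected) gene symbols, an optional parent cell type (e.g.
#' "Plasma B cells" is a subtype of "B cells"), and free-text provenance per
#' gene. Cell-type names must be unique, genes unique within an entry, and a
#' parent must name another entry of the same catalog.
#'
#' @param entries A list of entries, each a list with `name` (cell-type
#'   label), `genes` (character vector of symbols), optional `parent`, and
#'   optional `provenance` (character vector parallel to `genes`).
#' @param catalog_name Short label for the catalog.
#' @param version Free-text version tag.
#' @return An object of class `GeneSetCatalog`.
#' @seealso [load_catalog()], [read_catalog()], [write_catalog()]
#' @export
gene_set_catalog <- function(entries, catalog_name = "custom",
                             version = "1") {
  if (!length(entries)) stop("catalog must contain at least one entry")
  entries <- lapply(entries, function(e) {
    if (is.null(e$name) || !nzchar(e$name)) stop("entry without a name")
    e$genes <- normalize_symbols(e$genes)
    if (!length(e$genes)) stop("entry '", e$name, "' has no genes")
    dup <- unique(e$genes[duplicated(e$genes)])
    if (length(dup))
      stop("entry '", e$name, "' lists gene(s) twice: ",
           paste(dup, collapse = ", "))
    if (is.null(e$parent) || !nzchar(e$parent[1]) || is.na(e$parent[1]))
      e$parent <- NA_character_
    if (is.null(e$provenance)) e$provenance <- rep(NA_character_,
                                                   length(e$genes))
    if (length(e$provenance) != length(e$genes))
      stop("entry '", e$name, "': provenance length != gene count")
    e[c("name", "genes", "parent", "provenance")]
  })
  nm <- vapply(entries, `[[`, "", "name")
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("duplicate cell-type name(s): ", paste(dup, collapse = ", "))
  parents <- vapply(entries, `[[`, "", "parent")
  bad <- setdiff(parents[!is.na(parents)], nm)
  if (length(bad))
    stop("parent cell type(s) not in catalog: ", paste(bad, collapse = ", "))
  names(entries) <- nm
  structure(list(entries = entries, catalog_name = catalog_name,
                 version = version),
            class = "GeneSetCatalog")
}

#' @export
print.GeneSetCatalog <- function(x, ...) {
  cat(sprintf("GeneSetCatalog '%s' (version %s): %d cell types, %d unique genes\n",
              x$catalog_name, x$version, length(x$entries),
              length(catalog_genes(x))))
  for (e in x$entries)
    cat(sprintf("  %-32s %2d gene(s)%s\n", e$name, length(e$genes),
                if (!is.na(e$parent)) paste0("  [subtype of ", e$parent, "]")
                else ""))
  invisible(x)
}

#' @export
length.GeneSetCatalog <- function(x) length(x$entries)

#' Unique genes of a catalog
#' @param catalog A `GeneSetCatalog`.
#' @return Character vector of the distinct gene symbols across all entries.
#' @export
catalog_genes <- function(catalog) {
  stopifnot(inherits(catalog, "GeneSetCatalog"))
  unique(unlist(lapply(catalog$entries, `[[`, "genes"), use.names = FALSE))
}

#' Cell-type names of a catalog
#' @param catalog A `GeneSetCatalog`.
#' @return Character vector of entry names, in catalog order.
#' @export
catalog_cell_types <- function(catalog) {
  stopifnot(inherits(catalog, "GeneSetCatalog"))
  names(catalog$entries)
}

#' Catalog as a long data frame
#' @param x A `GeneSetCatalog`.
#' @param ... Unused.
#' @return `data.frame` with columns `cell_type`, `gene`, `provenance`,
#'   `parent` (one row per cell-type/gene pair).
#' @export
as.data.frame.GeneSetCatalog <- function(x, ...) {
  do.call(rbind, lapply(x$entries, function(e)
    data.frame(cell_type = e$name, gene = e$genes,
               provenance = e$provenance, parent = e$parent,
               stringsAsFactors = FALSE, row.names = NULL)))
}

#' Load a bundled marker-gene catalog
#'
#' Three catalogs for pancreatic ductal adenocarcinoma (PDAC) are shipped
#' with the package:
#' \describe{
#'   \item{`pdac_cmg`}{the candidate marker-gene set: 90 unique genes over 23
#'     immune cell types, assembled from a prior pan-cancer marker study
#'     (provenance `previously_used`) and from the wider literature
#'     (`newly_selected`).}
#'   \item{`pdac_mgic`}{the selected PDAC marker genes: the 55 candidates
#'     whose pairwise similarity passed the 0.6 threshold, covering 22 cell
#'     types (Plasmacytoid Dendritic cells retained no genes).}
#'   \item{`nsolver_default`}{the default cell-profiling marker set of the
#'     nSolver Advanced Analysis software, for comparison; provenance records
#'     whether each gene is measured by the PanCancer Immune Profiling panel.}
#' }
#'
#' @param name One of `"pdac_cmg"`, `"pdac_mgic"`, `"nsolver_default"`.
#' @return A [gene_set_catalog()] object.
#' @examples
#' cmg <- load_catalog("pdac_cmg")
#' length(catalog_genes(cmg))
#' @export
load_catalog <- function(name = c("pdac_cmg", "pdac_mgic",
                                  "nsolver_default")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("catalog_", name, ".tsv"),
                      package = "pdacImmune", mustWork = TRUE)
  read_catalog(path, catalog_name = name, version = "bundled")
}

#' Read a catalog from TSV
#'
#' Expected columns: `cell_type`, `gene`, and optionally `provenance` and
#' `parent` (the parent may be given on any row of an entry).
#'
#' @param path Path to a tab-separated catalog file.
#' @param catalog_name,version Metadata stored on the catalog.
#' @return A [gene_set_catalog()] object.
#' @export
read_catalog <- function(path, catalog_name = basename(path), version = "1") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "", fill = TRUE)
  need <- c("cell_type", "gene")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("catalog file lacks column(s): ", paste(missing, collapse = ", "))
  if (!"provenance" %in% colnames(df)) df$provenance <- NA_character_
  if (!"parent" %in% colnames(df)) df$parent <- NA_character_
  entries <- lapply(split(df, factor(df$cell_type,
                                     levels = unique(df$cell_type))),
                    function(d) {
    par <- setdiff(unique(d$parent), c(NA, ""))
    list(name = d$cell_type[1], genes = d$gene,
         parent = if (length(par)) par[1] else NA_character_,
         provenance = ifelse(d$provenance == "", NA, d$provenance))
  })
  gene_set_catalog(unname(entries), catalog_name = catalog_name,
                   version = version)
}

#' Write a catalog to TSV
#'
#' Long format (`cell_type`, `gene`, `provenance`, `parent`), readable back
#' with [read_catalog()].
#'
#' @param catalog A `GeneSetCatalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  df <- as.data.frame(catalog)
  df$parent[is.na(df$parent)] <- ""
  df$provenance[is.na(df$provenance)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
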