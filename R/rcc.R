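#' Read NanoString RCC files into an expression matrix
#'
#' Each RCC file holds the raw probe counts of one sample in a sectioned
#' text format; the `<Code_Summary>` section lists
#' `CodeClass,Name,Accession,Count` per probe. Files are merged by probe name
#' into one linear-scale [expression_matrix()], with `gene_class` mapped from
#' the probe `CodeClass` (Endogenous, Housekeeping, Positive, Negative). All
#' files must share an identical probe panel.
#'
#' @param paths Character vector of RCC file paths (one sample per file).
#' @return A linear-scale `ExpressionMatrix` with `gene_class` populated.
#' @seealso [normalize_housekeeping()], [detection_filter()]
#' @export
read_rcc <- function(paths) {
  if (!length(paths)) stop("no RCC files given")
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("file not found: ", paste(missing, collapse = ", "))
  parsed <- lapply(paths, parse_rcc_file)
  ref <- parsed[[1]]$codes[, c("CodeClass", "Name")]
  for (p in parsed[-1]) {
    other <- p$codes[, c("CodeClass", "Name")]
    if (nrow(other) != nrow(ref) ||
        !identical(ref[order(ref$Name), ], other[order(other$Name), ]))
      stop("inconsistent probe panels: ", p$path,
           " does not match ", parsed[[1]]$path)
  }
  ids <- make.unique(vapply(parsed, `[[`, "", "sample_id"))
  counts <- vapply(parsed, function(p)
    p$codes$Count[match(ref$Name, p$codes$Name)], numeric(nrow(ref)))
  dimnames(counts) <- list(ref$Name, ids)
  class_map <- c(Endogenous = "endogenous", Housekeeping = "housekeeping",
                 Positive = "positive_control", Negative = "negative_control")
  cls <- class_map[ref$CodeClass]
  if (anyNA(cls))
    stop("unknown CodeClass value(s): ",
         paste(unique(ref$CodeClass[is.na(cls)]), collapse = ", "))
  names(cls) <- normalize_symbols(ref$Name)
  expression_matrix(counts, scale = "linear", gene_class = cls)
}

parse_rcc_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  section <- function(tag) {
    open <- grep(paste0("^<", tag, ">$"), lines)
    close <- grep(paste0("^</", tag, ">$"), lines)
    if (length(open) != 1 || length(close) != 1 || close <= open)
      stop("malformed RCC file ", path, ": bad <", tag, "> section")
    lines[(open + 1):(close - 1)]
  }
  attrs <- section("Sample_Attributes")
  id_line <- grep("^ID,", attrs, value = TRUE)
  sample_id <- if (length(id_line)) sub("^ID,", "", id_line[1])
               else sub("\\.rcc$", "", basename(path), ignore.case = TRUE)
  body <- section("Code_Summary")
  fields <- strsplit(body, ",", fixed = TRUE)
  header <- fields[[1]]
  need <- c("CodeClass", "Name", "Count")
  if (!all(need %in% header))
    stop("malformed RCC file ", path,
         ": Code_Summary lacks CodeClass/Name/Count header")
  rows <- fields[-1]
  bad <- which(lengths(rows) != length(header))
  if (length(bad))
    stop("malformed RCC file ", path, ": ragged Code_Summary row ", bad[1])
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  colnames(tab) <- header
  cnt <- suppressWarnings(as.numeric(tab$Count))
  if (anyNA(cnt))
    stop("malformed RCC file ", path, ": non-numeric Count for probe ",
         tab$Name[which(is.na(cnt))[1]])
  tab$Count <- cnt
  list(path = path, sample_id = trimws(sample_id), codes = tab)
}
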