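test_that("expression matrix TSV round-trips and rejects malformed input", {
  v <- matrix(c(1.5, 0, 3, 2, 4.25, 7), nrow = 3,
              dimnames = list(c("cd19 ", "ms4a1", "PTPRC"), c("s1", "s2")))
  m <- expression_matrix(v)
  expect_equal(rownames(m$values), c("CD19", "MS4A1", "PTPRC"))

  path <- tempfile(fileext = ".tsv")
  write_expression(m, path)
  back <- read_expression(path)
  expect_equal(back$values, m$values)
  expect_equal(back$scale, "linear")

  csv <- tempfile(fileext = ".csv")
  write_expression(m, csv, dialect = "csv")
  expect_equal(read_expression(csv, dialect = "csv")$values, m$values)

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "CD19\t1\t2", "CD19\t3\t4"), dup)
  expect_error(read_expression(dup), "duplicate.*CD19")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "CD19\t1\tNA", "CD22\t3\t4"), bad)
  expect_error(read_expression(bad), "CD19.*s2")
})

test_that("constructor enforces scale and dimension invariants", {
  v <- matrix(c(-1, 2, 3, 4), 2,
              dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_error(expression_matrix(v), ">= 0")
  expect_silent(expression_matrix(v, scale = "log2"))
  v2 <- matrix(c(1, 2, Inf, 4), 2,
               dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_error(expression_matrix(v2, scale = "log2"), "finite")
  v3 <- matrix(1:4, 2, dimnames = list(c("A", "A"), c("s1", "s2")))
  expect_error(expression_matrix(v3), "duplicate gene")
})

test_that("log2 transform is correct, guarded, and strictly monotone", {
  v <- matrix(c(0, 3, 1, 7), 2, dimnames = list(c("A", "B"),
                                                c("s1", "s2")))
  m <- log2_transform(expression_matrix(v))
  expect_equal(m$values["A", "s1"], 0)   # log2(0 + 1)
  expect_equal(m$values["A", "s2"], 1)   # log2(1 + 1)
  expect_equal(m$values["B", "s1"], 2)   # log2(3 + 1)
  expect_equal(m$scale, "log2")
  expect_error(log2_transform(m), "already.*log2")

  set.seed(11)
  raw <- matrix(stats::rexp(60), 6,
                dimnames = list(paste0("G", 1:6), paste0("s", 1:10)))
  tr <- log2_transform(expression_matrix(raw))
  for (g in 1:6)
    expect_equal(order(tr$values[g, ]), order(raw[g, ]))
})

test_that("housekeeping normalization levels samples by HK geometric mean", {
  v <- matrix(c(10, 20, 100,
                10, 20, 50,
                10, 20, 200), nrow = 3,
              dimnames = list(c("HK1", "HK2", "GENE"),
                              c("s1", "s2", "s3")))
  m <- expression_matrix(v, gene_class = c(HK1 = "housekeeping",
                                           HK2 = "housekeeping"))
  # constant HK across samples -> unchanged
  expect_equal(normalize_housekeeping(m)$values, m$values)

  # double one sample's HK content -> that sample scaled down accordingly
  v2 <- v
  v2[c("HK1", "HK2"), "s3"] <- c(20, 40)
  m2 <- expression_matrix(v2, gene_class = c(HK1 = "housekeeping",
                                             HK2 = "housekeeping"))
  norm <- normalize_housekeeping(m2)
  geo <- c(sqrt(10 * 20), sqrt(10 * 20), sqrt(20 * 40))
  expect_equal(norm$values["GENE", ], v2["GENE", ] * mean(geo) / geo)

  expect_error(normalize_housekeeping(m, hk_genes = c("HK1", "NOPE")),
               "NOPE")
  v3 <- v; v3["HK1", "s1"] <- 0
  m3 <- expression_matrix(v3)
  expect_error(normalize_housekeeping(m3, hk_genes = c("HK1", "HK2")),
               "positive")
  expect_error(normalize_housekeeping(log2_transform(m), hk_genes = "HK1"),
               "linear")
})

test_that("detection filter keeps boundary cases and is idempotent", {
  v <- rbind(HI = c(9, 9, 9, 9, 9, 9),
             HALF = c(9, 9, 9, 1, 1, 1),
             LOW = c(9, 9, 1, 1, 1, 1))
  colnames(v) <- paste0("s", 1:6)
  m <- expression_matrix(v)
  res <- detection_filter(m, threshold = 5, min_fraction = 0.5)
  # 3 of 6 samples is exactly 50%: boundary inclusive
  expect_setequal(rownames(res$matrix$values), c("HI", "HALF"))
  expect_equal(res$dropped, "LOW")

  again <- detection_filter(res$matrix, threshold = 5, min_fraction = 0.5)
  expect_equal(again$dropped, character(0))
  expect_equal(again$matrix$values, res$matrix$values)

  all_kept <- detection_filter(m, threshold = 0)
  expect_equal(all_kept$dropped, character(0))

  expect_error(detection_filter(m, threshold = 5, min_fraction = 0),
               "min_fraction")
})

test_that("default detection threshold comes from negative controls", {
  v <- rbind(G1 = c(100, 200, 300), NEG1 = c(1, 2, 3), NEG2 = c(2, 3, 4))
  colnames(v) <- paste0("s", 1:3)
  m <- expression_matrix(v, gene_class = c(NEG1 = "negative_control",
                                           NEG2 = "negative_control"))
  neg <- c(1, 2, 3, 2, 3, 4)
  expect_equal(detection_threshold(m), mean(neg) + 2 * sd(neg))
  m2 <- expression_matrix(v)
  expect_error(detection_threshold(m2), "negative_control")
  expect_error(detection_filter(m2), "negative_control")
})

test_that("RCC files merge into a classed expression matrix", {
  panel <- default_rcc_panel()
  set.seed(21)
  paths <- vapply(1:2, function(i) {
    p <- panel
    p$Count <- sample(10:500, nrow(p))
    write_rcc_fixture(tempfile(fileext = ".RCC"), paste0("SAMPLE_", i), p)
  }, "")
  m <- read_rcc(paths)
  expect_equal(dim(m), c(10L, 2L))
  expect_equal(colnames(m$values), c("SAMPLE_1", "SAMPLE_2"))
  expect_equal(unname(m$gene_class["GAPDH"]), "housekeeping")
  expect_equal(unname(m$gene_class["NEG_A"]), "negative_control")
  expect_equal(unname(m$gene_class["POS_A"]), "positive_control")
  expect_equal(unname(m$gene_class["CD19"]), "endogenous")
  expect_equal(m$scale, "linear")

  # mismatched panel -> error
  p3 <- panel[-1, ]; p3$Count <- 5
  bad <- write_rcc_fixture(tempfile(fileext = ".RCC"),
                           "SAMPLE_3", p3)
  expect_error(read_rcc(c(paths, bad)), "panel")

  # malformed section -> error
  mal <- tempfile(fileext = ".RCC")
  writeLines(c("<Header>", "</Header>", "<Code_Summary>"), mal)
  expect_error(read_rcc(mal), "malformed|section")
})

test_that("bundled catalogs match their published summaries", {
  cmg <- load_catalog("pdac_cmg")
  mgic <- load_catalog("pdac_mgic")
  expect_equal(length(catalog_genes(cmg)), 90L)
  expect_equal(length(cmg), 23L)
  expect_equal(length(catalog_genes(mgic)), 55L)
  expect_equal(length(mgic), 22L)
  expect_setequal(mgic$entries[["B cells"]]$genes,
                  c("BLK", "CD19", "CD22", "CR2", "MS4A1"))
  # the one cell type that retained no marker
  expect_false("Plasmacytoid Dendritic cells" %in%
                 catalog_cell_types(mgic))
  expect_error(load_catalog("nope"))

  # every selected set is a subset of the candidate set of the same cell type
  for (ct in catalog_cell_types(mgic))
    expect_true(all(mgic$entries[[ct]]$genes %in%
                      cmg$entries[[ct]]$genes),
                label = paste("selected subset of candidates for", ct))
})

test_that("catalogs round-trip through TSV and validate structure", {
  cat1 <- gene_set_catalog(list(
    list(name = "B cells", genes = c("CD19", "MS4A1")),
    list(name = "Plasma B cells", genes = "CD38", parent = "B cells")))
  path <- tempfile(fileext = ".tsv")
  write_catalog(cat1, path)
  back <- read_catalog(path)
  expect_equal(catalog_cell_types(back), catalog_cell_types(cat1))
  expect_equal(back$entries[["Plasma B cells"]]$parent, "B cells")

  expect_error(gene_set_catalog(list(
    list(name = "A", genes = "X", parent = "MISSING"))), "parent")
  expect_error(gene_set_catalog(list(
    list(name = "A", genes = c("X", "X")))), "twice")
  expect_error(gene_set_catalog(list(
    list(name = "A", genes = "X"),
    list(name = "A", genes = "Y"))), "duplicate")
})
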