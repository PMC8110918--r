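make_score_fixture <- function() {
  rows <- list("CD8A" = c(4, 6, 2, 8), "CD8B" = c(6, 4, 4, 2),
               "PTPRC" = c(10, 8, 4, 5), "NCR1" = c(3, 3, 3, 3))
  m <- toy_log2_matrix(rows)
  catalog <- gene_set_catalog(list(
    list(name = "CD8+ T cells", genes = c("CD8A", "CD8B")),
    list(name = "Natural Killer cells", genes = "NCR1"),
    list(name = "CD45+", genes = "PTPRC")))
  list(m = m, catalog = catalog)
}

test_that("cell scores are per-sample means of marker log2 values", {
  f <- make_score_fixture()
  t <- cell_scores(f$m, f$catalog)
  expect_equal(unname(t$scores[, "CD8+ T cells"]), c(5, 5, 3, 5))
  # single-gene identity
  expect_equal(unname(t$scores[, "CD45+"]), unname(f$m$values["PTPRC", ]))
  expect_equal(unname(t$scores[, "Natural Killer cells"]), rep(3, 4))

  # brute-force oracle on a random 10-gene catalog
  set.seed(14)
  rows <- lapply(1:10, function(i) stats::rnorm(8, mean = 7))
  names(rows) <- sprintf("G%02d", 1:10)
  m <- toy_log2_matrix(rows)
  catalog <- gene_set_catalog(list(
    list(name = "A", genes = names(rows)[1:4]),
    list(name = "B", genes = names(rows)[5:10])))
  t2 <- cell_scores(m, catalog)
  for (s in colnames(m$values)) {
    expect_equal(t2$scores[s, "A"], mean(m$values[1:4, s]))
    expect_equal(t2$scores[s, "B"], mean(m$values[5:10, s]))
  }
  # scores sit within the marker range per sample
  expect_true(all(t2$scores[, "A"] >= apply(m$values[1:4, ], 2, min)))
  expect_true(all(t2$scores[, "A"] <= apply(m$values[1:4, ], 2, max)))
})

test_that("missing marker genes are recorded; empty cell types excluded", {
  f <- make_score_fixture()
  catalog <- gene_set_catalog(list(
    list(name = "CD8+ T cells", genes = c("CD8A", "CD8B", "ABSENT1")),
    list(name = "Ghost", genes = c("ABSENT2", "ABSENT3")),
    list(name = "CD45+", genes = "PTPRC")))
  expect_warning(t <- cell_scores(f$m, catalog), "Ghost")
  expect_false("Ghost" %in% colnames(t$scores))
  expect_equal(t$missing_genes[["CD8+ T cells"]], "ABSENT1")
  # score uses only the present genes
  expect_equal(unname(t$scores[, "CD8+ T cells"]), c(5, 5, 3, 5))
  lin <- expression_matrix(2^f$m$values, scale = "linear")
  expect_error(cell_scores(lin, f$catalog), "log2")
})

test_that("a global additive shift moves every score by the same constant", {
  f <- make_score_fixture()
  t0 <- cell_scores(f$m, f$catalog)
  shifted <- expression_matrix(f$m$values + 1.5, scale = "log2")
  t1 <- cell_scores(shifted, f$catalog)
  expect_equal(t1$scores, t0$scores + 1.5)
})

test_that("relative scores and abundance follow the reference formulas", {
  f <- make_score_fixture()
  t <- cell_scores(f$m, f$catalog)
  rel <- relative_scores(t, reference = "CD45+", mode = "ratio")
  expect_equal(unname(rel$scores[, "CD45+"]), rep(1, 4))
  expect_equal(unname(rel$scores[, "CD8+ T cells"]),
               c(5, 5, 3, 5) / c(10, 8, 4, 5))
  reld <- relative_scores(t, reference = "CD45+", mode = "log_diff")
  expect_equal(unname(reld$scores[, "CD45+"]), rep(0, 4))

  groups <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  ra <- relative_abundance(t, groups, reference = "CD45+", mode = "ratio")
  # spreadsheet oracle: group-mean score / group-mean reference score
  expect_equal(ra$values["A", "CD8+ T cells"], mean(c(5, 5)) / mean(c(10, 8)))
  expect_equal(ra$values["B", "CD8+ T cells"], mean(c(3, 5)) / mean(c(4, 5)))
  expect_equal(unname(ra$values[, "CD45+"]), c(1, 1))
  rad <- relative_abundance(t, groups, reference = "CD45+",
                            mode = "log_diff")
  expect_equal(rad$values["A", "CD8+ T cells"], 5 - 9)
  expect_equal(unname(rad$values[, "CD45+"]), c(0, 0))

  # log_diff is invariant to a global shift; ratio is not
  shifted <- cell_scores(expression_matrix(f$m$values + 2, scale = "log2"),
                         f$catalog)
  expect_equal(relative_abundance(shifted, groups, mode = "log_diff")$values,
               rad$values)
  expect_false(isTRUE(all.equal(
    relative_abundance(shifted, groups, mode = "ratio")$values, ra$values)))

  expect_error(relative_scores(t, reference = "Nope"), "Nope")
  expect_error(relative_abundance(t, groups[1:3]), "s4")
})

test_that("group comparison matches the hand-evaluated Welch formula", {
  rows <- list(MARKER = c(1, 2, 3, 4, 5, 6), PTPRC = rep(1, 6))
  m <- toy_log2_matrix(rows)
  catalog <- gene_set_catalog(list(list(name = "X", genes = "MARKER"),
                                   list(name = "CD45+", genes = "PTPRC")))
  t <- cell_scores(m, catalog)
  groups <- c(s1 = "g1", s2 = "g1", s3 = "g1",
              s4 = "g2", s5 = "g2", s6 = "g2")
  cmp <- compare_groups(t, groups, baseline_group = "g1")
  row <- cmp[cmp$cell_type == "X", ]
  # closed form: means 5 and 2, variances 1 and 1, n = 3 each
  se <- sqrt(1 / 3 + 1 / 3)
  t_hand <- (5 - 2) / se
  df_hand <- (1 / 3 + 1 / 3)^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  p_hand <- 2 * stats::pt(-abs(t_hand), df_hand)
  expect_equal(row$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(row$df, df_hand, tolerance = 1e-12)
  expect_equal(row$p_value, p_hand, tolerance = 1e-12)
  expect_equal(sign(row$t_statistic), sign(row$mean_group - row$mean_baseline))

  # swapping the baseline negates t and preserves p
  cmp2 <- compare_groups(t, groups, baseline_group = "g2")
  row2 <- cmp2[cmp2$cell_type == "X", ]
  expect_equal(row2$t_statistic, -row$t_statistic)
  expect_equal(row2$p_value, row$p_value)

  # constant scores in both groups: t = 0, p = 1 by convention
  ref <- cmp[cmp$cell_type == "CD45+", ]
  expect_equal(ref$t_statistic, 0)
  expect_equal(ref$p_value, 1)
})

test_that("group comparison validates groups and supports BH adjustment", {
  f <- make_score_fixture()
  t <- cell_scores(f$m, f$catalog)
  expect_error(compare_groups(t, c(s1 = "a", s2 = "b", s3 = "b", s4 = "b"),
                              baseline_group = "b"), "a")
  expect_error(compare_groups(t, c(s1 = "a", s2 = "a", s3 = "b", s4 = "b"),
                              baseline_group = "nope"), "nope")

  groups4 <- c(s1 = "base", s2 = "base", s3 = "tx", s4 = "tx")
  cmp <- compare_groups(t, groups4, baseline_group = "base", adjust = "BH")
  expect_true("p_adjusted" %in% colnames(cmp))
  expect_equal(cmp$p_adjusted, stats::p.adjust(cmp$p_value, "BH"))
  # one comparison per cell type per non-baseline group
  expect_equal(nrow(cmp), ncol(t$scores))
})

test_that("planted group effect is detected on the planted cell type", {
  fs <- fixtures()
  sim <- fs$two_groups
  catalog <- gene_set_catalog(lapply(names(sim$truth), function(ct)
    list(name = ct, genes = sim$truth[[ct]])))
  t <- cell_scores(sim$matrix, catalog)
  rel <- relative_scores(t, reference = "CD45+", mode = "ratio")
  cmp <- compare_groups(rel, baseline_group = "CTRL")
  cmp_t <- cmp[cmp$cell_type != "CD45+", ]
  expect_equal(cmp_t$cell_type[which.min(cmp_t$p_value)], "T cells")
  expect_lt(cmp$p_value[cmp$cell_type == "T cells"], 0.05)
})
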