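# Shared fixtures, built once per test run.

fixtures <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fixture_suite()
    cache
  }
})

# Small deterministic log2 matrix with hand-controllable rows.
toy_log2_matrix <- function(rows) {
  values <- do.call(rbind, rows)
  colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  expression_matrix(values, scale = "log2")
}

# Write a minimal NanoString RCC file; `probes` is a data.frame with
# CodeClass, Name, Count columns.
write_rcc_fixture <- function(path, sample_id, probes) {
  lines <- c(
    "<Header>",
    "FileVersion,1.7",
    "SoftwareVersion,4.0.0.3",
    "</Header>",
    "<Sample_Attributes>",
    paste0("ID,", sample_id),
    "Owner,test",
    "</Sample_Attributes>",
    "<Lane_Attributes>",
    "ID,1",
    "</Lane_Attributes>",
    "<Code_Summary>",
    "CodeClass,Name,Accession,Count",
    sprintf("%s,%s,ACC_%s,%s", probes$CodeClass, probes$Name, probes$Name,
            probes$Count),
    "</Code_Summary>"
  )
  writeLines(lines, path)
  path
}

default_rcc_panel <- function() {
  data.frame(
    CodeClass = c(rep("Endogenous", 6), rep("Housekeeping", 2),
                  "Positive", "Negative"),
    Name = c("CD19", "MS4A1", "CD3E", "CD8A", "PTPRC", "FOXP3",
             "GAPDH", "ACTB", "POS_A", "NEG_A"),
    stringsAsFactors = FALSE)
}

# Exhaustive search oracle for the all-pairs selection rule: the largest
# subset in which every pairwise similarity >= threshold, ties broken by
# higher mean pairwise similarity then lexicographic gene order.
all_pairs_oracle <- function(S, threshold) {
  genes <- rownames(S)
  p <- length(genes)
  best <- character(0); best_score <- -Inf
  for (mask in seq_len(2^p - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    if (length(idx) < 2 || length(idx) < length(best)) next
    sub <- S[idx, idx]
    off <- sub[upper.tri(sub)]
    if (any(off < threshold)) next
    cand <- sort(genes[idx])
    score <- mean(off)
    if (length(cand) > length(best) ||
        (length(cand) == length(best) &&
         (score > best_score + 1e-12 ||
          (abs(score - best_score) <= 1e-12 &&
           paste(cand, collapse = "|") < paste(best, collapse = "|"))))) {
      best <- cand; best_score <- score
    }
  }
  best
}
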