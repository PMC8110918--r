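---
title: "Defining and scoring immune-cell marker genes in tumor expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining and scoring immune-cell marker genes in tumor expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdacImmune)
```

## The problem

Bulk expression profiling of tumor tissue mixes signal from cancer cells,
stroma, and infiltrating immune cells. A practical way to read the immune
composition out of such data is through *marker genes*: genes whose
expression is treated as specific to one immune cell type, so that the mean
expression of a cell type's markers tracks that cell type's abundance across
samples. The catch is that marker specificity is tissue-dependent — a gene
that cleanly marks B cells in one tumor type may be expressed by other cells
in another. Before a marker set is trusted in a given tissue, its genes
should be shown to co-vary there the way true markers of a shared cell type
must.

`pdacImmune` implements a complete workflow for this: a co-expression
statistic tailored to the marker assumption, a selection procedure that
prunes candidate genes failing it, a permutation test for whole-set
coherence, and per-sample cell-type scoring with group comparison. It ships
curated catalogs for pancreatic ductal adenocarcinoma (PDAC), where the
workflow was developed, but every step takes an arbitrary catalog and an
arbitrary gene-by-sample matrix.

## The pairwise similarity statistic

If two genes are both clean markers of the same cell type, their log2
expression across samples should differ by roughly a constant: both equal
the cell type's (log) abundance plus a gene-specific offset. Pearson
correlation is too permissive for this — it is 1 for *any* linear
relationship, including slopes far from 1 that arise when one gene also
responds to something else. The package therefore uses a slope-penalizing
variant: for vectors $x, y$ over $n$ samples,

$$ sim(x, y) \;=\; \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}
   {\tfrac{n-1}{2}\,\bigl(\mathrm{var}(x) + \mathrm{var}(y)\bigr)} $$

with the unbiased ($n-1$) sample variance. Compared to Pearson, the
geometric mean of the two variances in the denominator is replaced by their
arithmetic mean. Consequences, all unit-tested:

* $sim(x, x + c) = 1$: equality holds exactly for unit-slope co-expression,
  regardless of the offset.
* $sim(x, a x + b) = 2a / (1 + a^2)$: a slope-2 (or slope-1/2) relationship
  scores 0.8, slope $-1$ scores $-1$.
* $|sim(x, y)| \le |\mathrm{cor}(x, y)|$, with equality iff the variances
  agree (AM–GM): the slope penalty can only shrink the score.

The unbiased variance is used because it makes $sim(x, x) = 1$ an algebraic
identity, which is what the interpretation demands. Vectors shorter than 3
are rejected outright: a two-sample "similarity" is sign noise, and a loud
failure beats a quiet one. A constant gene has no defined similarity; the
package reports 0 for its pairs, flags the gene as degenerate, and warns,
so one flat probe cannot abort a catalog-wide run.

## Marker selection

Candidates for a cell type are filtered on log2-scale data with a pairwise
similarity threshold, 0.6 by default — high enough that surviving sets are
tight unit-slope blocks. A pairwise threshold does not by itself say how
per-gene keep/drop decisions are made, so two explicit rules are provided:

* **`prune_mean`** (default): iteratively remove the candidate with the
  lowest mean off-diagonal similarity until every remaining gene's mean
  similarity is at or above the threshold, or fewer than two genes remain.
  This mirrors how one reads a similarity heat map: the coherent block
  stays, stragglers go.
* **`all_pairs`**: the largest subset in which *every pair* meets the
  threshold — a maximum clique in the thresholded similarity graph, found
  exactly (via `igraph`), with ties broken by higher mean similarity and
  then lexicographically. Stricter, and the two agree on clean single-block
  structure (a property the test suite checks, along with equivalence of
  `all_pairs` to exhaustive subset search for up to 12 candidates).

Both rules are deterministic. Cell types defined by a single candidate pass
through flagged `single_gene` rather than being dropped: one-gene
definitions (NK cells via NCR1, CD45+ via PTPRC) are common in practice and
the right response is a confidence flag, not deletion. Candidates absent
from the matrix are dropped with a warning; a cell type losing all its
candidates is flagged `empty`.

## Set-level concordance and its permutation null

Pairwise similarity judges gene pairs; the concordance statistic judges a
set as a whole. For the set's expression matrix $X$ ($p$ genes × $n$
samples) with covariance $C$,

$$ concordance(X) \;=\; \frac{u^\top C\, u}{\mathrm{trace}(C)},
   \qquad u = (p^{-1/2}, \ldots, p^{-1/2}) $$

the fraction of the set's total variance lying along the equal-weights
direction. A Rayleigh quotient of a PSD matrix at a unit vector, it is
bounded in $[0, 1]$; it is 1 exactly for slope-1 co-expression and about
$1/p$ for independent equal-variance genes. Significance comes from a
permutation null: the observed concordance is compared against 1000 random
gene sets of the same size drawn from a background pool, and the p-value is
the fraction of random sets scoring *strictly higher*. The pool defaults to
all endogenous genes of the matrix (controls and housekeeping excluded);
the tested genes stay in the pool, since the null is "a randomly selected
set of similar size", though `exclude_tested = TRUE` is available. The
plain estimator can return exactly 0 — by construction it is a multiple of
$1/n_{perm}$ — and a conservative $(r+1)/(n+1)$ variant is offered behind a
flag for users who need p-values bounded away from zero.

Inside the permutation loop the quadratic form is evaluated through the
identity $u^\top C u = \mathrm{var}(\mathrm{colSums}(X))/p$, which avoids
building a covariance matrix per draw; a unit test pins this fast path to
the literal `cov()`-based statistic, and a brute-force double-loop oracle
pins both to the definition at $10^{-12}$.

## Scoring, relative abundance, and group comparison

A cell type's score in a sample is the arithmetic mean of its marker genes'
log2 values; a single-gene cell type's score is that gene's value. To
compare immune composition across samples with different total immune
content, scores are reported relative to CD45+ (gene PTPRC, expressed by
all leukocytes). Two modes exist because the published convention —
*dividing* mean log2 expressions — is unusual for log-scale data:

* `ratio` (default): score ÷ reference score, the literal convention;
* `log_diff`: score − reference score, i.e. a log fold change versus
  CD45+, which unlike the ratio is invariant to a global additive shift of
  the log2 data (both behaviors are tested).

The mode is always recorded in the output. Group differences are assessed
with two-sided Welch t-tests of per-sample (relative) scores against a
baseline group — Welch rather than Student because the motivating designs
have groups of six samples with no variance-equality guarantee. Degenerate
inputs are decided by convention rather than error: two constant groups
with equal means give $t = 0, p = 1$. P-values are unadjusted by default,
matching how such per-cell-type comparisons are usually reported; a
Benjamini–Hochberg column is available via `adjust = "BH"`.

## Data handling

Expression matrices are read from TSV/CSV (genes in rows, first column
`gene`), or merged from per-sample NanoString RCC files, whose `CodeClass`
annotations populate the gene-class field. Linear-scale data are
log2-transformed as $\log_2(x + 1)$; the offset is configurable, +1 being
the convention that maps zero to zero and avoids $-\infty$. The transform
refuses to run twice. Housekeeping normalization scales each sample by the
ratio of the across-sample mean of housekeeping geometric means to the
sample's own housekeeping geometric mean — the standard content
normalization for counting platforms, documented as an approximation of
vendor pipelines rather than a parity implementation. The detection filter
keeps genes exceeding a threshold in at least 50% of samples (boundary
inclusive). No published value exists for the threshold itself, so the
default is mean + 2 SD of the negative-control probes when probe classes
are available, and a required explicit value otherwise.

Gene symbols are matched after uppercasing and trimming only; no alias
resolution is attempted. Catalog genes missing from a matrix are reported,
never silently imputed.

## The bundled catalogs

`load_catalog()` provides three PDAC catalogs: `pdac_cmg`, the candidate
set (90 unique genes, 23 cell types) with per-gene provenance
(`previously_used` from a prior pan-cancer marker compendium vs
`newly_selected` from the literature); `pdac_mgic`, the selected PDAC
marker set (55 genes, 22 cell types — Plasmacytoid Dendritic cells retained
no genes); and `nsolver_default`, the default cell-profiling markers of the
nSolver Advanced Analysis software, annotated by whether each gene is
measured on the PanCancer Immune Profiling panel. Eight cell types of
`pdac_mgic` have no counterpart in the default software catalog. Every
selected set is a subset of the corresponding candidate set, an invariant
the test suite enforces.

## The synthetic-data generator

`simulate_expression()` exists so the whole pipeline is testable without
external downloads, and its model is the method's own assumption made
literal: per sample and cell type a latent abundance
$L_{ks} \sim N(\mu_{ks}, 1)$ (group effects shift $\mu$), and marker gene
$g$ of block $k$ observed as $baseline_g + a\,L_{ks} + N(0, \sigma)$ on the
log2 scale. With loading $a = 1$ and $\sigma = 0$ every within-block
similarity is exactly 1; mixed loadings reach the $2a/(1+a^2)$ closed form;
independent noise genes and near-constant housekeeping genes complete the
matrix. Baselines are drawn uniformly from 4–10 log2 units, a typical
detected-expression range. `fixture_suite()` pins four named regimes used
throughout the tests: `clean_block` (one 5-gene unit-loading block, noise
SD 0.2, 50 samples, 6 decoys — the recovery setting, in which selection
achieves precision and recall of at least 0.95 over 100 seeds),
`null_pool` (500 independent genes, 50 samples — under which the
permutation p-values are calibrated: empirical type-I error at
$\alpha = 0.05$ sits inside the binomial 95% band over 200 null sets),
`two_groups` (two groups of six samples, one cell type's latent shifted by
2 — the planted effect is the top hit of the group comparison), and
`degenerate` (constant genes — flagged, never fatal).

What the generator does *not* emulate: count-level noise (negative
binomial), compositional mixing of cell types, cross-loading between cell
types (available explicitly via per-block loadings but off by default), or
batch structure. Passing tests on synthetic data therefore demonstrate
correctness of the statistics and procedures under the model's own
assumptions, not marker validity in any real tissue — that judgment always
requires the similarity/concordance checks on the real dataset at hand.

## Numerical and design notes

* Thresholds are compared inclusively (`>= 0.6`), matching the published
  rule "at least 0.6"; the detection filter's "at least 50% of samples" is
  likewise boundary-inclusive.
* Pruning ties (equal lowest mean similarity) are broken lexicographically
  by gene symbol, making selection fully deterministic.
* All covariance/variance estimators are unbiased ($n-1$), consistently
  across similarity and concordance.
* Permutation RNG is a single seeded generator per call; the seed, pool
  size, and permutation count are recorded in every result object, and the
  caller's RNG state is restored afterwards.
* Problem sizes used by the shipped checks — 50-sample simulations, pools
  of 500 genes, 1000 permutations, 100–200 replicate runs — were chosen as
  the smallest sizes at which the stochastic properties (calibration,
  recovery) are stable; they complete in seconds.

## Worked example

```{r example}
fs <- fixture_suite()
sim <- fs$clean_block
candidates <- candidate_catalog(sim, decoys_per_type = 6)

sel <- select_markers(sim$matrix, candidates, threshold = 0.6)
selection_report(sel)

res <- concordance_pvalue(sim$matrix, sel$results[["B cells"]]$selected,
                          n_permutations = 1000, seed = 42)
res
```

The five planted markers survive selection, the six decoys do not, and the
selected set's concordance is far beyond what random sets of five genes
achieve.

## Limitations

The method estimates *relative* scores for comparing groups of samples; it
does not estimate absolute cell counts, cannot separate cell abundance
from per-cell transcriptional activity, and inherits the marker-gene
assumption that expression is cell-type-exclusive — an assumption
single-cell data show is only approximately true. Single-gene cell types
and sets whose similarity stays below threshold are reported with status
flags precisely because their definitions are weak. The housekeeping
normalization approximates, but does not replicate, vendor pipelines.
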