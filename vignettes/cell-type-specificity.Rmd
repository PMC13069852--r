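---
title: "Scoring cell-type specificity with one-vs-rest AUCs"
author: "aucmarker authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cell-type specificity with one-vs-rest AUCs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aucmarker)
```

## The model

Gene expression across cell types forms a gradient: marker genes peak
in one population and are near-silent elsewhere, preferentially
expressed (DE) genes combine a basal level with enrichment in a few
populations, and ubiquitous genes have the same distribution
everywhere. `aucmarker` places each gene on this gradient with a
one-vs-rest ROC construction. For gene $g$ and cell type $k$ at a
chosen annotation level, and a read-count threshold $t$,

$$\mathrm{TPR}(t) = \Pr(\text{count} > t \mid \text{cell of type } k),
\qquad
\mathrm{FPR}(t) = \Pr(\text{count} > t \mid \text{cell not of type } k),$$

and $\mathrm{AUC}(g,k)$ is the area under the $(\mathrm{FPR},
\mathrm{TPR})$ curve swept over all distinct observed counts (plus a
sentinel below the minimum, anchoring the curve at $(1,1)$; the other
anchor is $(0,0)$). Equivalently, with mid-ranks for ties,

$$\mathrm{AUC}(g,k) = \frac{U}{n_1 n_2}
 = \Pr(X_{\text{in}} > X_{\text{out}}) +
   \tfrac12 \Pr(X_{\text{in}} = X_{\text{out}}),$$

which is what `compute_auc_table()` evaluates. The strictly-greater
threshold predicate together with mid-rank ties makes the trapezoidal
and rank routes coincide exactly; the test suite enforces agreement to
1e-12 on a thousand tie-heavy random instances. An AUC of 0.5 means no
separation, 1 perfect separation; values below 0.5 mean depletion.

Assumptions worth stating:

- **Raw counts.** AUC is rank-based, hence invariant to any per-gene
  monotone transform (log-normalization, CPM scaling per gene change
  nothing), but *not* to per-cell depth scaling, which permutes ranks
  within a gene. The default follows the literal read-count
  definition; `normalize_depth = TRUE` divides by per-cell totals
  first for users who prefer depth-adjusted ranks.
- **One-vs-rest, per level.** Each hierarchy level (class, subclass,
  cluster) is analyzed independently; no pooling across levels.
- **No QC.** Readers perform no cell or gene filtering; the matrix is
  taken as annotated.

## Gene taxonomy and thresholds

Per gene, `auc_max()` takes the row-wise maximum and its argmax type
(ties broken by table order and reported). `classify_genes()` applies
the two defining cutoffs, whose boundary semantics are part of the
contract:

- candidate marker: $\mathrm{AUC_{max}} \ge 0.8$ (exactly 0.8 is a
  marker),
- ubiquitous: $\mathrm{AUC_{max}} < 0.6$ (exactly 0.6 is
  intermediate),
- intermediate (preferential/DE) otherwise.

The 0.8 cutoff is the level at which canonical cortical subclass
markers sit for their own subclass; 0.6 marks the point below which
separation is weak enough to call a gene broadly expressed. Both are
tunable arguments, validated to satisfy
$0 \le \text{ubiquitous} \le \text{marker} \le 1$.

`count_markers_per_type()` counts a gene for every type where its AUC
clears the threshold but once in the distinct total.
`assignment_curve()` reports, per AUC cutoff on a grid over
$[0.5, 1]$, the mean ± SD number of types a gene is assigned to. Two
deliberately exposed choices:

- Genes with zero assignments at a cutoff are excluded from that
  cutoff's mean by default (`zero_policy = "count"` includes them).
  Exclusion keeps the curve interpretable at high cutoffs, where
  counting zeros drives the mean to 0; but note that only the
  "count" variant is guaranteed non-increasing in the cutoff —
  dropping genes that fall to zero can raise the mean of the
  remainder.
- The per-pair rule (gene assigned to every type with AUC ≥ cutoff)
  is the default reading of "assigned to"; an `aucmax_bin` mode that
  groups genes by the bin of their AUC_max is available for the
  alternative reading.

`cluster_celltypes()` clusters cell-type columns on their AUC vectors
over a marker panel with Euclidean distance and average linkage —
conventional, deterministic choices, since nothing in the statistic
dictates a metric.

## Gene-set analysis

`compare_sets_mannwhitney()` compares AUC_max distributions between
two gene sets with a two-sided Mann–Whitney U test (mid-rank ties) and
reports the difference in medians alongside. The p value is exact —
from the null rank distribution — for tie-free samples with
$n_a n_b \le 1000$, and otherwise uses the normal approximation with
tie-corrected variance and a 0.5 continuity correction; the suite
checks exactness against exhaustive enumeration for all tie-free
samples up to $n = 5$ and agreement of the two routes within 0.02 at
8×8. `pairwise_compare()` arranges all pairs into symmetric p and
antisymmetric median-difference matrices with significance stars
(* p < 0.05, ** p < 0.01); raw p values are the default, mirroring
how such heatmaps are usually annotated, with Benjamini–Hochberg
across the upper triangle behind `adjust = "BH"`.

`resample_null()` asks whether a set's AUC_max summary (median by
default, mean optional) is higher than random gene sets of the same
size drawn without replacement from the detected-gene universe
(`detect_genes()`, default: nonzero in ≥ 1 cell — the detection rule
is configurable since reasonable analyses differ here). The empirical
one-sided p uses the add-one rule $(1 + \#\{null \ge obs\})/(B+1)$, so
p is never 0 and the floor is $1/(B+1)$; B defaults to 9,999. For tiny
universes `exhaustive = TRUE` enumerates every subset and returns the
exact fraction. Draws are unmatched on expression; a set-vs-universe
Mann–Whitney (`compare_sets_mannwhitney(target, setdiff)`) is the
directly available alternative. Genes in a set but absent from the AUC
table or undetected are dropped before comparison — the realistic
situation where only part of a curated disease list is detected in a
given atlas.

`constraint_summary()` reports the median LOEUF of a set and the
fraction of matched genes *strictly above* the 0.6 constraint
threshold (LOEUF > 0.6: not intolerant to loss of function);
`cross_dataset_consistency()` runs the per-set two-dataset
Mann–Whitney comparison used to check that specificity profiles
replicate across atlases.

## What the simulator emulates — and what it does not

`simulate_dataset()` draws
$\mathrm{count}(c,g) \sim \mathrm{NB}(\mu = d_c\,\mu_{g,\mathrm{type}(c)},
\ \mathrm{size} = \phi)$ with per-cell depth factors $d_c$ log-uniform
on $[0.5, 2]$ applied multiplicatively to all genes of the cell (so
the depth-normalization flag has something to act on). Role means:
markers 10 in the single target type vs 0.1 elsewhere; DE genes
baseline 1 with fold 4 in 1–3 target types; ubiquitous genes 2
everywhere. Dispersion defaults to size = 1 (strongly overdispersed);
`Inf` gives Poisson. Defaults — 4 types × 200 cells, 10 markers per
type, 40 DE, 100 ubiquitous — are the package's reference study
condition: large enough that planted markers separate cleanly, small
enough that the whole pipeline runs in seconds.

The NB-with-depth model is the minimal structure the rank-based AUC
responds to. It deliberately omits batch effects, doublets, ambient
RNA, gene–gene correlation, zero-inflation beyond NB, and realistic
library-size distributions. Passing the recovery tests (≥ 95% of
planted markers classified as markers with the correct target type,
≤ 5% of ubiquitous genes misclassified) therefore demonstrates the
statistic and its implementation, not performance on any real atlas;
real marker calls depend on annotation quality and sequencing depth in
ways the simulator does not model. `simulate_gene_sets()` and
`simulate_constraint_table()` build role-based gene sets and LOEUF
tables with known expected directions (markers drawn least constrained
by default) so the Fig-3-style comparisons have oracles.

## Numerical choices and degenerate inputs

- Ties everywhere are mid-ranked; a gene constant across all cells
  scores exactly 0.5 for every type.
- Thresholds sweep the distinct observed values strictly-greater,
  plus one sentinel below the minimum.
- Zeros are handled analytically in the sparse path (a gene's zero
  cells share one mid-rank), so cost scales with nonzeros per gene.
- Empty groups, single-label levels, empty gene sets, sets larger
  than the universe, and out-of-range AUC values on read are all
  errors with one-line diagnostics; cells with missing labels at a
  level are dropped from that level with a reported count; gene-set
  members missing from the matrix are reported, not fatal.
- Duplicate gene symbols keep the highest-total-count column (with a
  warning); symbols are matched case-insensitively throughout.
- All randomness (simulation, resampling, subsampled gene sets) flows
  through explicit integer seeds; identical seeds reproduce counts,
  tables and pipeline TSVs byte for byte.

## Problem sizes in the test suite

The suite verifies the rank/trapezoid equivalence on 1,000 random
tie-heavy instances (group sizes ≤ 30), Mann–Whitney exactness by full
enumeration up to $n = 5$ per group, resampling-null calibration over
2,000 repetitions at B = 499 against a 400-gene universe (rejection at
$\alpha = 0.05$ stays ≤ 0.07), and full-pipeline recovery on the
default 800-cell simulation — sizes chosen so the statistics are
well-resolved while the whole suite runs in about a minute.

## Known limitations

AUC compares one type against the pooled rest, so a gene shared by two
sibling types is penalized at fine levels while scoring high at the
parent level — per-level analysis is a feature, but cross-level
synthesis is left to the user. The resampling null is unmatched on
expression level; strongly expression-biased gene sets may warrant a
matched null. No multiple-positive-class ROC, no differential
expression p values, and no plotting are provided; the TSV outputs are
designed to feed standard plotting tools.
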