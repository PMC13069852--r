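# aucmarker

Quantifying the cell-type specificity and sensitivity of genes from
labeled single-cell count data.

## The problem

Single-cell atlases organize brain (and other) cells into hierarchies
of classes, subclasses and clusters. Genes range along a continuum
from **marker genes** (a quasi-categorical peak of expression in one
cell population), through **preferentially/differentially expressed
(DE) genes** (basal expression everywhere plus enrichment in a few
types), to **ubiquitous genes** (the same distribution in every type).
Placing a gene on this continuum matters for interpreting disease gene
sets: a gene set dominated by markers points at specific cellular
vulnerabilities, while a set of broadly expressed genes (as is typical
of autism-associated genes) suggests pleiotropy.

`aucmarker` scores that continuum with a one-vs-rest ROC analysis. For
gene *g* and cell type *k*, sweep a read-count threshold *t*:

- TPR(t) = fraction of type-*k* cells with counts of *g* strictly above *t*
- FPR(t) = fraction of all other cells with counts of *g* above *t*

The area under the resulting ROC curve, **AUC(g, k) ∈ [0, 1]**, is the
probability (ties counted half) that a random type-*k* cell expresses
*g* more highly than a random other cell — computed either by the
trapezoidal rule on the threshold sweep or, equivalently and fast, as
the Mann–Whitney statistic U/(n₁n₂) with mid-ranks. Per gene,
**AUC_max** = max over types, and genes are classified as:

| category     | rule               |
|--------------|--------------------|
| marker       | AUC_max ≥ 0.8      |
| intermediate | 0.6 ≤ AUC_max < 0.8 |
| ubiquitous   | AUC_max < 0.6      |

Downstream, the package compares AUC_max distributions between named
gene sets (two-sided Mann–Whitney U with median differences, pairwise
heatmap matrices, optional BH adjustment), tests a set against a
random-gene resampling null, summarizes loss-of-function constraint
(LOEUF, threshold 0.6), and checks cross-dataset replication. A
negative-binomial simulator with planted marker / DE / ubiquitous
genes makes every stage testable without external atlases.

## Worked example

```r
library(aucmarker)

# 4 types x 200 cells; 10 planted markers per type, 40 DE genes,
# 100 ubiquitous genes, NB dispersion 1, per-cell depth in [0.5, 2]
sim <- simulate_dataset(simulation_config(seed = 1))

tab <- compute_auc_table(sim$counts, sim$annotation, "type")
cls <- classify_genes(tab)
table(cls$category)
#>       marker intermediate   ubiquitous
#>           40           33          107

count_markers_per_type(tab)$per_type
#> T01 T02 T03 T04
#>  10  10  10  10

amax <- setNames(cls$auc_max, cls$gene)
sets <- simulate_gene_sets(sim$truth,
  list(markers = list(roles = "marker"),
       ubiquitous = list(roles = "ubiquitous")))

compare_sets_mannwhitney(amax[sets$markers], amax[sets$ubiquitous],
                         "markers", "ubiquitous")
#>     set_a      set_b n_a n_b u_statistic p_two_sided median_diff
#> 1 markers ubiquitous  40 100        4000    2.89e-20       0.422

resample_null(amax[sets$markers], amax, B = 9999, seed = 1)
#> Resampling null (median, B=9999): observed=0.9463, p=0.0001
```

All 40 planted markers are recovered (10 per type, each with the
correct target type), the marker set's AUC_max median exceeds the
ubiquitous set's by 0.42 with an overwhelming two-sided Mann–Whitney
p, and the marker median of 0.946 beats all 9,999 random gene sets of
the same size (empirical p = 1/10,000, the add-one floor).

A command-line front end wrapping the same functions ships at
`inst/cli/aucmarker` (subcommands `simulate`, `auc`, `classify`,
`compare`, `pipeline`), and `run_pipeline()` executes the whole chain
with a checksum manifest; reruns with the same seed are byte-identical.

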