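# scellintegrate

GSEA-supervised batch integration and lineage annotation for multi-sample
single-cell RNA-seq.

## The problem

Studies of hematopoietic stem/progenitor cells (and comparable
multi-sample scRNA-seq designs) profile the same cell types across many
donors, tissues and developmental stages. Standard batch correction must
walk a line: remove the technical separation between biologically
identical populations without collapsing populations that genuinely exist
in only one sample (e.g. a tissue-restricted progenitor). This package
implements a supervised strategy: cluster correspondence across samples is
established first — from marker-gene enrichment, independent of the
embedding geometry — and then injected into the correction step as a
per-cell prior.

## The method in brief

1. **Per-sample processing.** QC filtering (UMI > 1,000, genes > 500,
   mitochondrial fraction <= 10% by default; genes kept when detected in
   >= 10 cells), library-size normalisation to 10,000 with `log1p`,
   highly-variable-gene selection by a gamma-GLM fit of CV² against
   1/mean, PCA (40 PCs), cosine-kNN/SNN graph (k = 30) and Louvain
   clustering.
2. **Markers.** Per cluster and gene, a Wilcoxon rank-sum test on
   log-normalised expression and a Fisher's exact test on
   expressing-cell frequencies are combined by Fisher's method
   (`X = -2(ln p_w + ln p_f) ~ χ²₄`) and BH-adjusted; markers satisfy
   `|log2FC| >= 1.5`, adjusted `p < 0.05`, expressing frequency `> 0.3`.
3. **Matching.** Every cluster's ranked gene list
   (`log2FC · (-log10 p_adj)`) is scored against every cluster's marker
   set by preranked GSEA (weighted running sum, permutation null). The
   matrix of positive NES is cut by average-linkage hierarchical
   clustering (silhouette-selected k) into meta-clusters; meta-clusters
   spanning one sample are flagged `unique`.
4. **Supervised correction.** Cells get prior probability 0.9 on their
   meta-cluster. A diversity-penalised soft k-means correction
   (cosine soft assignment at temperature σ = 0.1, batch-diversity
   penalty θ = 2, per-cluster ridge removal of batch/donor effects,
   λ = 1) multiplies its assignments by `prior^w`, so a flat prior
   reproduces the unsupervised algorithm exactly.
5. **Annotation and QC of the integration.** Rank-AUC (AUCell-style)
   signature scores classify cells into lineages (argmax score > 0.15);
   kBET acceptance rates and iLISI/cLISI quantify batch mixing versus
   cell-type purity.

A negative-binomial multi-batch simulator with planted types, markers and
batch effects (`simulate_counts()`, `default_benchmark()`) makes every
stage testable without external data.

## Worked example

Two batches share three cell types; a fourth type exists only in batch 2.

```r
library(scellintegrate)

props <- rbind(c(1/3, 1/3, 1/3, 0),
               c(0.25, 0.25, 0.25, 0.25))
sim <- simulate_counts(sim_config(n_batches = 2, n_types = 4,
                                  type_props = props,
                                  cells_per_batch = 800, n_genes = 1000,
                                  markers_per_type = 30, seed = 42))

res <- run_supervised_integration(split_by_sample(sim$counts),
                                  config = list(n_perm = 300, seed = 1))
res$meta
#> MetaClusterMap: 7 sample-clusters -> 4 meta-clusters (3 common, 1 unique)
res$meta$assignment
#>   sample cluster meta
#> 1 batch1       1    1
#> 2 batch1       2    2
#> 3 batch1       3    3
#> 4 batch2       1    1
#> 5 batch2       2    2
#> 6 batch2       3    3
#> 7 batch2       4    4
res$meta$status
#>        1        2        3        4
#> "common" "common" "common" "unique"
```

The three shared types are matched one-to-one across batches and the
batch-2-only type is flagged `unique` — it will keep its own cluster
prior instead of being forced onto a batch-1 population. Batch mixing
improves while type structure is preserved:

```r
batch <- res$merged$sample_of_cell
round(c(before = median(lisi(res$pca, batch)),
        after  = median(lisi(res$corrected, batch))), 3)
#> before  after
#>  1.000  1.711
```

An iLISI of 1 means every neighbourhood is single-batch (no mixing);
after correction the median neighbourhood contains both batches almost
evenly (maximum attainable here is 2). Lineage classification against the
planted signatures recovers the design, including the absence of type T4
from batch 1 (cells failing QC are dropped, hence totals below 800):

```r
calls <- classify_lineage(aucell_score(res$norm,
                                       truth_gene_sets(sim$truth),
                                       seed = 1))
table(calls$label, batch)
#>     batch
#>      batch1 batch2
#>   T1    243    186
#>   T2    234    173
#>   T3    237    179
#>   T4      0    177
```

## Package layout

- `R/` — data model and I/O, preprocessing, SNN/Louvain clustering,
  marker statistics, preranked GSEA, supervised integration, signature
  scoring, integration metrics, simulator, pipeline orchestration
- `tests/testthat/` — unit, property and acceptance tests with
  independent brute-force/closed-form oracles
- `vignettes/supervised-integration.Rmd` — methods, parameter and design
  documentation
- `inst/cli/scellintegrate` — command-line wrapper
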