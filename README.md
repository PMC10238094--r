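# egrnet

Inference of signed enhancer gene-regulatory networks (eGRNs) from
paired single-cell RNA + ATAC (multiome) count matrices, in R.

An eGRN is a transcription factor (TF) together with the enhancer
regions its motif occupies and the genes those enhancers regulate,
linked by signed TF→region→gene edges. `egrnet` implements the full
inference chain:

* joint RNA/ATAC cell QC and cluster-level QC, log-normalization, and
  iterative-overlap consensus peak merging;
* LDA topic modelling of binarized accessibility (collapsed Gibbs in
  C++), topic-number selection by UMass coherence, and topic-imputed
  accessibility `θφ`;
* differentially accessible regions (Wilcoxon + BH at
  `p_adj < 5e-3`, `log2FC > 1.5`) and a pseudo-bulk track contrast
  using a signed base-10 Poisson log-likelihood ratio
  (|LLR| > 1.5, gap ≤ 150 bp, length ≥ 300 bp);
* recovery-curve motif enrichment: per-motif AUC over the top 0.5% of
  the region ranking, NES standardized over the database, enrichment at
  NES > 3, hit calling in the top 5%, and direct/extended TF cistromes;
* gradient-boosted region→gene and TF→gene importances (500 rounds,
  η = 0.01, 90% feature subsampling) with Spearman correlations,
  restricted to a 100 bp–50 kb TSS window;
* sign dichotomization at |ρ| > 0.03, nine-rule edge pruning
  (minimum-variance split, per-gene quantiles 0.75–0.95, top-5/10/15),
  GSEA leading-edge selection on the TF importance ranking, and
  unification into per-(TF, class, sign) eGRNs;
* AUCell activity per cell and per 150×15 pseudo-bulk, eGRN quality
  filtering at |Pearson ρ| > 0.2 with activator/repressor calls, and
  regulon specificity scores `RSS = 1 − sqrt(JSD)`.

Because the full-scale datasets behind this kind of analysis are not
reproducible at desk scale, the package ships a seeded synthetic
multiome generator with planted TF→region→gene structure (activating
and repressing), planted topics and a motif-score database, so every
stage is testable against ground truth.

## Worked example

```r
library(egrnet)

cfg   <- synthetic_config(seed = 1)       # ~2,000 cells, 5 types, 10 TFs
truth <- generate_truth(cfg)
data  <- simulate_multiome(truth, cfg)

res <- run_egrn_pipeline(data, seed = 101)
ev  <- evaluate_egrns(res, truth)
ev[, c("tf", "n_true", "n_predicted", "precision", "recall", "call")]
```

```
     tf n_true n_predicted precision    recall      call
1  tf01     22          26 0.8461538 1.0000000 activator
2  tf02     23          30 0.7333333 0.9565217 activator
3  tf03     23          27 0.8518519 1.0000000 activator
4  tf04     23          24 0.8750000 0.9130435 activator
5  tf05     23          22 0.9545455 0.9130435 activator
6  tf06     28          34 0.7941176 0.9642857 activator
7  tf07     25          37 0.6486486 0.9600000 activator
8  tf08     22          22 0.9090909 0.9090909 activator
9  tf09     26          38 0.6842105 1.0000000 repressor
10 tf10     20          20 0.9500000 0.9500000 repressor
```

The median target-gene precision here is 0.85 and the median recall
0.96 against the planted in-window edges.

Each row compares one planted TF's best-supported recovered eGRN with
the planted in-window edges: `precision` is the fraction of predicted
target genes that are planted targets, `recall` the fraction of
planted targets recovered, and `call` the activator/repressor label
from the pseudo-bulk TF-activity correlation — the two planted
repressors come back labelled `repressor`. `res$rss_gene` holds the
regulon specificity matrix (eGRN × cell type), and
`egrn_edge_list(res$egrns)` serializes the final signed edge lists.

The methods vignette (`vignettes/egrn-inference.Rmd`) documents the
model, every tunable threshold, the generator's assumptions and the
package's numerical conventions.

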