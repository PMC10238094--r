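---
title: "Inferring signed enhancer gene-regulatory networks from paired single-cell multiome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring signed enhancer gene-regulatory networks from paired single-cell multiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egrnet)
```

## The problem

Paired single-cell multiome assays measure, in the same cell, a gene
expression profile (RNA counts) and a chromatin accessibility profile
(ATAC fragment counts over candidate regulatory regions). An enhancer
gene-regulatory network (eGRN) summarizes how a transcription factor
(TF) acts through such regions: it is a TF together with the enhancer
regions its motif occupies and the genes those enhancers regulate,
linked by TF→region→gene edges, each carrying a sign (activating or
repressing). The statistical leverage comes from co-variability across
cells: where a TF is more expressed, the accessibility of its bound
regions and the expression of its target genes shift together.

`egrnet` implements this inference chain end to end, together with a
seeded synthetic multiome generator that plants a known regulatory
structure, so that every stage — and the pipeline as a whole — can be
validated against ground truth at desk scale.

## The inference chain

1. **Quality control** (`filter_cells`, `filter_low_quality_clusters`).
   A cell is retained only if it passes all RNA criteria (≥ 200 detected
   genes, ≤ 15% mitochondrial signal by default) and all ATAC criteria
   (fragment count, ≥ 60% fragments in peaks, TSS enrichment ≥ 2).
   Cluster-level filtering removes clusters whose mean detected-genes
   falls one standard deviation below the global per-cell mean. The
   fragment filter's conventional statement ("minimum number of
   fragments per cell of log10(3.5)") is ambiguous; both readings are
   selectable (`fragment_filter_scale`), the default requiring
   `log10(fragments) ≥ 3.5`.

2. **Consensus peaks** (`standardize_peaks`, `merge_peaks_iterative`).
   Scored summits are standardized to 500 bp and merged greedily: keep
   the best-scoring peak, discard everything overlapping it, repeat.
   Ties resolve by (chrom, start) so the output is deterministic.

3. **Topic modelling** (`fit_lda`, `select_model`,
   `impute_accessibility`). Latent Dirichlet Allocation by collapsed
   Gibbs sampling (implemented in C++) on the binarized region×cell
   matrix, with cisTopic's conventional priors `alpha = 50/T`,
   `beta = 0.1` and 300 sweeps. The model over a grid of topic numbers
   with the best **median UMass coherence** (top-10 regions per topic)
   is selected; "best topic coherence" does not pin down a metric, so
   the metric choice is this package's own and is configurable.
   Imputed accessibility is the cell-topic × topic-region product —
   each cell's denoised accessibility distribution over regions.

4. **Differential accessibility** (`detect_dars`, `pseudobulk_tracks`,
   `diff_tracks`). Per-region two-sided Wilcoxon rank-sum tests with
   Benjamini–Hochberg adjustment; a region passes at `p_adj < 5e-3` and
   `log2FC > 1.5` (fold change on means with a 1e-8 pseudocount).
   Pseudo-bulk tracks are binned aggregates per cell group; the track
   contrast uses a signed base-10 Poisson log-likelihood-ratio per bin
   (a documented simplification of bedGraph-difference callers), with
   |LLR| > 1.5, gaps ≤ 150 bp merged, calls < 300 bp dropped, and a
   "common" set for bins elevated in both tracks (background level:
   10th percentile of nonzero bin means).

5. **Motif enrichment and cistromes** (`motif_enrichment`,
   `build_cistromes`). Region ranking per motif by score; recovery-curve
   AUC over the top 0.5% of the ranking, normalized by the best
   possible curve so AUC ∈ [0, 1]; NES standardized over all motifs in
   the database (sample SD). Motifs with NES > 3 are enriched; hits are
   query regions within the top 5% of the motif's ranking. Direct
   cistromes use motifs annotated to the TF itself; extended cistromes
   add similarity- and orthology-annotated motifs. Merged-consensus
   groups contribute once.

6. **Edge scores** (`candidate_pairs`, `region_gene_scores`,
   `tf_gene_adjacencies`). Candidate region–gene pairs lie within
   100 bp–50 kb of the gene's TSS (distance to the closest covered
   base; a region covering the TSS has distance 0 and is excluded by the
   100 bp minimum — the window is applied literally). Gradient-boosted
   tree ensembles (500 rounds, learning rate 0.01, 90% feature
   subsampling, depth 3 — mirroring the GRNBoost-style presets) predict
   each gene's expression from its candidate regions' imputed
   accessibility, and from all TFs' expression. Importance is the **raw
   summed split gain** of a predictor: raw gain is comparable across
   target genes, which the leading-edge step below depends on;
   per-target normalized shares are available via `normalize = TRUE`.
   Spearman correlations are recorded alongside.

7. **Assembly** (`sign_edges`, `prune_region_gene`,
   `gsea_leading_edge`, `assemble_egrns`). Both edge levels are
   dichotomized at |ρ| > 0.03 (edges with |ρ| ≤ 0.03 are discarded; the
   repressing side is ρ < −0.03). Region→gene edges are pruned per gene
   by nine rules: a deterministic two-cluster minimum-variance split of
   the importance vector (an exhaustively testable stand-in for
   step-function binarization), five per-gene quantile cutoffs
   (0.75–0.95, type-7), and per-gene top-5/10/15. For each TF,
   annotation class and functional category, the pruned edges
   intersected with the cistrome imply a gene set, which is tested by a
   weighted Kolmogorov–Smirnov running sum (weight exponent 1) against
   the TF's importance ranking; only leading-edge genes (members at or
   before the positive maximum) survive, and methods are unioned with
   per-edge provenance.

   One design point deserves emphasis. A repressor's chain is
   TF ⊣ region → gene: the TF *closes* the region, and the gene follows
   the region, so the region–gene correlation of a genuine repressor
   edge is *positive* while the TF–gene correlation is negative. An
   eGRN's functional category is therefore taken from the TF-level
   dichotomization (which is what "activating" and "repressing" mean
   biologically for the TF), while the region–gene sign classes gate
   which edges enter and are kept in the provenance. Labelling eGRNs by
   the region–gene sign alone would make a repressing eGRN
   unconstructible.

8. **Activity, quality filter and specificity** (`aucell`,
   `make_pseudobulks`, `filter_egrns`, `rss`). AUCell ranks a cell's
   features by value and integrates the recovery curve of the eGRN's
   target set. Pseudo-bulks are 150 profiles per cell type, each the
   mean of 15 randomly sampled cells. An eGRN is kept when the absolute
   Pearson correlation between TF expression and eGRN activity across
   pseudo-bulks exceeds 0.2; extended eGRNs are dropped when the
   direct eGRN of the same TF and sign survives; the correlation sign
   is the final activator/repressor call. The regulon specificity score
   is `1 − sqrt(JSD)` between the normalized activity distribution over
   cells and a cell-group indicator (base-2 Jensen–Shannon divergence).

`run_egrn_pipeline()` chains all stages; `evaluate_egrns()` scores the
result against a planted truth.

## The synthetic multiome generator

No generative model is prescribed for this kind of data by the sources
this package follows; every distributional choice here is the package's
own, documented stand-in. The generator (`synthetic_config`,
`generate_truth`, `simulate_multiome`, `write_dataset`) plants:

* a single synthetic chromosome (3 Mb) with 400 gene TSSs at ≥ 3 kb
  spacing and 800 regions of 500 bp;
* 10 TFs (2 repressors), each with 15 target regions anchored near
  sampled gene TSSs; each region links 1–3 genes; about 15% of links
  fall outside the recoverable 100 bp–50 kb window and are flagged
  `out_of_window` — they exercise the window filter and are excluded
  from recall references, since no window-limited method can see them;
* four accessibility topics: each region has a home topic
  (unnormalized weight +40 over Gamma(2,1) noise); each cell draws its
  topic mixture from a Dirichlet (concentration 4) centred on its
  type's mildly tilted mixture. Cell-type tilts are deliberately weak:
  most topic variation is cell-level, so that baseline accessibility
  differences between types stay below the differential-calling fold
  change and the planted regulatory signal is the dominant type-specific
  structure;
* accessibility probability `p = clamp(150 · θφ)`; each planted edge
  shifts `logit(p)` by `weight × standardized log TF expression`
  (weights ±2.5 × U(0.8, 1.2)); ATAC counts are Binomial(2, p),
  matching near-binary sparse fragment counts;
* TF expression is negative binomial with one high cell type per TF
  (mean 50 vs 2, size 5, round-robin over the five types so the rare
  type also hosts TFs); target-gene means are multiplicatively scaled
  by `(p_region / mean p_region)^link_strength`; all gene counts are
  negative binomial;
* motif scores: a TF's motif scores ~Normal(10, 1.5) in its target
  regions and ~Normal(2, 1) elsewhere; 200 decoy motifs score noise
  everywhere; half the TFs also carry a weaker similarity-class motif
  to exercise extended cistromes;
* per-cell QC metrics (FRiP ~ Beta(30, 10), TSS enrichment ~
  Gamma(8, 1.2), total fragments = peak counts / FRiP) are simulated
  directly rather than derived from fragment-level simulation, which is
  out of scope — the QC filters are still exercised end to end.

One global seed expands into fixed per-stage child seeds
(`child_seed`), so each stage is independently reproducible and two
runs of the writer produce byte-identical files.

What the generator does *not* emulate: batch effects, doublets,
sequence-level motif placement, fragment-level coverage structure,
trans-chromosomal layout, and realistic gene–gene co-regulation beyond
the planted edges. Passing the recovery studies therefore shows the
pipeline correctly extracts the kind of signal it models — not that it
is robust to every artefact of real multiome data.

## Pipeline defaults at desk scale

The reference simulation is ~2,000 cells, 5 cell types (one rare, 4%),
400 genes, 800 regions. A few pipeline defaults are adaptations of
genome-scale conventions to this size, set once and documented here:

* **Fragment filter**: simulated libraries carry a few hundred
  fragments per cell, so the pipeline default lowers the log10 fragment
  threshold to 2; all other QC thresholds keep their conventional
  values.
* **Topic grid**: {4, 8, 12} with coherence-based selection. A model
  somewhat larger than the four planted topics gives the imputation
  enough capacity to carry TF-driven accessibility shifts, which the
  region–gene regression needs.
* **Query sets for motif enrichment**: differential regions from
  pairwise cell-type contrasts computed on raw ATAC counts
  (`dar_input = "counts"`; imputed input is selectable). Raw counts
  preserve single-region effects that a small topic model smooths away,
  and pairwise contrasts keep each query small, which keeps the
  recovery-curve enrichment discriminative when the database holds only
  800 regions (integration depth 0.5% = top 4 regions).
* **AUCell depths**: the correlation filter uses pseudo-bulk activity
  at depth 0.2 — at 400 genes the conventional 5% depth (19 genes) is
  smaller than a typical regulon and the AUC degenerates to ~0 for all
  but top-expressed sets; the single-cell activity matrix behind the
  specificity scores keeps the conventional 0.05, whose near-zero
  baseline outside the active population sharpens the specificity
  contrast.
* **Per-TF summary**: among a TF's retained eGRNs, the best-supported
  one (maximal contributing GSEA enrichment score,
  `best_egrns_per_tf`) defines the TF's target set and call. The
  activity-correlation filter alone cannot separate a TF's genuine
  target module from an anti-correlated bystander module (another cell
  type's program), but the enrichment of the gene set in the TF's own
  importance ranking can, and does so cleanly in the recovery studies.

## Numerical choices and degenerate inputs

* Probabilities shifted outside (0, 1) are clamped to
  [1e-6, 1−1e-6] and counted (`n_clamped`), never an error.
* Quantiles are type-7 (linear interpolation); the 1-D split scans all
  cut points between distinct sorted values and prefers the smaller
  low group on exact ties; all-equal importance vectors are unprunable
  by that rule and keep the gene's regions.
* GSEA ranking ties break by gene identifier; an exact magnitude tie
  between the positive and negative extrema of the running sum
  resolves to the positive side.
* AUCell/recovery rankings break ties by feature index
  (deterministic, unlike randomized-tie AUCell builds — a documented
  divergence).
* `log2FC` on imputed probabilities uses a 1e-8 pseudocount.
* Zero-variance targets get zero importances and undefined
  correlations, and are flagged, not dropped silently; a zero-SD motif
  AUC vector (degenerate database) is an error by design.
* Wilcoxon tests use the exact distribution where `stats::wilcox.test`
  does (small samples without ties), otherwise its normal
  approximation.

## Problem sizes used by the validation suite

The test suite and the acceptance script regenerate everything from
code: oracle comparisons run 500 random instances per statistic (1,000
for the 1-D split); the motif study runs 100 seeds of the 10-TF
database with a slim cell budget (the motif stage does not read cells);
topic recovery fits 10 seeds at full scale; the end-to-end study runs
the complete pipeline on one full-scale dataset; the null
differential study permutes labels 20 times over 200 regions. These
sizes were chosen to keep the whole validation reproducible on a single
CPU in well under an hour while leaving each study's verdict stable
across seeds.

## Known limitations

* The topic coherence metric, the generative model, and the LLR track
  contrast are documented stand-ins where the upstream conventions are
  unstated; all are configurable.
* The motif stage consumes precomputed region×motif scores; there is
  no sequence scanning, motif clustering or orthology mapping.
* Rare cell types are handled (pseudo-bulk sampling switches to
  replacement below 15 cells) but regulon specificity for repressors
  is intrinsically aimed away from the TF's home type: a repressor's
  target module is depleted, not enriched, where the TF is expressed,
  so its RSS peaks elsewhere by construction.
* No batch correction, doublet handling, clustering or embedding is
  provided; cluster labels are an input.
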