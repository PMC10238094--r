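#' Quality-control thresholds for paired RNA+ATAC cells
#'
#' Defaults follow the conventional multiome filters: at least 200 detected
#' genes per cell, at most 15\% mitochondrial signal, genes kept when
#' detected in at least 3 cells; on the ATAC side a fragment-count filter,
#' at least 60\% of fragments in the consensus peak set (FRiP) and a TSS
#' enrichment of at least 2.
#'
#' The fragment filter is stated ambiguously in the conventions this
#' follows ("minimum number of fragments per cell of log10(3.5)"); both
#' readings are selectable via `fragment_filter_scale`: `"log10"` (default)
#' requires `log10(total_fragments) >= min_log10_fragments`; `"count"`
#' requires `total_fragments >= min_log10_fragments` taken literally as a
#' count (log10(3.5) ~ 0.54 under that reading).
#'
#' @param min_genes_per_cell minimum detected genes per cell.
#' @param max_mito_fraction maximum fraction of counts from mitochondrial
#'   genes.
#' @param min_cells_per_gene minimum cells a gene must be detected in.
#' @param min_log10_fragments ATAC fragment threshold (see above).
#' @param min_frip minimum fraction of fragments in peaks.
#' @param min_tss_enrichment minimum TSS enrichment score.
#' @param fragment_filter_scale `"log10"` or `"count"`.
#' @param mito_prefixes gene-name prefixes marking mitochondrial genes.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes_per_cell = 200,
                          max_mito_fraction = 0.15,
                          min_cells_per_gene = 3,
                          min_log10_fragments = 3.5,
                          min_frip = 0.60,
                          min_tss_enrichment = 2,
                          fragment_filter_scale = c("log10", "count"),
                          mito_prefixes = c("mt:", "mt-", "MT-")) {
  stopifnot(max_mito_fraction >= 0, max_mito_fraction <= 1,
            min_frip >= 0, min_frip <= 1,
            min_genes_per_cell >= 0, min_cells_per_gene >= 0)
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 max_mito_fraction = max_mito_fraction,
                 min_cells_per_gene = min_cells_per_gene,
                 min_log10_fragments = min_log10_fragments,
                 min_frip = min_frip,
                 min_tss_enrichment = min_tss_enrichment,
                 fragment_filter_scale = match.arg(fragment_filter_scale),
                 mito_prefixes = mito_prefixes),
            class = "qc_thresholds")
}

#' Filter cells on joint RNA and ATAC quality criteria
#'
#' A cell is retained iff it passes every RNA criterion (detected genes,
#' mitochondrial fraction) and every ATAC criterion (fragments, FRiP, TSS
#' enrichment). The report counts, per criterion, how many cells fail it
#' (a cell can fail several).
#'
#' @param dataset an `egrnet_multiome` (or any list with `rna_counts`,
#'   `atac_counts` sharing barcodes and `cell_annotations` carrying
#'   `total_fragments`, `frip`, `tss_enrichment`).
#' @param thresholds a [qc_thresholds()] object.
#' @return list with `cells` (retained barcodes), `report` (data frame of
#'   per-criterion failure counts) and `pass` (named logical).
#' @export
filter_cells <- function(dataset, thresholds = qc_thresholds()) {
  rna <- dataset$rna_counts
  atac <- dataset$atac_counts
  shared <- intersect(colnames(rna), colnames(atac))
  if (length(shared) == 0) stop("input error: RNA and ATAC share no barcodes",
                                call. = FALSE)
  rna <- rna[, shared, drop = FALSE]
  ann <- dataset$cell_annotations
  ann <- ann[match(shared, ann$cell), , drop = FALSE]

  detected <- Matrix::colSums(rna > 0)
  mito <- startsWith_any(rownames(rna), thresholds$mito_prefixes)
  mito_frac <- if (any(mito)) {
    tot <- Matrix::colSums(rna)
    ifelse(tot > 0, Matrix::colSums(rna[mito, , drop = FALSE]) / tot, 0)
  } else rep(0, length(shared))
  frag_ok <- if (thresholds$fragment_filter_scale == "log10") {
    log10(pmax(ann$total_fragments, 1)) >= thresholds$min_log10_fragments
  } else {
    ann$total_fragments >= thresholds$min_log10_fragments
  }
  crit <- cbind(
    min_genes = detected >= thresholds$min_genes_per_cell,
    max_mito = mito_frac <= thresholds$max_mito_fraction,
    min_fragments = frag_ok,
    min_frip = ann$frip >= thresholds$min_frip,
    min_tss_enrichment = ann$tss_enrichment >= thresholds$min_tss_enrichment)
  pass <- apply(crit, 1, all)
  names(pass) <- shared
  report <- data.frame(criterion = colnames(crit),
                       n_failed = colSums(!crit),
                       stringsAsFactors = FALSE)
  list(cells = shared[pass], report = report, pass = pass)
}

startsWith_any <- function(x, prefixes) {
  out <- rep(FALSE, length(x))
  for (p in prefixes) out <- out | startsWith(x, p)
  out
}

#' Drop clusters whose cells have unusually few detected genes
#'
#' Removes clusters whose mean detected-genes-per-cell falls below the
#' global per-cell mean minus one per-cell standard deviation. The
#' reference statistics can instead be computed over cluster means via
#' `stat_over = "clusters"`.
#'
#' @param rna_counts gene x cell count matrix.
#' @param cluster_labels cluster label per cell (same order as columns).
#' @param stat_over compute the global mean/SD over `"cells"` (default) or
#'   over `"clusters"` (i.e. the per-cluster means).
#' @return list with `clusters` (retained labels), `cells` (retained
#'   barcodes) and `table` (per-cluster mean detected genes + decision).
#' @export
filter_low_quality_clusters <- function(rna_counts, cluster_labels,
                                        stat_over = c("cells", "clusters")) {
  stat_over <- match.arg(stat_over)
  stopifnot(length(cluster_labels) == ncol(rna_counts))
  detected <- Matrix::colSums(rna_counts > 0)
  cl_means <- tapply(detected, cluster_labels, mean)
  if (length(cl_means) < 2) {
    warning("single cluster: returned unchanged")
    return(list(clusters = names(cl_means), cells = colnames(rna_counts),
                table = data.frame(cluster = names(cl_means),
                                   mean_detected = as.numeric(cl_means),
                                   removed = FALSE)))
  }
  ref <- if (stat_over == "cells") detected else as.numeric(cl_means)
  cutoff <- mean(ref) - sd(ref)
  removed <- cl_means < cutoff
  keep_cells <- colnames(rna_counts)[!(cluster_labels %in%
                                         names(cl_means)[removed])]
  list(clusters = names(cl_means)[!removed], cells = keep_cells,
       table = data.frame(cluster = names(cl_means),
                          mean_detected = as.numeric(cl_means),
                          removed = as.logical(removed),
                          stringsAsFactors = FALSE),
       cutoff = cutoff)
}

#' Library-size log-normalization of counts
#'
#' Scales each cell to a common target sum, then applies `log1p` (natural
#' log). The target sum of 1e4 is the field's conventional default.
#'
#' @param rna_counts gene x cell non-negative count matrix.
#' @param target_sum per-cell total after scaling.
#' @return dense gene x cell matrix of log-normalized values.
#' @export
lognormalize <- function(rna_counts, target_sum = 1e4) {
  totals <- Matrix::colSums(rna_counts)
  if (any(totals == 0)) stop("all-zero cell reached normalization; ",
                             "apply QC filtering first", call. = FALSE)
  m <- as_dense(rna_counts)
  log1p(sweep(m, 2, totals / target_sum, "/"))
}

#' Iterative-overlap merging of scored fixed-width peaks
#'
#' Greedy consensus construction: repeatedly keep the highest-scoring
#' remaining peak and discard every peak overlapping it by >= 1 bp, until
#' no peaks remain. Ties in score are broken by (chrom, start) order so
#' the result is deterministic. Output is sorted and pairwise
#' non-overlapping; the `name` column gives the selection rank.
#'
#' @param peaks data frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `score`.
#' @param blacklist optional data frame of intervals (`chrom`, `start`,
#'   `end`); peaks overlapping any are dropped first.
#' @return data frame of retained peaks sorted by (chrom, start), with a
#'   `name` rank column.
#' @export
merge_peaks_iterative <- function(peaks, blacklist = NULL) {
  if (is.null(peaks) || nrow(peaks) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), score = numeric(),
                      name = character(), stringsAsFactors = FALSE))
  }
  stopifnot(all(is.finite(peaks$score)), all(peaks$start >= 0),
            all(peaks$end > peaks$start))
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    bad <- vapply(seq_len(nrow(peaks)), function(i) {
      any(blacklist$chrom == peaks$chrom[i] &
            blacklist$start < peaks$end[i] &
            blacklist$end > peaks$start[i])
    }, logical(1))
    peaks <- peaks[!bad, , drop = FALSE]
  }
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  peaks <- peaks[ord, , drop = FALSE]
  kept <- logical(nrow(peaks))
  alive <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!alive[i]) next
    kept[i] <- TRUE
    overlap <- alive & peaks$chrom == peaks$chrom[i] &
      peaks$start < peaks$end[i] & peaks$end > peaks$start[i]
    alive[overlap] <- FALSE
  }
  out <- peaks[kept, , drop = FALSE]
  out$name <- paste0("peak_", seq_len(nrow(out)))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standardize summits to fixed-width scored peaks
#'
#' @param summits data frame with `chrom`, `pos` (0-based summit) and
#'   `score`.
#' @param width peak width (bp), centred on the summit.
#' @return data frame with `chrom`, `start`, `end`, `score`.
#' @export
standardize_peaks <- function(summits, width = 500L) {
  half <- width %/% 2L
  data.frame(chrom = summits$chrom,
             start = pmax(0, summits$pos - half),
             end = pmax(0, summits$pos - half) + width,
             score = summits$score, stringsAsFactors = FALSE)
}
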