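test_that("cell filtering applies every threshold jointly", {
  d <- small_dataset(seed = 7)
  ds <- d$data

  # vacuous thresholds retain every cell
  lax <- qc_thresholds(min_genes_per_cell = 0, max_mito_fraction = 1,
                       min_cells_per_gene = 0, min_log10_fragments = 0,
                       min_frip = 0, min_tss_enrichment = 0)
  expect_length(filter_cells(ds, lax)$cells, ncol(ds$rna_counts))

  # a cell one gene short of the detected-genes threshold is removed
  detected <- Matrix::colSums(ds$rna_counts > 0)
  thr <- qc_thresholds(min_genes_per_cell = detected[1] + 1,
                       max_mito_fraction = 1, min_log10_fragments = 0,
                       min_frip = 0, min_tss_enrichment = 0)
  res <- filter_cells(ds, thr)
  expect_false(colnames(ds$rna_counts)[1] %in% res$cells)

  # planted QC outliers are counted under the right criterion
  ds2 <- ds
  bad <- colnames(ds2$rna_counts)[1:10]
  ds2$cell_annotations$frip[match(bad, ds2$cell_annotations$cell)] <- 0.1
  res2 <- filter_cells(ds2, qc_thresholds(min_genes_per_cell = 0,
                                          min_log10_fragments = 0,
                                          min_frip = 0.3,
                                          min_tss_enrichment = 0))
  expect_equal(res2$report$n_failed[res2$report$criterion == "min_frip"], 10)
  expect_true(all(!(bad %in% res2$cells)))

  # idempotence: filtering the filtered dataset removes nothing
  keep <- res2$cells
  ds3 <- ds2
  ds3$rna_counts <- ds2$rna_counts[, keep]
  ds3$atac_counts <- ds2$atac_counts[, keep]
  ds3$cell_annotations <- ds2$cell_annotations[
    ds2$cell_annotations$cell %in% keep, ]
  res3 <- filter_cells(ds3, qc_thresholds(min_genes_per_cell = 0,
                                          min_log10_fragments = 0,
                                          min_frip = 0.3,
                                          min_tss_enrichment = 0))
  expect_setequal(res3$cells, keep)

  # disjoint barcodes are an input error
  ds4 <- ds
  colnames(ds4$rna_counts) <- paste0("x", colnames(ds4$rna_counts))
  expect_error(filter_cells(ds4), "barcodes")
})

test_that("low-quality cluster filter drops clusters 1 SD below the mean", {
  set.seed(1)
  # three clusters with planted depths: high, high, very low
  n_genes <- 200
  mk <- function(n, depth) {
    matrix(rbinom(n_genes * n, 1, depth), n_genes, n)
  }
  counts <- cbind(mk(50, 0.5), mk(50, 0.55), mk(30, 0.05))
  colnames(counts) <- paste0("c", seq_len(ncol(counts)))
  labels <- rep(c("A", "B", "C"), c(50, 50, 30))

  res <- filter_low_quality_clusters(counts, labels)
  # hand computation of the rule on per-cell detected genes
  detected <- colSums(counts > 0)
  cutoff <- mean(detected) - sd(detected)
  expected_removed <- names(which(tapply(detected, labels, mean) < cutoff))
  expect_setequal(setdiff(c("A", "B", "C"), res$clusters), expected_removed)
  expect_true("C" %in% expected_removed)

  # label permutation leaves the removed cell set unchanged
  perm <- c(A = "z2", B = "z3", C = "z1")
  res_p <- filter_low_quality_clusters(counts, unname(perm[labels]))
  expect_setequal(res_p$cells, res$cells)

  # equal-depth clusters: nothing removed
  eq <- cbind(mk(40, 0.5), mk(40, 0.5))
  colnames(eq) <- paste0("e", seq_len(80))
  res_eq <- filter_low_quality_clusters(eq, rep(c("A", "B"), each = 40))
  expect_setequal(res_eq$clusters, c("A", "B"))

  # single cluster returned unchanged with a warning
  expect_warning(one <- filter_low_quality_clusters(eq, rep("A", 80)),
                 "single cluster")
  expect_equal(one$clusters, "A")
})

test_that("log-normalization matches its closed form and oracle", {
  set.seed(2)
  m <- matrix(rpois(50 * 8, 5), 50, 8,
              dimnames = list(paste0("g", 1:50), paste0("c", 1:8)))
  m[, 1] <- 0
  m[3, 1] <- 7  # single nonzero gene in cell 1
  norm <- lognormalize(m)
  expect_equal(norm[3, 1], log1p(1e4))

  # doubling a cell's counts changes nothing
  m2 <- m
  m2[, 2] <- m[, 2] * 2
  expect_equal(lognormalize(m2)[, 2], norm[, 2])

  # entrywise equality with a two-line reimplementation
  oracle <- log1p(sweep(m, 2, colSums(m), "/") * 1e4)
  expect_equal(norm, oracle, tolerance = 1e-12)

  # back-transform conservation
  expect_equal(unname(colSums(expm1(norm))), rep(1e4, 8), tolerance = 1e-6)

  expect_error(lognormalize(cbind(m[, 1] * 0)), "all-zero")
})

test_that("iterative peak merging follows the greedy score rule", {
  pk <- data.frame(chrom = "chr1",
                   start = c(0, 200, 800), end = c(500, 700, 1300),
                   score = c(10, 8, 5))
  out <- merge_peaks_iterative(pk)
  expect_equal(out$start, c(0, 800))
  expect_equal(out$end, c(500, 1300))

  # non-overlapping input returns unchanged (sorted)
  pk2 <- data.frame(chrom = "chr1", start = c(1000, 0), end = c(1500, 500),
                    score = c(1, 2))
  out2 <- merge_peaks_iterative(pk2)
  expect_equal(out2$start, c(0, 1000))

  # identical intervals: higher score wins
  pk3 <- data.frame(chrom = "chr1", start = c(0, 0), end = c(500, 500),
                    score = c(3, 9))
  out3 <- merge_peaks_iterative(pk3)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$score, 9)

  # output is always pairwise non-overlapping (random property check)
  set.seed(4)
  for (i in 1:20) {
    n <- 40
    rp <- standardize_peaks(data.frame(
      chrom = sample(c("chr1", "chr2"), n, TRUE),
      pos = sample(5000, n), score = runif(n)))
    res <- merge_peaks_iterative(rp)
    by_chr <- split(res, res$chrom)
    for (b in by_chr) {
      if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
    }
  }

  # empty input gives empty output
  expect_equal(nrow(merge_peaks_iterative(pk[0, ])), 0)

  # blacklist removes overlapping peaks up front
  out_bl <- merge_peaks_iterative(pk, blacklist = data.frame(
    chrom = "chr1", start = 900, end = 1000))
  expect_equal(out_bl$start, 0)
})
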