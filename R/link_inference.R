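#' Candidate region-gene pairs within a TSS-distance window
#'
#' Pairs every region with every gene whose TSS lies within
#' \[`min_dist`, `max_dist`\] base pairs of the region. Distance is taken
#' from the closest covered base of the 0-based half-open region to the
#' TSS point (0 when the region covers the TSS), strand-independent.
#' Genes missing from the TSS table are skipped with a message.
#'
#' @param regions data frame with `region`, `chrom`, `start`, `end`.
#' @param tss_table data frame with `gene`, `chrom`, `position`.
#' @param min_dist,max_dist window bounds in bp (defaults 100 and 50000).
#' @return data frame (`region`, `gene`, `distance`) ordered by gene then
#'   distance.
#' @export
candidate_pairs <- function(regions, tss_table, min_dist = 100,
                            max_dist = 50000) {
  bad <- is.na(tss_table$position)
  if (any(bad)) {
    message(sum(bad), " genes without TSS entry excluded")
    tss_table <- tss_table[!bad, , drop = FALSE]
  }
  out <- lapply(seq_len(nrow(tss_table)), function(i) {
    same <- regions$chrom == tss_table$chrom[i]
    d <- region_gene_distance(regions$start, regions$end,
                              tss_table$position[i])
    keep <- same & d >= min_dist & d <= max_dist
    if (!any(keep)) return(NULL)
    data.frame(region = regions$region[keep], gene = tss_table$gene[i],
               distance = d[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(region = character(), gene = character(),
                      distance = numeric()))
  }
  out <- out[order(out$gene, out$distance, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# arboreto-like gradient-boosting preset: 500 rounds, eta 0.01, 90% of
# features sampled per tree, shallow trees; single thread + fixed seed for
# determinism. Histogram splits with 64 bins: plenty for probability- and
# log-scale inputs, and much faster than exact splits at these sizes.
gbm_params <- function(colsample = 0.9, max_depth = 3, eta = 0.01) {
  list(objective = "reg:squarederror", max_depth = max_depth, eta = eta,
       colsample_bytree = colsample, tree_method = "hist", max_bin = 64,
       nthread = 1)
}

# split-gain importance for one regression target: the summed gain of
# every split using each predictor (raw, comparable across targets, as in
# GRNBoost-style adjacency scoring); `normalize` rescales to shares
# summing to 1. All zeros for a zero-variance target.
boosted_importance <- function(X, y, seed, nrounds = 500,
                               params = gbm_params(), normalize = FALSE) {
  imp <- setNames(rep(0, ncol(X)), colnames(X))
  if (sd(y) == 0 || ncol(X) == 0) return(imp)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  set.seed(seed)
  fit <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = nrounds, verbose = 0)
  tree <- xgboost::xgb.model.dt.tree(model = fit)
  tree <- tree[tree$Feature != "Leaf", , drop = FALSE]
  if (nrow(tree) > 0) {
    gain <- tapply(tree$Gain, tree$Feature, sum)
    imp[names(gain)] <- as.numeric(gain)
  }
  if (normalize && sum(imp) > 0) imp <- imp / sum(imp)
  imp
}

spearman_vec <- function(X, y) {
  apply(X, 2, function(x) {
    if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
    cor(x, y, method = "spearman")
  })
}

#' Region-to-gene importance and correlation scores
#'
#' Per gene, a gradient-boosted tree ensemble predicts its normalized
#' expression from the imputed accessibility of its candidate regions;
#' the importance of a (region, gene) edge is the summed split gain of
#' that region in the ensemble (raw gain, so importances are comparable
#' across genes; `normalize = TRUE` rescales per-gene to shares summing
#' to 1). Spearman
#' correlation between each region's accessibility and the gene's
#' expression is recorded alongside. Zero-variance genes get importance 0
#' and undefined rho, flagged in `zero_variance`.
#'
#' @param imputed_accessibility cell x region matrix.
#' @param normalized_expression gene x cell matrix (same cells).
#' @param pairs a [candidate_pairs()] table.
#' @param seed integer seed for the ensembles.
#' @param nrounds boosting rounds.
#' @param normalize rescale each target's importances to shares summing
#'   to 1 (default: raw summed gain).
#' @return data frame (`source` = region, `target` = gene, `importance`,
#'   `rho`, `distance`, `zero_variance`), class `egrnet_edge_table`,
#'   attribute `level = "region_gene"`.
#' @export
region_gene_scores <- function(imputed_accessibility, normalized_expression,
                               pairs, seed = 1L, nrounds = 500,
                               normalize = FALSE) {
  stopifnot(nrow(imputed_accessibility) == ncol(normalized_expression))
  genes <- unique(pairs$gene)
  genes <- genes[genes %in% rownames(normalized_expression)]
  rows <- vector("list", length(genes))
  for (k in seq_along(genes)) {
    g <- genes[k]
    sub <- pairs[pairs$gene == g, , drop = FALSE]
    regs <- sub$region[sub$region %in% colnames(imputed_accessibility)]
    if (length(regs) == 0) next
    X <- as_dense(imputed_accessibility[, regs, drop = FALSE])
    y <- as.numeric(normalized_expression[g, ])
    zv <- sd(y) == 0
    imp <- boosted_importance(X, y, seed = child_seed(seed, k),
                              nrounds = nrounds, normalize = normalize)
    rows[[k]] <- data.frame(
      source = regs, target = g, importance = unname(imp[regs]),
      rho = if (zv) NA_real_ else unname(spearman_vec(X, y)),
      distance = sub$distance[match(regs, sub$region)],
      zero_variance = zv, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, level = "region_gene", class = c("egrnet_edge_table",
                                                  "data.frame"))
}

#' TF-to-gene adjacency scores
#'
#' Per gene, a gradient-boosted ensemble regresses its normalized
#' expression on all TFs' expression (a TF gene excludes itself from its
#' own predictors); split-gain importance shares and Spearman correlations
#' are recorded for every (TF, gene) pair.
#'
#' @param normalized_expression gene x cell matrix.
#' @param tf_list TF gene identifiers (subset of rownames; >= 2).
#' @param seed integer seed.
#' @param nrounds boosting rounds.
#' @param normalize rescale each gene's importances to shares summing to
#'   1 (default: raw summed gain).
#' @param targets genes to score (default: all genes).
#' @return data frame (`source` = TF, `target` = gene, `importance`,
#'   `rho`, `zero_variance`), class `egrnet_edge_table`, attribute
#'   `level = "tf_gene"`.
#' @export
tf_gene_adjacencies <- function(normalized_expression, tf_list, seed = 1L,
                                nrounds = 500, normalize = FALSE,
                                targets = rownames(normalized_expression)) {
  stopifnot(all(tf_list %in% rownames(normalized_expression)))
  if (length(tf_list) < 2) stop("need >= 2 TFs", call. = FALSE)
  tf_mat <- t(as_dense(normalized_expression[tf_list, , drop = FALSE]))
  rows <- vector("list", length(targets))
  for (k in seq_along(targets)) {
    g <- targets[k]
    preds <- setdiff(tf_list, g)
    X <- tf_mat[, preds, drop = FALSE]
    y <- as.numeric(normalized_expression[g, ])
    zv <- sd(y) == 0
    imp <- boosted_importance(X, y, seed = child_seed(seed, k),
                              nrounds = nrounds, normalize = normalize)
    rows[[k]] <- data.frame(
      source = preds, target = g, importance = unname(imp[preds]),
      rho = if (zv) NA_real_ else unname(spearman_vec(X, y)),
      zero_variance = zv, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, level = "tf_gene", class = c("egrnet_edge_table",
                                              "data.frame"))
}
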