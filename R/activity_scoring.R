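#' Per-cell AUCell activity of a feature set
#'
#' For each cell, features are ranked by decreasing value (ties broken by
#' feature index) and the recovery curve of the set along the top
#' `R = max(1, floor(top_fraction * n_features))` ranks is integrated:
#' `AUC = sum_k H(k) / sum_k min(k, |S|)`, the normalization making the
#' best possible arrangement score 1.
#'
#' @param matrix feature x cell numeric matrix (expression or imputed
#'   accessibility).
#' @param feature_set character vector of features (non-empty subset of
#'   rownames).
#' @param top_fraction fraction of the feature ranking integrated.
#' @return named numeric vector, one AUC in \[0, 1\] per cell.
#' @export
aucell <- function(matrix, feature_set, top_fraction = 0.05) {
  feature_set <- unique(feature_set)
  if (length(feature_set) == 0) stop("empty feature set", call. = FALSE)
  if (!all(feature_set %in% rownames(matrix)))
    stop("feature_set must be a subset of the matrix features",
         call. = FALSE)
  n <- nrow(matrix)
  R <- max(1L, floor(top_fraction * n))
  set_idx <- match(feature_set, rownames(matrix))
  denom <- sum(pmin(seq_len(R), length(set_idx)))
  m <- as_dense(matrix)
  out <- vapply(seq_len(ncol(m)), function(j) {
    ord <- order(-m[, j], seq_len(n))
    sum(cumsum(ord[seq_len(R)] %in% set_idx)) / denom
  }, numeric(1))
  names(out) <- colnames(matrix)
  out
}

#' AUCell scores for a set of eGRNs
#'
#' Applies [aucell()] to each eGRN's target-gene set (modality `"gene"`)
#' or target-region set (modality `"region"`).
#'
#' @param egrns an [assemble_egrns()] result.
#' @param matrix feature x cell matrix matching the modality.
#' @param modality `"gene"` or `"region"`.
#' @param top_fraction passed to [aucell()].
#' @return eGRN x cell matrix of AUC values.
#' @export
aucell_egrns <- function(egrns, matrix, modality = c("gene", "region"),
                         top_fraction = 0.05) {
  modality <- match.arg(modality)
  feats <- rownames(matrix)
  rows <- lapply(egrns, function(e) {
    set <- if (modality == "gene") e$target_genes else e$target_regions
    set <- intersect(set, feats)
    if (length(set) == 0) return(rep(NA_real_, ncol(matrix)))
    aucell(matrix, set, top_fraction)
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- list(names(egrns), colnames(matrix))
  out
}

#' Pseudo-bulk profiles by repeated small random samples per group
#'
#' Per group, draws `n_pseudobulks` profiles, each the arithmetic mean of
#' `cells_per_pseudobulk` cells sampled without replacement when the group
#' has at least that many cells, with replacement otherwise (logged).
#'
#' @param matrix feature x cell matrix.
#' @param labels group label per cell.
#' @param n_pseudobulks profiles per group (default 150).
#' @param cells_per_pseudobulk cells per profile (default 15).
#' @param seed integer seed.
#' @return list with `profiles` (feature x profile matrix), `meta`
#'   (profile, group, with_replacement) and `sampling_log` (cell ids per
#'   profile).
#' @export
make_pseudobulks <- function(matrix, labels, n_pseudobulks = 150L,
                             cells_per_pseudobulk = 15L, seed = 1L) {
  stopifnot(length(labels) == ncol(matrix))
  groups <- sort(unique(labels))
  if (any(table(labels) == 0)) stop("empty group", call. = FALSE)
  set.seed(child_seed(seed, 7))
  m <- as_dense(matrix)
  profiles <- list()
  meta <- list()
  log <- list()
  for (g in groups) {
    cells_g <- which(labels == g)
    replace <- length(cells_g) < cells_per_pseudobulk
    for (b in seq_len(n_pseudobulks)) {
      picked <- cells_g[sample.int(length(cells_g), cells_per_pseudobulk,
                                   replace = replace)]
      nm <- paste0(g, "_pb", b)
      profiles[[nm]] <- rowMeans(m[, picked, drop = FALSE])
      meta[[nm]] <- data.frame(profile = nm, group = g,
                               with_replacement = replace,
                               stringsAsFactors = FALSE)
      log[[nm]] <- colnames(matrix)[picked] %||% picked
    }
  }
  list(profiles = do.call(cbind, profiles),
       meta = do.call(rbind, meta),
       sampling_log = log, seed = seed)
}

#' Quality-filter eGRNs by TF-expression/activity correlation
#'
#' Keeps eGRNs whose pseudo-bulk AUCell activity has absolute Pearson
#' correlation with the TF's pseudo-bulk expression above `rho_min`. When
#' a TF's direct eGRN survives, its extended eGRN of the same sign class
#' is dropped. The correlation sign is recorded as the final
#' activator/repressor call. eGRNs with zero-variance activity or TF
#' expression are dropped and flagged.
#'
#' @param egrns an [assemble_egrns()] result.
#' @param tf_expression TF x profile matrix of pseudo-bulk expression.
#' @param auc_matrix eGRN x profile AUCell matrix on the same profiles.
#' @param rho_min absolute-correlation threshold (default 0.2).
#' @return list with `egrns` (retained, each annotated with `rho` and
#'   `call` in activator/repressor) and `report` (one row per input eGRN).
#' @export
filter_egrns <- function(egrns, tf_expression, auc_matrix, rho_min = 0.2) {
  report <- list()
  rho_of <- setNames(rep(NA_real_, length(egrns)), names(egrns))
  for (nm in names(egrns)) {
    e <- egrns[[nm]]
    if (!(e$tf %in% rownames(tf_expression)) ||
        !(nm %in% rownames(auc_matrix))) next
    x <- tf_expression[e$tf, ]
    y <- auc_matrix[nm, ]
    if (sd(x) == 0 || sd(y) == 0 || anyNA(y)) {
      report[[nm]] <- data.frame(name = nm, tf = e$tf, class = e$class,
                                 sign = e$sign, rho = NA_real_,
                                 kept = FALSE, reason = "zero_variance",
                                 call = NA_character_,
                                 stringsAsFactors = FALSE)
      next
    }
    rho <- cor(x, y)
    rho_of[nm] <- rho
    kept <- abs(rho) > rho_min
    report[[nm]] <- data.frame(
      name = nm, tf = e$tf, class = e$class, sign = e$sign, rho = rho,
      kept = kept, reason = if (kept) "pass" else "low_correlation",
      call = if (rho > 0) "activator" else "repressor",
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, report)
  rownames(report) <- NULL
  ## direct-over-extended de-duplication within (tf, sign)
  if (!is.null(report) && nrow(report) > 0) {
    for (i in which(report$kept & report$class == "extended")) {
      direct_ok <- report$kept & report$class == "direct" &
        report$tf == report$tf[i] & report$sign == report$sign[i]
      if (any(direct_ok)) {
        report$kept[i] <- FALSE
        report$reason[i] <- "direct_preferred"
      }
    }
  }
  kept_names <- report$name[report$kept]
  kept <- egrns[kept_names]
  for (nm in kept_names) {
    kept[[nm]]$rho <- report$rho[report$name == nm]
    kept[[nm]]$call <- report$call[report$name == nm]
  }
  list(egrns = structure(kept, class = "egrnet_egrn_set"), report = report)
}

#' Regulon specificity scores
#'
#' Per (eGRN, group): the eGRN's AUC vector over cells is normalized to a
#' probability distribution `P`; `Q` is uniform over the group's cells and
#' zero elsewhere; `RSS = 1 - sqrt(JSD(P, Q))` with base-2 Jensen-Shannon
#' divergence, so RSS is 1 when activity matches the group indicator
#' exactly and 0 when their supports are disjoint.
#'
#' @param auc_matrix eGRN x cell matrix of non-negative AUC values.
#' @param labels group label per cell.
#' @return eGRN x group matrix of RSS values in \[0, 1\] (NA for all-zero
#'   activity vectors, flagged with a warning).
#' @export
rss <- function(auc_matrix, labels) {
  stopifnot(length(labels) == ncol(auc_matrix), all(auc_matrix >= 0,
                                                    na.rm = TRUE))
  groups <- sort(unique(labels))
  out <- matrix(NA_real_, nrow(auc_matrix), length(groups),
                dimnames = list(rownames(auc_matrix), groups))
  for (i in seq_len(nrow(auc_matrix))) {
    a <- auc_matrix[i, ]
    if (anyNA(a) || sum(a) == 0) {
      warning("all-zero or NA activity vector for '",
              rownames(auc_matrix)[i] %||% i, "': RSS undefined")
      next
    }
    P <- a / sum(a)
    for (g in groups) {
      Q <- as.numeric(labels == g)
      Q <- Q / sum(Q)
      out[i, g] <- 1 - sqrt(jsd_base2(P, Q))
    }
  }
  out
}

# base-2 Jensen-Shannon divergence between two probability vectors
jsd_base2 <- function(P, Q) {
  M <- (P + Q) / 2
  kl <- function(A) {
    nz <- A > 0
    sum(A[nz] * log2(A[nz] / M[nz]))
  }
  (kl(P) + kl(Q)) / 2
}

#' Group-comparison t statistics for signature activities
#'
#' Per requested comparison, a t-test of the signature score between two
#' groups (one-tailed "greater" by default, or paired two-sided), with
#' Bonferroni adjustment across comparisons. Degenerate-variance
#' comparisons are flagged with `p = NaN`.
#'
#' @param scores numeric vector of per-observation signature scores.
#' @param labels group label per observation.
#' @param comparisons data frame with columns `group1`, `group2`.
#' @param alternative passed to [stats::t.test()] (default `"greater"`).
#' @param paired paired test (observations matched by order within group).
#' @return data frame with `group1`, `group2`, `t`, `p_value`, `p_adj`.
#' @export
signature_enrichment <- function(scores, labels, comparisons,
                                 alternative = "greater", paired = FALSE) {
  stopifnot(length(scores) == length(labels))
  res <- lapply(seq_len(nrow(comparisons)), function(i) {
    x <- scores[labels == comparisons$group1[i]]
    y <- scores[labels == comparisons$group2[i]]
    if (length(x) < 2 || length(y) < 2 ||
        (sd(x) == 0 && sd(y) == 0)) {
      return(data.frame(group1 = comparisons$group1[i],
                        group2 = comparisons$group2[i],
                        t = NA_real_, p_value = NaN,
                        stringsAsFactors = FALSE))
    }
    tt <- t.test(x, y, alternative = alternative, paired = paired)
    data.frame(group1 = comparisons$group1[i],
               group2 = comparisons$group2[i],
               t = unname(tt$statistic), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- p.adjust(res$p_value, method = "bonferroni")
  res
}

#' Fisher's exact overlap test of two sets in a universe
#'
#' Two-sided Fisher's exact test on the 2x2 membership table. The
#' reported odds ratio is the sample cross-product ratio (`Inf`/`0` for
#' degenerate tables); the conditional MLE from [stats::fisher.test()] is
#' returned alongside.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all items.
#' @return list with `odds_ratio`, `odds_ratio_mle`, `p_value`, `table`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  stopifnot(all(set_a %in% universe), all(set_b %in% universe))
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- table(factor(in_a, c(TRUE, FALSE)), factor(in_b, c(TRUE, FALSE)))
  ft <- fisher.test(tab)
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  list(odds_ratio = or, odds_ratio_mle = unname(ft$estimate),
       p_value = ft$p.value, table = tab)
}
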