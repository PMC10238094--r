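#' Fit an LDA topic model to a binarized region x cell matrix
#'
#' Collapsed Gibbs sampling with symmetric Dirichlet priors; cells are
#' documents, regions the vocabulary, and the tokens are the nonzero
#' entries of the binarized accessibility matrix. `theta` (cell x topic)
#' and `phi` (topic x region) are posterior point estimates from the final
#' sweep. Priors default to `alpha = 50/T`, `beta = 0.1`, the conventions
#' of the cisTopic family of tools. Cells or regions that are empty after
#' binarization are dropped with a warning.
#'
#' @param binary_matrix region x cell matrix with entries in \{0, 1\}
#'   (nonzero entries of a count matrix are treated as 1).
#' @param T number of topics (>= 1; `T = 1` returns the degenerate model:
#'   all-ones `theta` and `phi` equal to the global region frequencies).
#' @param alpha,beta Dirichlet concentrations (`NULL` for the defaults).
#' @param n_iterations Gibbs sweeps.
#' @param seed integer seed for the sampler.
#' @return an object of class `egrnet_topic_model`: `T`, `theta`, `phi`,
#'   `alpha`, `beta`, `n_iterations`, `seed`, `log_likelihood_trace` and
#'   `coherence_per_topic` (UMass, top-10 regions).
#' @export
fit_lda <- function(binary_matrix, T, alpha = NULL, beta = 0.1,
                    n_iterations = 300L, seed = 1L) {
  stopifnot(T >= 1)
  m <- methods::as(Matrix::Matrix(binary_matrix, sparse = TRUE), "CsparseMatrix")
  m@x[] <- 1
  keep_regions <- Matrix::rowSums(m) > 0
  keep_cells <- Matrix::colSums(m) > 0
  if (!all(keep_regions) || !all(keep_cells)) {
    warning(sum(!keep_regions), " empty regions and ", sum(!keep_cells),
            " empty cells dropped before LDA")
    m <- m[keep_regions, keep_cells, drop = FALSE]
  }
  if (is.null(alpha)) alpha <- 50 / T
  tm <- methods::as(m, "TsparseMatrix")
  if (T == 1L) {
    freq <- Matrix::rowSums(m) / sum(m)
    model <- list(theta = matrix(1, ncol(m), 1,
                                 dimnames = list(colnames(m), "topic1")),
                  phi = matrix(freq, 1, nrow(m),
                               dimnames = list("topic1", rownames(m))),
                  log_likelihood_trace = numeric(0))
  } else {
    fit <- lda_gibbs_cpp(doc = tm@j, word = tm@i, n_docs = ncol(m),
                         n_words = nrow(m), n_topics = as.integer(T),
                         alpha = alpha, beta = beta,
                         n_iter = as.integer(n_iterations),
                         seed = as.integer(seed) %% 2147483647L)
    dimnames(fit$theta) <- list(colnames(m), paste0("topic", seq_len(T)))
    dimnames(fit$phi) <- list(paste0("topic", seq_len(T)), rownames(m))
    model <- fit
  }
  out <- list(T = as.integer(T), theta = model$theta, phi = model$phi,
              alpha = alpha, beta = beta,
              n_iterations = as.integer(n_iterations), seed = as.integer(seed),
              log_likelihood_trace = model$log_likelihood_trace,
              coherence_per_topic = topic_coherence(model$phi, m))
  class(out) <- "egrnet_topic_model"
  out
}

#' UMass topic coherence over each topic's top regions
#'
#' For the `n_top` highest-probability regions of a topic (in decreasing
#' phi order), sums `log((D(r_m, r_l) + 1) / D(r_l))` over ordered pairs
#' `l < m`, where `D` counts the cells in which regions are (co-)detected
#' in the binarized matrix.
#'
#' @param phi topic x region probability matrix.
#' @param binary_matrix region x cell binarized matrix.
#' @param n_top regions per topic entering the score.
#' @return numeric vector, one coherence per topic.
#' @export
topic_coherence <- function(phi, binary_matrix, n_top = 10L) {
  m <- methods::as(Matrix::Matrix(binary_matrix, sparse = TRUE), "CsparseMatrix")
  m@x[] <- 1
  vapply(seq_len(nrow(phi)), function(t) {
    ord <- order(-phi[t, ], seq_len(ncol(phi)))
    top <- ord[seq_len(min(n_top, length(ord)))]
    sub <- m[top, , drop = FALSE]
    doc_freq <- Matrix::rowSums(sub)
    co <- as.matrix(Matrix::tcrossprod(sub))
    s <- 0
    for (i in seq_along(top)[-1]) {
      for (j in seq_len(i - 1)) {
        if (doc_freq[j] > 0) s <- s + log((co[i, j] + 1) / doc_freq[j])
      }
    }
    s
  }, numeric(1))
}

#' Select the topic model with the best median topic coherence
#'
#' @param models list of [fit_lda()] results.
#' @return the winning model, with a `selection_table` attribute giving
#'   `T` and median coherence for every candidate.
#' @export
select_model <- function(models) {
  stopifnot(length(models) >= 1)
  med <- vapply(models, function(m) median(m$coherence_per_topic), numeric(1))
  best <- which.max(med)
  out <- models[[best]]
  attr(out, "selection_table") <- data.frame(
    T = vapply(models, function(m) m$T, integer(1)),
    median_coherence = med)
  out
}

#' Topic-imputed accessibility probabilities
#'
#' `imputed(c, r) = sum_t theta(c, t) * phi(t, r)`; each cell's row is a
#' probability distribution over regions (sums to 1), the model's
#' denoised reconstruction of that cell's accessibility profile.
#'
#' @param model an [fit_lda()] result.
#' @return cell x region matrix.
#' @export
impute_accessibility <- function(model) {
  model$theta %*% model$phi
}

#' Differentially accessible regions by Wilcoxon rank-sum test
#'
#' Per region, a two-sided Wilcoxon rank-sum test of the imputed
#' accessibility in `group` cells versus `reference` cells, with
#' Benjamini-Hochberg adjustment across regions.
#' `log2FC = log2((mean_group + eps) / (mean_ref + eps))`; a region
#' passes when `p_adj < p_adj_threshold` and `log2FC > lfc_threshold`.
#'
#' @param imputed cell x region matrix (imputed probabilities; raw counts
#'   may be supplied instead).
#' @param labels label per cell (row).
#' @param group,reference disjoint label sets, each covering >= 2 cells.
#' @param p_adj_threshold,lfc_threshold pass thresholds.
#' @param eps pseudocount for the fold change.
#' @return data frame with `region`, `group`, `log2FC`, `p_value`,
#'   `p_adj`, `passes`.
#' @export
detect_dars <- function(imputed, labels, group, reference,
                        p_adj_threshold = 5e-3, lfc_threshold = 1.5,
                        eps = 1e-8) {
  stopifnot(length(labels) == nrow(imputed),
            length(intersect(group, reference)) == 0)
  gi <- labels %in% group
  ri <- labels %in% reference
  if (sum(gi) < 2 || sum(ri) < 2)
    stop("group and reference must each contain >= 2 cells", call. = FALSE)
  x <- imputed[gi, , drop = FALSE]
  y <- imputed[ri, , drop = FALSE]
  pv <- vapply(seq_len(ncol(imputed)), function(j) {
    suppressWarnings(wilcox.test(x[, j], y[, j])$p.value)
  }, numeric(1))
  lfc <- log2((colMeans(x) + eps) / (colMeans(y) + eps))
  padj <- p.adjust(pv, method = "BH")
  data.frame(region = colnames(imputed) %||% seq_len(ncol(imputed)),
             group = paste(group, collapse = "+"),
             log2FC = lfc, p_value = pv, p_adj = padj,
             passes = padj < p_adj_threshold & lfc > lfc_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pseudo-bulk binned coverage tracks per cell group
#'
#' Aggregates region-level ATAC counts of all cells sharing a label into
#' genomic bins (a region's counts are assigned to the bin containing its
#' midpoint, conserving total mass). Per-group depth factors (total
#' counts) are recorded for later normalization.
#'
#' @param atac_counts region x cell count matrix.
#' @param labels group label per cell.
#' @param bin_size bin width in bp (> 0).
#' @param regions data frame with `region`, `chrom`, `start`, `end`
#'   matching the rows of `atac_counts`.
#' @param genome_length chromosome length (defaults to covering all
#'   regions).
#' @return list with `bins` (start/end per bin), `tracks` (group x bin
#'   matrix) and `depth` (named totals).
#' @export
pseudobulk_tracks <- function(atac_counts, labels, bin_size, regions,
                              genome_length = NULL) {
  if (bin_size <= 0) stop("bin_size must be > 0", call. = FALSE)
  stopifnot(length(labels) == ncol(atac_counts))
  regions <- regions[match(rownames(atac_counts), regions$region), ]
  mid <- (regions$start + regions$end) / 2
  L <- genome_length %||% max(regions$end)
  n_bins <- ceiling(L / bin_size)
  bin_of <- pmin(floor(mid / bin_size) + 1L, n_bins)
  groups <- sort(unique(labels))
  tracks <- matrix(0, length(groups), n_bins,
                   dimnames = list(groups, NULL))
  for (g in groups) {
    cell_sum <- Matrix::rowSums(atac_counts[, labels == g, drop = FALSE])
    agg <- tapply(cell_sum, bin_of, sum)
    tracks[g, as.integer(names(agg))] <- as.numeric(agg)
  }
  list(bins = data.frame(start = (seq_len(n_bins) - 1L) * bin_size,
                         end = pmin(seq_len(n_bins) * bin_size, L)),
       tracks = tracks,
       depth = setNames(rowSums(tracks), groups))
}

#' Differential regions between two pseudo-bulk tracks
#'
#' A Poisson likelihood-ratio contrast of two depth-normalized binned
#' tracks: with normalized counts `x1`, `x2` and `m = (x1 + x2)/2`, the
#' signed statistic is
#' `LLR = sign(x1 - x2) * (x1*ln(x1/m) + x2*ln(x2/m)) / ln(10)`
#' (with `0*ln 0 := 0`). Bins with `|LLR| > llr_threshold` are assigned to
#' the higher condition; same-sign bins are merged across gaps up to
#' `max_gap` bp and merged intervals shorter than `min_length` bp are
#' dropped. Bins above a background level in both tracks but not
#' differential form the `common` set (background defaults to the 10th
#' percentile of nonzero bin means).
#'
#' @param track1,track2 numeric vectors over identical bins.
#' @param bins data frame of bin `start`/`end` (as from
#'   [pseudobulk_tracks()]).
#' @param depth1,depth2 track depth factors (tracks are scaled to the
#'   smaller depth).
#' @param llr_threshold,max_gap,min_length calling parameters.
#' @param background `NULL` for the percentile default, or a fixed level.
#' @return list of three interval data frames (`cond1`, `cond2`,
#'   `common`), each with `start`, `end`, `mean_llr` (mean |LLR|, log10
#'   scale).
#' @export
diff_tracks <- function(track1, track2, bins, depth1 = sum(track1),
                        depth2 = sum(track2), llr_threshold = 1.5,
                        max_gap = 150, min_length = 300,
                        background = NULL) {
  if (length(track1) != length(track2) || length(track1) != nrow(bins))
    stop("mismatched bins between tracks", call. = FALSE)
  target <- min(depth1, depth2)
  x1 <- if (depth1 > 0) track1 * target / depth1 else track1
  x2 <- if (depth2 > 0) track2 * target / depth2 else track2
  m <- (x1 + x2) / 2
  xlx <- function(x, m) ifelse(x > 0 & m > 0, x * log(x / m), 0)
  llr <- sign(x1 - x2) * (xlx(x1, m) + xlx(x2, m)) / log(10)
  bg <- background %||% {
    nz <- m[m > 0]
    if (length(nz) == 0) Inf else unname(quantile(nz, 0.10, type = 7))
  }
  call_set <- function(flag, llr_abs) {
    idx <- which(flag)
    if (length(idx) == 0)
      return(data.frame(start = numeric(), end = numeric(),
                        mean_llr = numeric()))
    runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
    iv <- do.call(rbind, lapply(runs, function(r) {
      data.frame(start = bins$start[r[1]], end = bins$end[r[length(r)]],
                 mean_llr = mean(llr_abs[r]), n = length(r))
    }))
    iv <- iv[order(iv$start), , drop = FALSE]
    # merge across small gaps
    out <- iv[1, , drop = FALSE]
    if (nrow(iv) > 1) {
      for (i in 2:nrow(iv)) {
        last <- nrow(out)
        if (iv$start[i] - out$end[last] <= max_gap) {
          w1 <- out$n[last]; w2 <- iv$n[i]
          out$mean_llr[last] <- (out$mean_llr[last] * w1 +
                                   iv$mean_llr[i] * w2) / (w1 + w2)
          out$n[last] <- w1 + w2
          out$end[last] <- iv$end[i]
        } else out <- rbind(out, iv[i, ])
      }
    }
    out <- out[out$end - out$start >= min_length, , drop = FALSE]
    rownames(out) <- NULL
    out[, c("start", "end", "mean_llr")]
  }
  abs_llr <- abs(llr)
  list(cond1 = call_set(llr > llr_threshold, abs_llr),
       cond2 = call_set(llr < -llr_threshold, abs_llr),
       common = call_set(x1 > bg & x2 > bg & abs_llr <= llr_threshold,
                         abs_llr),
       llr = llr, background = bg)
}
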