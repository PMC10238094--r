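# Small generator configurations shared across test files. The "small"
# config keeps unit tests fast; acceptance tests use the package default.

small_config <- function(seed = 7, ...) {
  defaults <- list(
    n_cell_types = 4L, cells_per_type = c(60L, 60L, 60L, 20L),
    n_topics = 3L, n_genes = 100L, n_tfs = 5L, n_regions = 200L,
    n_decoy_motifs = 30L, n_repressor_tfs = 1L,
    genome_length = 1.2e6, tss_min_gap = 2000, regions_per_tf = 6L,
    seed = seed)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

small_dataset <- local({
  cache <- new.env()
  function(seed = 7, ...) {
    key <- paste0("d", seed, paste(c(...), collapse = "_"))
    if (is.null(cache[[key]])) {
      cfg <- small_config(seed = seed, ...)
      tr <- generate_truth(cfg)
      cache[[key]] <- list(cfg = cfg, truth = tr,
                           data = simulate_multiome(tr, cfg))
    }
    cache[[key]]
  }
})

# QC thresholds scaled to the small synthetic libraries
small_thresholds <- function(...) {
  qc_thresholds(min_genes_per_cell = 20, min_log10_fragments = 1, ...)
}

# brute-force recovery AUC: explicit per-rank loop (independent oracle)
brute_recovery_auc <- function(ranking, query, R) {
  H <- numeric(R)
  for (k in seq_len(R)) H[k] <- sum(ranking[seq_len(k)] %in% query)
  best <- sum(pmin(seq_len(R), length(query)))
  sum(H) / best
}

# brute-force GSEA running sum (independent oracle)
brute_gsea_es <- function(ranking, gene_set, p = 1) {
  ord <- order(-ranking, names(ranking))
  g <- names(ranking)[ord]
  v <- ranking[ord]
  hit <- g %in% gene_set
  w <- if (p == 0) rep(1, sum(hit)) else abs(v[hit])^p
  if (sum(w) == 0) w <- rep(1, sum(hit))
  run <- numeric(length(g))
  acc <- 0
  j <- 0
  for (i in seq_along(g)) {
    if (hit[i]) {
      j <- j + 1
      acc <- acc + w[j] / sum(w)
    } else {
      acc <- acc - 1 / (length(g) - sum(hit))
    }
    run[i] <- acc
  }
  if (max(run) >= -min(run) - 1e-12) max(run) else min(run)
}

# direct Jensen-Shannon divergence (base 2), summing over the support
brute_jsd <- function(P, Q) {
  M <- (P + Q) / 2
  s <- 0
  for (i in seq_along(P)) {
    if (P[i] > 0) s <- s + 0.5 * P[i] * log2(P[i] / M[i])
    if (Q[i] > 0) s <- s + 0.5 * Q[i] * log2(Q[i] / M[i])
  }
  s
}

# exhaustive 1-D two-cluster split minimizing within-group SS
brute_split_1d <- function(values) {
  s <- sort(values)
  n <- length(s)
  ss <- function(x) if (length(x) <= 1) 0 else sum((x - mean(x))^2)
  best_i <- NA
  best_ss <- Inf
  for (i in seq_len(n - 1)) {
    if (s[i] == s[i + 1]) next
    cur <- ss(s[1:i]) + ss(s[(i + 1):n])
    if (cur < best_ss - 1e-12) {
      best_ss <- cur
      best_i <- i
    }
  }
  (s[best_i] + s[best_i + 1]) / 2
}
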