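#' Dichotomize edges into activating and repressing classes
#'
#' Edges with Spearman rho above `+rho_threshold` are activating, below
#' `-rho_threshold` repressing; edges with `|rho| <= rho_threshold` or an
#' undefined rho are discarded (and counted).
#'
#' @param edge_table data frame with a `rho` column (e.g. from
#'   [region_gene_scores()]).
#' @param rho_threshold positive threshold (default 0.03).
#' @return list with `activating`, `repressing` (row subsets),
#'   `n_discarded` and `n_undefined`.
#' @export
sign_edges <- function(edge_table, rho_threshold = 0.03) {
  if (!is.numeric(rho_threshold) || rho_threshold <= 0)
    stop("rho_threshold must be > 0", call. = FALSE)
  rho <- edge_table$rho
  undef <- is.na(rho)
  act <- !undef & rho > rho_threshold
  rep_ <- !undef & rho < -rho_threshold
  list(activating = edge_table[act, , drop = FALSE],
       repressing = edge_table[rep_, , drop = FALSE],
       n_discarded = sum(!undef & !act & !rep_),
       n_undefined = sum(undef))
}

#' Deterministic two-group split of a 1-D importance vector
#'
#' Scans every cut point between consecutive distinct sorted values and
#' picks the split minimizing the within-group sum of squared deviations
#' (ties resolved by the smallest low-group size). This is the package's
#' binarization step for importance vectors, in the spirit of BASC-style
#' step-function binarization.
#'
#' @param values numeric vector, length >= 2, not all equal.
#' @return list with `threshold` (midpoint of the optimal boundary pair),
#'   `high` (values above the threshold) and `high_idx` (their indices in
#'   the input).
#' @export
split_threshold_1d <- function(values) {
  stopifnot(length(values) >= 2)
  if (length(unique(values)) == 1)
    stop("all values equal: no two-group split exists", call. = FALSE)
  s <- sort(values)
  n <- length(s)
  ss <- function(x) if (length(x) <= 1) 0 else sum((x - mean(x))^2)
  best <- NULL
  best_ss <- Inf
  for (i in seq_len(n - 1)) {
    if (s[i] == s[i + 1]) next
    cur <- ss(s[seq_len(i)]) + ss(s[seq(i + 1, n)])
    if (cur < best_ss - 1e-12) {
      best_ss <- cur
      best <- i
    }
  }
  thr <- (s[best] + s[best + 1]) / 2
  list(threshold = thr, high = values[values > thr],
       high_idx = which(values > thr))
}

#' Prune region-to-gene edges by multiple importance rules
#'
#' For each gene's group of candidate regions, produces nine named edge
#' subsets: the binarization high group (`basc`), per-gene importance
#' quantile cutoffs (`q75`, `q80`, `q85`, `q90`, `q95`, type-7 quantiles,
#' edges with importance >= the cutoff kept) and per-gene top-k by
#' importance (`top5`, `top10`, `top15`; ties broken by region id; genes
#' with fewer regions keep all). Genes whose importances are all equal
#' are unprunable by the binarization rule and keep all regions there.
#'
#' @param edge_table region-to-gene edge data frame (`source`, `target`,
#'   `importance`).
#' @param quantiles,top_k the rule grids.
#' @return named list of edge-table subsets, keyed by method.
#' @export
prune_region_gene <- function(edge_table,
                              quantiles = c(0.75, 0.80, 0.85, 0.90, 0.95),
                              top_k = c(5L, 10L, 15L)) {
  methods_names <- c("basc", paste0("q", quantiles * 100),
                     paste0("top", top_k))
  keep <- lapply(methods_names, function(m) logical(nrow(edge_table)))
  names(keep) <- methods_names
  for (g in unique(edge_table$target)) {
    idx <- which(edge_table$target == g)
    imp <- edge_table$importance[idx]
    ## binarization rule
    if (length(idx) < 2 || length(unique(imp)) == 1) {
      keep$basc[idx] <- TRUE
    } else {
      sp <- split_threshold_1d(imp)
      keep$basc[idx[sp$high_idx]] <- TRUE
    }
    ## per-gene quantile rules
    for (q in quantiles) {
      cut <- quantile(imp, q, type = 7, names = FALSE)
      keep[[paste0("q", q * 100)]][idx[imp >= cut]] <- TRUE
    }
    ## per-gene top-k rules
    ord <- idx[order(-imp, edge_table$source[idx])]
    for (k in top_k) {
      keep[[paste0("top", k)]][ord[seq_len(min(k, length(ord)))]] <- TRUE
    }
  }
  lapply(keep, function(mask) edge_table[mask, , drop = FALSE])
}

#' GSEA enrichment score and leading edge for one TF's target set
#'
#' Weighted Kolmogorov-Smirnov running sum over the ranking (decreasing
#' importance, ties broken by gene identifier): hitting a set member
#' increments by `importance^p` normalized over the set, missing
#' decrements by `1/(N - |S|)`. The enrichment score is the signed
#' extremum of the running sum; the leading edge is the set members at or
#' before the positive maximum (empty when `ES <= 0`).
#'
#' @param ranking named numeric vector of TF-to-gene importances over the
#'   gene universe.
#' @param gene_set character vector, a strict non-empty subset of the
#'   universe.
#' @param weight_exponent exponent `p` (0 gives the unweighted statistic).
#' @return list of class `egrnet_gsea`: `ES`, `leading_edge`,
#'   `running_sum`, `order` (genes in ranking order), `weight_exponent`.
#' @export
gsea_leading_edge <- function(ranking, gene_set, weight_exponent = 1) {
  genes <- names(ranking)
  stopifnot(!is.null(genes))
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0 || !all(gene_set %in% genes))
    stop("gene_set must be a non-empty subset of the ranked universe",
         call. = FALSE)
  if (length(gene_set) == length(genes))
    stop("gene_set equals the universe: enrichment undefined", call. = FALSE)
  ord <- order(-ranking, genes)
  genes_o <- genes[ord]
  vals_o <- ranking[ord]
  is_hit <- genes_o %in% gene_set
  N <- length(genes_o)
  S <- sum(is_hit)
  w <- if (weight_exponent == 0) rep(1, S) else
    abs(vals_o[is_hit])^weight_exponent
  if (sum(w) == 0) w <- rep(1, S)
  inc <- numeric(N)
  inc[is_hit] <- w / sum(w)
  inc[!is_hit] <- -1 / (N - S)
  running <- cumsum(inc)
  # signed extremum; an exact magnitude tie resolves to the positive side
  hi <- max(running)
  lo <- min(running)
  ES <- if (hi >= -lo - 1e-12) hi else lo
  leading <- if (ES > 0) {
    i_max <- which.max(running)
    genes_o[seq_len(i_max)][is_hit[seq_len(i_max)]]
  } else character()
  structure(list(ES = ES, leading_edge = leading, running_sum = running,
                 order = genes_o, weight_exponent = weight_exponent),
            class = "egrnet_gsea")
}

#' Assemble signed eGRNs from cistromes, pruned edges and TF rankings
#'
#' Every edge level is sign-dichotomized before assembly: region-to-gene
#' edges arrive already split into activating/repressing tables (their
#' own Spearman rho), and the TF-to-gene correlation assigns every gene a
#' functional category with respect to the TF (`activating` when
#' `rho > rho_threshold`, `repressing` when `rho < -rho_threshold`,
#' otherwise no category). For every combination of TF, annotation class
#' (direct/extended), functional category and pruning method: the pruned
#' region-to-gene edges are intersected with the TF's cistrome regions
#' and restricted to genes of that category, the implied gene set is
#' tested by [gsea_leading_edge()] against the TF's TF-to-gene importance
#' ranking, and leading-edge genes (with their regions) are retained.
#' Edges are unioned across pruning methods (and region-gene sign tables)
#' into one eGRN per (TF, class, category), with per-edge provenance.
#' The eGRN's `sign` is its TF-level functional category, so planted
#' repressors yield repressing eGRNs; each edge's own region-gene sign
#' class is recorded in the provenance. TFs whose cistrome is disjoint
#' from all pruned regions yield no eGRN.
#'
#' @param cistromes a [build_cistromes()] data frame (region names must
#'   match the edge tables).
#' @param pruned_by_sign list: region-gene sign
#'   (`activating`/`repressing`) -> [prune_region_gene()] result.
#' @param tf_gene_table a [tf_gene_adjacencies()] edge table (supplies
#'   both the importance rankings and the TF-level correlations).
#' @param weight_exponent GSEA weight exponent.
#' @param rho_threshold TF-level dichotomization threshold.
#' @return list of eGRN records (class `egrnet_egrn_set`); each record
#'   has `tf`, `class`, `sign`, `target_genes`, `target_regions`, `edges`
#'   (region, gene, provenance) and `es` (per-method enrichment scores).
#' @export
assemble_egrns <- function(cistromes, pruned_by_sign, tf_gene_table,
                           weight_exponent = 1, rho_threshold = 0.03) {
  out <- list()
  if (nrow(cistromes) == 0) return(structure(out, class = "egrnet_egrn_set"))
  for (ci in seq_len(nrow(cistromes))) {
    tf <- cistromes$tf[ci]
    cls <- cistromes$class[ci]
    cregions <- cistromes$regions[[ci]]
    rk_rows <- tf_gene_table$source == tf
    if (!any(rk_rows)) next
    ranking <- setNames(tf_gene_table$importance[rk_rows],
                        tf_gene_table$target[rk_rows])
    tf_rho <- setNames(tf_gene_table$rho[rk_rows],
                       tf_gene_table$target[rk_rows])
    for (sgn in c("activating", "repressing")) {
      allowed <- names(tf_rho)[!is.na(tf_rho) &
                                 (if (sgn == "activating")
                                   tf_rho > rho_threshold else
                                     tf_rho < -rho_threshold)]
      if (length(allowed) == 0) next
      edge_union <- NULL
      es_list <- c()
      for (rg_sign in names(pruned_by_sign)) {
        for (method in names(pruned_by_sign[[rg_sign]])) {
          sub <- pruned_by_sign[[rg_sign]][[method]]
          sub <- sub[sub$source %in% cregions &
                       sub$target %in% allowed, , drop = FALSE]
          gene_set <- intersect(unique(sub$target), names(ranking))
          if (length(gene_set) == 0 || length(gene_set) >= length(ranking))
            next
          gs <- gsea_leading_edge(ranking, gene_set, weight_exponent)
          es_list[paste(rg_sign, method, sep = ".")] <- gs$ES
          if (gs$ES <= 0 || length(gs$leading_edge) == 0) next
          kept <- sub[sub$target %in% gs$leading_edge,
                      c("source", "target"), drop = FALSE]
          if (nrow(kept) == 0) next
          kept$provenance <- paste(rg_sign, method, sep = ".")
          edge_union <- rbind(edge_union, kept)
        }
      }
      if (is.null(edge_union) || nrow(edge_union) == 0) next
      prov <- tapply(edge_union$provenance,
                     paste(edge_union$source, edge_union$target, sep = "\r"),
                     function(x) paste(sort(unique(x)), collapse = ","))
      uniq <- unique(edge_union[, c("source", "target")])
      uniq$provenance <- unname(prov[paste(uniq$source, uniq$target,
                                           sep = "\r")])
      uniq <- uniq[order(uniq$source, uniq$target), , drop = FALSE]
      rownames(uniq) <- NULL
      names(uniq)[1:2] <- c("region", "gene")
      out[[paste(tf, cls, sgn, sep = "_")]] <- list(
        tf = tf, class = cls, sign = sgn,
        target_genes = sort(unique(uniq$gene)),
        target_regions = sort(unique(uniq$region)),
        edges = uniq, es = es_list)
    }
  }
  structure(out, class = "egrnet_egrn_set")
}

#' Serialize eGRNs as a TSV edge list
#'
#' One row per (tf, region, gene) edge with sign, annotation class and
#' pruning-method provenance.
#'
#' @param egrns an [assemble_egrns()] result (possibly filtered).
#' @param path output TSV path (`NULL` to return the data frame only).
#' @return the edge data frame, invisibly when written.
#' @export
egrn_edge_list <- function(egrns, path = NULL) {
  rows <- lapply(egrns, function(e) {
    data.frame(tf = e$tf, region = e$edges$region, gene = e$edges$gene,
               sign = e$sign, class = e$class,
               provenance = e$edges$provenance, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Write gene or region sets in GMT-like format
#'
#' One set per line: name, description, then members, tab-separated.
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named descriptions (default ".").
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, (descriptions[[nm]] %||% "."), sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
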