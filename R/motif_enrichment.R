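#' Rank database regions per motif by decreasing score
#'
#' @param scores region x motif numeric matrix (finite).
#' @return integer matrix of the same shape: column `m` holds the region
#'   indices of motif `m`'s ranking (best first); score ties are broken by
#'   ascending region index.
#' @export
rank_regions <- function(scores) {
  stopifnot(all(is.finite(scores)))
  apply(scores, 2, function(s) order(-s, seq_along(s)))
}

#' Recovery-curve AUC of a query region set along one motif ranking
#'
#' The recovery curve `H(k)` counts query regions among the top `k`
#' ranked regions, for `k` up to `R = max(1, floor(auc_fraction *
#' n_regions))`. The AUC is `sum_k H(k)` normalized by the best possible
#' arrangement `sum_k min(k, |query|)`, so it lies in \[0, 1\].
#'
#' @param ranking integer vector of region indices, best first (one column
#'   of [rank_regions()]).
#' @param query_set indices (or logical mask) of the query regions.
#' @param auc_fraction top fraction of the ranking integrated.
#' @return scalar AUC in \[0, 1\].
#' @export
recovery_auc <- function(ranking, query_set, auc_fraction = 0.005) {
  n <- length(ranking)
  if (is.logical(query_set)) query_set <- which(query_set)
  if (length(query_set) == 0) stop("empty query set", call. = FALSE)
  R <- max(1L, floor(auc_fraction * n))
  hits <- cumsum(ranking[seq_len(R)] %in% query_set)
  denom <- sum(pmin(seq_len(R), length(query_set)))
  sum(hits) / denom
}

#' Normalized enrichment scores across a motif database
#'
#' Standardizes per-motif recovery AUCs against all motifs:
#' `NES_m = (AUC_m - mean(AUC)) / sd(AUC)` with the sample (n-1) SD.
#'
#' @param aucs named numeric vector of per-motif AUCs (>= 3 motifs).
#' @return named numeric vector of NES values.
#' @export
motif_nes <- function(aucs) {
  stopifnot(length(aucs) >= 3)
  s <- sd(aucs)
  if (s == 0) stop("degenerate motif database: all AUCs equal, SD is zero",
                   call. = FALSE)
  (aucs - mean(aucs)) / s
}

#' Recovery-curve motif enrichment of a query region set
#'
#' Computes per-motif AUCs at `auc_fraction` depth, standardizes them to
#' NES, and for every enriched motif (NES above `nes_threshold`) calls the
#' query regions ranked within the top `rank_fraction` of that motif's
#' ranking as hits.
#'
#' @param scores region x motif score matrix (the database).
#' @param query_set indices, names or logical mask of query regions.
#' @param auc_fraction recovery-curve integration depth.
#' @param rank_fraction hit-calling depth (top fraction of the ranking).
#' @param nes_threshold enrichment cutoff.
#' @param rankings optional precomputed [rank_regions()] result for
#'   `scores`; rankings are query-independent, so callers scoring many
#'   query sets against one database can compute them once.
#' @return list of class `egrnet_motif_enrichment`: `table` (motif, AUC,
#'   NES, enriched, n_hits) and `hits` (named list of query region indices
#'   per enriched motif).
#' @export
motif_enrichment <- function(scores, query_set, auc_fraction = 0.005,
                             rank_fraction = 0.05, nes_threshold = 3,
                             rankings = NULL) {
  if (is.character(query_set)) query_set <- match(query_set, rownames(scores))
  if (is.logical(query_set)) query_set <- which(query_set)
  stopifnot(!anyNA(query_set), length(query_set) >= 1)
  if (is.null(rankings)) rankings <- rank_regions(scores)
  aucs <- vapply(seq_len(ncol(scores)), function(m) {
    recovery_auc(rankings[, m], query_set, auc_fraction)
  }, numeric(1))
  names(aucs) <- colnames(scores)
  nes <- motif_nes(aucs)
  enriched <- nes > nes_threshold
  R_hit <- max(1L, floor(rank_fraction * nrow(scores)))
  hits <- lapply(which(enriched), function(m) {
    intersect(rankings[seq_len(R_hit), m], query_set)
  })
  names(hits) <- names(aucs)[enriched]
  out <- list(table = data.frame(motif = names(aucs), AUC = unname(aucs),
                                 NES = unname(nes),
                                 enriched = unname(enriched),
                                 n_hits = vapply(names(aucs), function(m) {
                                   if (m %in% names(hits))
                                     length(hits[[m]]) else 0L
                                 }, integer(1)),
                                 row.names = NULL, stringsAsFactors = FALSE),
              hits = hits, nes_threshold = nes_threshold,
              rank_fraction = rank_fraction, auc_fraction = auc_fraction)
  class(out) <- "egrnet_motif_enrichment"
  out
}

#' Build direct and extended TF cistromes from motif enrichment
#'
#' A TF's direct cistrome is the union of per-region hits of its enriched
#' motifs with a `direct` annotation; the extended cistrome unions hits
#' over direct, similarity and orthology annotations. Motifs sharing a
#' merged-consensus group contribute their hit set once. Motifs without a
#' TF annotation are skipped.
#'
#' @param enrichment an [motif_enrichment()] result.
#' @param annotations data frame with `motif`, `tf`, `class`
#'   (`direct`/`similarity`/`orthology`) and optionally `group`.
#' @param region_names optional names to map hit indices onto.
#' @return data frame of class rows, one per (tf, class in
#'   \{direct, extended\}) with non-empty regions: `tf`, `class`,
#'   `regions` (list column) and `motifs` (list column).
#' @export
build_cistromes <- function(enrichment, annotations, region_names = NULL) {
  hits <- enrichment$hits
  if (length(hits) == 0) {
    return(data.frame(tf = character(), class = character()))
  }
  ann <- annotations[annotations$motif %in% names(hits), , drop = FALSE]
  if (is.null(ann$group)) ann$group <- ann$motif
  rows <- list()
  for (tf in unique(ann$tf)) {
    sub <- ann[ann$tf == tf, , drop = FALSE]
    for (cls in c("direct", "extended")) {
      keep <- if (cls == "direct") sub$class == "direct"
              else sub$class %in% c("direct", "similarity", "orthology")
      mot <- sub$motif[keep]
      # one contribution per merged-consensus group
      mot <- mot[!duplicated(sub$group[keep])]
      if (length(mot) == 0) next
      regs <- sort(unique(unlist(hits[mot])))
      if (length(regs) == 0) next
      if (!is.null(region_names)) regs <- region_names[regs]
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, class = cls, stringsAsFactors = FALSE,
        regions = I(list(regs)), motifs = I(list(mot)))
    }
  }
  if (length(rows) == 0) return(data.frame(tf = character(),
                                           class = character()))
  do.call(rbind, rows)
}

#' Binary motif-group hit table over regions
#'
#' A region scores a hit for a motif group when the maximum score over the
#' group's member motifs reaches `min_score`.
#'
#' @param scores region x motif score matrix.
#' @param motif_groups named list: group id -> member motif names.
#' @param regions region names (rows of the output); default all.
#' @param min_score hit threshold.
#' @return logical region x group matrix.
#' @export
score_feature_map <- function(scores, motif_groups,
                              regions = rownames(scores), min_score = 6) {
  if (length(regions) == 0) {
    return(matrix(logical(0), 0, length(motif_groups),
                  dimnames = list(NULL, names(motif_groups))))
  }
  out <- matrix(FALSE, length(regions), length(motif_groups),
                dimnames = list(regions, names(motif_groups)))
  for (g in names(motif_groups)) {
    members <- motif_groups[[g]]
    if (!all(members %in% colnames(scores)))
      stop("unknown motif group member in group '", g, "'", call. = FALSE)
    sub <- scores[regions, members, drop = FALSE]
    out[, g] <- apply(sub, 1, max) >= min_score
  }
  out
}
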