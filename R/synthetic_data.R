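#' Configuration for the synthetic multiome generator
#'
#' Bundles every knob of the synthetic paired RNA+ATAC generator. The
#' defaults define the package's reference simulation: about 2,000 cells in
#' five cell types (one rare, 4\% of cells), four accessibility topics,
#' 400 genes of which 10 are transcription factors (2 repressors),
#' 800 candidate regulatory regions and a motif database with one direct
#' motif per TF plus 200 decoy motifs, all on a single 3 Mb chromosome.
#'
#' @param n_cell_types number of cell types.
#' @param cells_per_type integer vector (length `n_cell_types`) of cells per
#'   type; the default makes the last type rare.
#' @param n_topics number of planted accessibility topics.
#' @param n_genes total genes (TFs included).
#' @param n_tfs number of transcription factors (first `n_tfs` gene ids).
#' @param n_regions number of accessible regions (500 bp each).
#' @param n_decoy_motifs motifs with no planted target regions.
#' @param n_repressor_tfs how many TFs act as repressors (negative weights).
#' @param regulatory_effect_size logit-scale magnitude of a TF's effect on a
#'   target region's accessibility probability.
#' @param link_strength expression-scale exponent tying a target gene's mean
#'   to its linked regions' accessibility probabilities.
#' @param nb_dispersion negative-binomial size parameter for counts (larger
#'   means less overdispersed).
#' @param motif_signal_mean mean motif score of a TF's motif inside its
#'   target regions.
#' @param motif_noise_mean mean motif score everywhere else.
#' @param genome_length length (bp) of the single synthetic chromosome.
#' @param tss_min_gap minimum spacing (bp) between consecutive gene TSSs.
#' @param regions_per_tf planted target regions per TF.
#' @param out_of_window_frac fraction of planted region-gene links placed
#'   outside the recoverable 100 bp - 50 kb TSS window (flagged).
#' @param accessibility_depth scale factor mapping the cell-topic times
#'   topic-region probability onto a per-region accessibility probability.
#' @param dirichlet_conc concentration of the per-cell Dirichlet around its
#'   cell type's topic mixture.
#' @param topic_boost unnormalized weight added to a region in its home
#'   topic (controls topic separation).
#' @param tf_expr_high_mean,tf_expr_low_mean negative-binomial means for a
#'   TF's expression in its high type versus elsewhere.
#' @param seed integer seed; expanded into per-stage child seeds.
#' @return an object of class `egrnet_config` (a validated list).
#' @export
synthetic_config <- function(n_cell_types = 5L,
                             cells_per_type = c(520L, 500L, 480L, 420L, 80L),
                             n_topics = 4L,
                             n_genes = 400L,
                             n_tfs = 10L,
                             n_regions = 800L,
                             n_decoy_motifs = 200L,
                             n_repressor_tfs = 2L,
                             regulatory_effect_size = 2.5,
                             link_strength = 1.0,
                             nb_dispersion = 5,
                             motif_signal_mean = 10,
                             motif_noise_mean = 2,
                             genome_length = 3e6,
                             tss_min_gap = 3000,
                             regions_per_tf = 15L,
                             out_of_window_frac = 0.15,
                             accessibility_depth = 150,
                             dirichlet_conc = 4,
                             topic_boost = 40,
                             tf_expr_high_mean = 50,
                             tf_expr_low_mean = 2,
                             seed = 1L) {
  cfg <- list(
    n_cell_types = as.integer(n_cell_types),
    cells_per_type = as.integer(cells_per_type),
    n_topics = as.integer(n_topics),
    n_genes = as.integer(n_genes),
    n_tfs = as.integer(n_tfs),
    n_regions = as.integer(n_regions),
    n_decoy_motifs = as.integer(n_decoy_motifs),
    n_repressor_tfs = as.integer(n_repressor_tfs),
    regulatory_effect_size = regulatory_effect_size,
    link_strength = link_strength,
    nb_dispersion = nb_dispersion,
    motif_signal_mean = motif_signal_mean,
    motif_noise_mean = motif_noise_mean,
    genome_length = genome_length,
    tss_min_gap = tss_min_gap,
    regions_per_tf = as.integer(regions_per_tf),
    out_of_window_frac = out_of_window_frac,
    accessibility_depth = accessibility_depth,
    dirichlet_conc = dirichlet_conc,
    topic_boost = topic_boost,
    tf_expr_high_mean = tf_expr_high_mean,
    tf_expr_low_mean = tf_expr_low_mean,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "egrnet_config"
  cfg
}

validate_config <- function(cfg) {
  counts <- c(cfg$n_cell_types, cfg$n_topics, cfg$n_genes, cfg$n_tfs,
              cfg$n_regions, cfg$regions_per_tf)
  assert_that(all(counts >= 1L), "all counts must be >= 1")
  assert_that(cfg$n_tfs <= cfg$n_genes,
              "configuration error: n_tfs must not exceed n_genes")
  assert_that(length(cfg$cells_per_type) == cfg$n_cell_types,
              "cells_per_type must have length n_cell_types")
  assert_that(all(cfg$cells_per_type >= 1L), "cells_per_type must be >= 1")
  assert_that(cfg$n_repressor_tfs >= 0L && cfg$n_repressor_tfs <= cfg$n_tfs,
              "n_repressor_tfs must lie in [0, n_tfs]")
  assert_that(is.finite(cfg$regulatory_effect_size) &&
                is.finite(cfg$link_strength),
              "effect sizes must be finite")
  assert_that(cfg$nb_dispersion > 0, "nb_dispersion must be > 0")
  assert_that(cfg$n_tfs * cfg$regions_per_tf <= cfg$n_regions,
              "not enough regions for the requested planted targets")
  invisible(TRUE)
}

#' Generate the planted regulatory ground truth
#'
#' Lays out a single synthetic chromosome (gene TSSs with a minimum gap,
#' 500 bp regions), assigns each TF a set of target regions placed at
#' sampled distances from anchor gene TSSs (a configurable fraction lands
#' outside the recoverable 100 bp - 50 kb window and is flagged
#' `out_of_window`), links each planted region to 1-3 genes, draws signed
#' regulatory weights (the configured number of TFs are repressors), builds
#' per-topic region distributions and per-type topic mixtures, and assigns
#' one direct motif per TF (the first half of the TFs also receive a
#' similarity-class motif to exercise extended cistromes).
#'
#' @param config an [synthetic_config()] object.
#' @return an object of class `egrnet_truth`: gene/region layout, the signed
#'   edge table, topic structure, cell-type assignment, TF expression means
#'   by type, and the motif annotation table.
#' @export
generate_truth <- function(config) {
  validate_config(config)
  cfg <- config
  set.seed(child_seed(cfg$seed, 1))

  n_cells <- sum(cfg$cells_per_type)
  cell_types <- paste0("type", seq_len(cfg$n_cell_types))
  cells <- sprintf("cell%05d", seq_len(n_cells))
  cell_type_of_cell <- setNames(rep(cell_types, cfg$cells_per_type), cells)

  ## gene TSS layout: sorted uniform draws plus the enforced minimum gap
  slack <- cfg$genome_length - (cfg$n_genes - 1) * cfg$tss_min_gap - 1
  if (slack <= 0) {
    stop("layout error: genome too short to place ", cfg$n_genes,
         " TSSs with tss_min_gap = ", cfg$tss_min_gap, call. = FALSE)
  }
  tss_pos <- sort(round(runif(cfg$n_genes, 0, slack))) +
    (seq_len(cfg$n_genes) - 1) * cfg$tss_min_gap
  genes <- c(sprintf("tf%02d", seq_len(cfg$n_tfs)),
             sprintf("gene%04d", seq(cfg$n_tfs + 1L, cfg$n_genes)))
  # shuffle positions so TFs are not clustered at the chromosome start
  tss_pos <- tss_pos[sample.int(cfg$n_genes)]
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  tss_table <- data.frame(gene = genes, chrom = "chrS",
                          position = tss_pos, strand = strand,
                          stringsAsFactors = FALSE)
  tf_list <- genes[seq_len(cfg$n_tfs)]
  repressors <- if (cfg$n_repressor_tfs > 0)
    tf_list[seq(cfg$n_tfs - cfg$n_repressor_tfs + 1L, cfg$n_tfs)] else character()

  ## planted TF target regions anchored near sampled non-TF gene TSSs
  non_tf <- setdiff(genes, tf_list)
  anchors <- sample(non_tf, cfg$n_tfs * cfg$regions_per_tf, replace = FALSE)
  width <- 500L
  region_rows <- list()
  edge_rows <- list()
  ridx <- 0L
  tss_of <- setNames(tss_table$position, tss_table$gene)
  for (i in seq_len(cfg$n_tfs)) {
    tf <- tf_list[i]
    sgn <- if (tf %in% repressors) -1 else 1
    for (j in seq_len(cfg$regions_per_tf)) {
      ridx <- ridx + 1L
      anchor <- anchors[(i - 1L) * cfg$regions_per_tf + j]
      in_window <- runif(1) >= cfg$out_of_window_frac
      d <- if (in_window) round(runif(1, 600, 45000)) else
        round(runif(1, 55000, 120000))
      side <- sample(c(-1, 1), 1)
      center <- tss_of[[anchor]] + side * d
      start <- max(0, min(center - width / 2, cfg$genome_length - width))
      region_id <- sprintf("region%04d", ridx)
      region_rows[[ridx]] <- data.frame(
        region = region_id, chrom = "chrS", start = start,
        end = start + width, planted_tf = tf, stringsAsFactors = FALSE)
      ## linked genes: the anchor plus up to 2 extra genes; extras are
      ## drawn from the recoverable window or, at the same configured
      ## rate as anchors, from the band just outside it
      linked <- anchor
      dist_all <- region_gene_distance(start, start + width, tss_pos)
      near_in <- setdiff(genes[dist_all >= 100 & dist_all <= 50000],
                         c(anchor, tf_list))
      near_out <- setdiff(genes[dist_all > 50000 & dist_all <= 120000],
                          c(anchor, tf_list))
      n_extra <- sample(0:2L, 1)
      for (e in seq_len(n_extra)) {
        pool <- if (runif(1) < cfg$out_of_window_frac && length(near_out))
          near_out else near_in
        pool <- setdiff(pool, linked)
        if (length(pool)) linked <- c(linked, sample(pool, 1))
      }
      w <- sgn * cfg$regulatory_effect_size * runif(1, 0.8, 1.2)
      for (g in linked) {
        dg <- region_gene_distance(start, start + width, tss_of[[g]])
        edge_rows[[length(edge_rows) + 1L]] <- data.frame(
          tf = tf, region = region_id, gene = g,
          sign = if (sgn > 0) "activating" else "repressing",
          weight = w, distance = dg,
          out_of_window = !(dg >= 100 & dg <= 50000),
          stringsAsFactors = FALSE)
      }
    }
  }
  ## background regions fill the remainder of the tile
  n_bg <- cfg$n_regions - ridx
  bg_start <- round(runif(n_bg, 0, cfg$genome_length - width))
  for (k in seq_len(n_bg)) {
    region_rows[[ridx + k]] <- data.frame(
      region = sprintf("region%04d", ridx + k), chrom = "chrS",
      start = bg_start[k], end = bg_start[k] + width,
      planted_tf = NA_character_, stringsAsFactors = FALSE)
  }
  regions <- do.call(rbind, region_rows)
  edges <- do.call(rbind, edge_rows)
  rownames(regions) <- rownames(edges) <- NULL

  ## topic structure: each region has a home topic it loads on
  home_topic <- sample.int(cfg$n_topics, cfg$n_regions, replace = TRUE)
  phi_raw <- matrix(rgamma(cfg$n_topics * cfg$n_regions, shape = 2, rate = 1),
                    nrow = cfg$n_topics)
  for (t in seq_len(cfg$n_topics)) {
    phi_raw[t, home_topic == t] <- phi_raw[t, home_topic == t] + cfg$topic_boost
  }
  phi <- phi_raw / rowSums(phi_raw)
  dimnames(phi) <- list(paste0("topic", seq_len(cfg$n_topics)), regions$region)

  ## per-type topic mixture: a mild home-topic tilt per type; most of the
  ## topic variation is per-cell (Dirichlet), so cell types differ only
  ## weakly in their baseline accessibility profile
  type_topic <- matrix(1, cfg$n_cell_types, cfg$n_topics,
                       dimnames = list(cell_types,
                                       paste0("topic", seq_len(cfg$n_topics))))
  for (k in seq_len(cfg$n_cell_types)) {
    type_topic[k, ((k - 1L) %% cfg$n_topics) + 1L] <- 1.5
  }
  type_topic <- type_topic / rowSums(type_topic)

  ## TF expression program: one high type per TF, round-robin over types
  tf_expr_mean <- matrix(cfg$tf_expr_low_mean, cfg$n_tfs, cfg$n_cell_types,
                         dimnames = list(tf_list, cell_types))
  for (i in seq_len(cfg$n_tfs)) {
    tf_expr_mean[i, ((i - 1L) %% cfg$n_cell_types) + 1L] <- cfg$tf_expr_high_mean
  }

  ## motif database annotation: one direct motif per TF; first half of the
  ## TFs get an additional similarity-class motif (weaker signal)
  motif_of_tf <- setNames(paste0("mot_", tf_list, "_dir"), tf_list)
  ann <- data.frame(motif = unname(motif_of_tf), tf = tf_list,
                    class = "direct", similarity_fdr = NA_real_,
                    orthology_identity = NA_real_, group = unname(motif_of_tf),
                    stringsAsFactors = FALSE)
  sim_tfs <- tf_list[seq_len(cfg$n_tfs %/% 2)]
  if (length(sim_tfs) > 0) {
    ann <- rbind(ann, data.frame(
      motif = paste0("mot_", sim_tfs, "_sim"), tf = sim_tfs,
      class = "similarity", similarity_fdr = 1e-4,
      orthology_identity = NA_real_,
      group = paste0("mot_", sim_tfs, "_sim"), stringsAsFactors = FALSE))
  }
  decoys <- sprintf("decoy%03d", seq_len(cfg$n_decoy_motifs))

  truth <- list(
    genes = genes, tf_list = tf_list, repressor_tfs = repressors,
    tss_table = tss_table, regions = regions, edges = edges,
    cells = cells, cell_types = cell_types,
    cell_type_of_cell = cell_type_of_cell,
    type_topic_mixture = type_topic,
    topic_region_distributions = phi,
    tf_expr_mean = tf_expr_mean,
    motif_of_tf = motif_of_tf, motif_annotations = ann,
    decoy_motifs = decoys, config = cfg)
  class(truth) <- "egrnet_truth"
  truth
}

# distance from a 0-based half-open interval to a TSS point: 0 when the
# region covers the TSS, else base pairs to the closest covered base
region_gene_distance <- function(start, end, tss) {
  ifelse(tss >= start & tss < end, 0,
         pmin(abs(start - tss), abs((end - 1) - tss)))
}

#' Simulate a paired multiome dataset from a planted truth
#'
#' Generative model (the package's own, documented in the methods
#' vignette): each cell draws a topic mixture from a Dirichlet centred on
#' its type's mixture; baseline region accessibility probability is the
#' cell-topic by topic-region product scaled by `accessibility_depth`; TF
#' counts are negative binomial with type-specific means; each planted
#' (tf, region) edge shifts the region's accessibility probability on the
#' logit scale by `weight` times the standardized log TF expression;
#' ATAC counts are Binomial(2, p); a target gene's mean is multiplicatively
#' scaled by its linked regions' accessibility probabilities (exponent
#' `link_strength`); gene counts are negative binomial; the motif score of
#' a TF's motif in its target regions is drawn around `motif_signal_mean`,
#' elsewhere around `motif_noise_mean`. Probabilities pushed outside (0,1)
#' by the shift are clamped to \[1e-6, 1-1e-6\] and counted, never an error.
#'
#' @param truth an [generate_truth()] result.
#' @param config the matching [synthetic_config()].
#' @return an object of class `egrnet_multiome` with `rna_counts`
#'   (gene x cell, sparse), `atac_counts` (region x cell, sparse),
#'   `regions`, `tss_table`, `motif_scores` (region x motif),
#'   `motif_annotations`, `cell_annotations` (type, condition and simulated
#'   ATAC QC metrics) and `n_clamped` (count of clamped probabilities).
#' @export
simulate_multiome <- function(truth, config) {
  stopifnot(inherits(truth, "egrnet_truth"))
  cfg <- config
  validate_config(cfg)
  set.seed(child_seed(cfg$seed, 2))

  cells <- truth$cells
  n_cells <- length(cells)
  n_regions <- cfg$n_regions
  n_genes <- cfg$n_genes
  n_topics <- cfg$n_topics
  type_idx <- match(truth$cell_type_of_cell, truth$cell_types)

  ## per-cell topic mixtures (Dirichlet via gamma draws)
  alpha <- cfg$dirichlet_conc * truth$type_topic_mixture[type_idx, , drop = FALSE]
  theta <- matrix(rgamma(n_cells * n_topics, shape = alpha), n_cells, n_topics)
  theta <- theta / rowSums(theta)

  ## TF expression, drawn first: edges push accessibility, not the TF itself
  tf_counts <- matrix(0L, cfg$n_tfs, n_cells,
                      dimnames = list(truth$tf_list, cells))
  for (i in seq_len(cfg$n_tfs)) {
    mu <- truth$tf_expr_mean[i, type_idx]
    tf_counts[i, ] <- rnbinom(n_cells, mu = mu, size = cfg$nb_dispersion)
  }
  zlog <- function(x) {
    lx <- log1p(x)
    s <- sd(lx)
    if (s == 0) rep(0, length(x)) else (lx - mean(lx)) / s
  }
  tf_z <- t(apply(tf_counts, 1, zlog))

  ## accessibility probabilities: topic baseline plus planted logit shifts
  p_base <- clamp_prob(cfg$accessibility_depth *
                         (theta %*% truth$topic_region_distributions))
  lgt <- log(p_base / (1 - p_base))
  tf_region <- unique(truth$edges[, c("tf", "region", "weight")])
  for (k in seq_len(nrow(tf_region))) {
    r <- match(tf_region$region[k], truth$regions$region)
    f <- match(tf_region$tf[k], truth$tf_list)
    lgt[, r] <- lgt[, r] + tf_region$weight[k] * tf_z[f, ]
  }
  p_final <- 1 / (1 + exp(-lgt))
  n_clamped <- sum(p_final < 1e-6 | p_final > 1 - 1e-6)
  p_final <- clamp_prob(p_final)

  atac <- matrix(rbinom(n_cells * n_regions, 2L, p_final), n_cells, n_regions)
  atac_counts <- Matrix::Matrix(t(atac), sparse = TRUE)
  dimnames(atac_counts) <- list(truth$regions$region, cells)

  ## gene expression: log-normal baselines with mild type modulation, then
  ## multiplicative coupling of target genes to their regions' probabilities
  base_mean <- exp(rnorm(n_genes, log(8), 0.6))
  type_factor <- matrix(exp(rnorm(n_genes * cfg$n_cell_types, 0, 0.3)),
                        n_genes, cfg$n_cell_types)
  mu_gene <- base_mean * type_factor[, type_idx, drop = FALSE][cbind(
    rep(seq_len(n_genes), n_cells), rep(seq_len(n_cells), each = n_genes))]
  mu_gene <- matrix(mu_gene, n_genes, n_cells)
  pbar <- colMeans(p_final)
  for (g in unique(truth$edges$gene)) {
    gi <- match(g, truth$genes)
    regs <- truth$edges$region[truth$edges$gene == g]
    ri <- match(regs, truth$regions$region)
    scale <- rep(1, n_cells)
    for (r in ri) scale <- scale * (p_final[, r] / pbar[r])^cfg$link_strength
    mu_gene[gi, ] <- mu_gene[gi, ] * scale
  }
  rna <- matrix(rnbinom(n_genes * n_cells, mu = mu_gene,
                        size = cfg$nb_dispersion), n_genes, n_cells)
  rna[seq_len(cfg$n_tfs), ] <- tf_counts
  rna_counts <- Matrix::Matrix(rna, sparse = TRUE)
  dimnames(rna_counts) <- list(truth$genes, cells)

  ## motif scores: elevated in a TF's planted target regions
  motifs <- c(truth$motif_annotations$motif, truth$decoy_motifs)
  ms <- matrix(pmax(0, rnorm(n_regions * length(motifs),
                             cfg$motif_noise_mean, 1)),
               n_regions, length(motifs),
               dimnames = list(truth$regions$region, motifs))
  for (k in seq_len(nrow(truth$motif_annotations))) {
    m <- truth$motif_annotations$motif[k]
    tf <- truth$motif_annotations$tf[k]
    targets <- unique(truth$edges$region[truth$edges$tf == tf])
    mean_k <- cfg$motif_signal_mean *
      (if (truth$motif_annotations$class[k] == "direct") 1 else 0.85)
    ms[targets, m] <- pmax(0, rnorm(length(targets), mean_k, 1.5))
  }

  ## simulated per-cell ATAC QC metrics (not derived from fragments)
  frip <- rbeta(n_cells, 30, 10)
  total_fragments <- as.integer(round(Matrix::colSums(atac_counts) / frip))
  tss_enrichment <- rgamma(n_cells, shape = 8, rate = 1.2)
  cell_annotations <- data.frame(
    cell = cells, cell_type = unname(truth$cell_type_of_cell),
    condition = sample(c("cond1", "cond2"), n_cells, replace = TRUE),
    total_fragments = total_fragments, frip = frip,
    tss_enrichment = tss_enrichment, stringsAsFactors = FALSE)

  out <- list(rna_counts = rna_counts, atac_counts = atac_counts,
              regions = truth$regions[, c("region", "chrom", "start", "end")],
              tss_table = truth$tss_table, motif_scores = ms,
              motif_annotations = truth$motif_annotations,
              cell_annotations = cell_annotations,
              n_clamped = n_clamped, config = cfg)
  class(out) <- "egrnet_multiome"
  out
}

#' Write a simulated dataset to plain-text files
#'
#' Emits MatrixMarket matrices (integer coordinate field) with barcode and
#' feature TSVs, regions as BED4 sorted by (chrom, start), the TSS table,
#' motif scores and annotations as TSV, cell annotations as TSV, and the
#' ground truth and configuration as JSON, plus a manifest with an md5
#' checksum per file. Identical inputs and seed give byte-identical files.
#'
#' @param dataset an [simulate_multiome()] result.
#' @param truth the matching [generate_truth()] result (or `NULL` to omit).
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return invisibly, the manifest data frame (file, md5).
#' @export
write_dataset <- function(dataset, truth = NULL, out_dir, overwrite = FALSE) {
  stopifnot(inherits(dataset, "egrnet_multiome"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    stop("refusing to write into non-empty directory '", out_dir,
         "' without overwrite = TRUE", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, file) {
    write.table(df, file.path(out_dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE, na = ".")
  }
  write_mm_integer(dataset$rna_counts, file.path(out_dir, "rna_counts.mtx"))
  write_mm_integer(dataset$atac_counts, file.path(out_dir, "atac_counts.mtx"))
  writeLines(colnames(dataset$rna_counts), file.path(out_dir, "barcodes.tsv"))
  writeLines(rownames(dataset$rna_counts), file.path(out_dir, "rna_features.tsv"))
  writeLines(rownames(dataset$atac_counts), file.path(out_dir, "atac_features.tsv"))
  bed <- dataset$regions[order(dataset$regions$chrom, dataset$regions$start), ]
  write.table(bed[, c("chrom", "start", "end", "region")],
              file.path(out_dir, "regions.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  tsv(dataset$tss_table, "tss.tsv")
  ms <- data.frame(region = rownames(dataset$motif_scores),
                   dataset$motif_scores, check.names = FALSE)
  tsv(ms, "motif_scores.tsv")
  tsv(dataset$motif_annotations, "motif_annotations.tsv")
  tsv(dataset$cell_annotations, "cell_annotations.tsv")
  jsonlite::write_json(unclass(dataset$config),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(truth)) {
    tr <- list(tf_list = truth$tf_list, repressor_tfs = truth$repressor_tfs,
               edges = truth$edges,
               motif_of_tf = as.list(truth$motif_of_tf),
               cell_type_of_cell = as.list(truth$cell_type_of_cell),
               topic_region_distributions =
                 apply(truth$topic_region_distributions, 1, identity,
                       simplify = FALSE))
    jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  files <- sort(dir(out_dir))
  files <- setdiff(files, "manifest.tsv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  tsv(manifest, "manifest.tsv")
  invisible(manifest)
}

# MatrixMarket coordinate writer with an integer value field (the reader
# side goes through Matrix::readMM)
write_mm_integer <- function(m, path) {
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  tm <- methods::as(m, "TsparseMatrix")
  o <- order(tm@j, tm@i)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow(m), ncol(m), length(tm@x))), con)
  writeLines(paste(tm@i[o] + 1L, tm@j[o] + 1L,
                   format(tm@x[o], scientific = FALSE, trim = TRUE)), con)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory produced by [write_dataset()].
#' @return an `egrnet_multiome` list (without the clamp counter).
#' @export
read_dataset <- function(dir) {
  rd <- function(f, ...) read.table(file.path(dir, f), sep = "\t",
                                    header = TRUE, na.strings = ".",
                                    stringsAsFactors = FALSE, ...)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  rna <- methods::as(Matrix::readMM(file.path(dir, "rna_counts.mtx")), "CsparseMatrix")
  atac <- methods::as(Matrix::readMM(file.path(dir, "atac_counts.mtx")), "CsparseMatrix")
  dimnames(rna) <- list(readLines(file.path(dir, "rna_features.tsv")), barcodes)
  dimnames(atac) <- list(readLines(file.path(dir, "atac_features.tsv")), barcodes)
  bed <- read.table(file.path(dir, "regions.bed"), sep = "\t",
                    col.names = c("chrom", "start", "end", "region"),
                    stringsAsFactors = FALSE)
  ms <- rd("motif_scores.tsv", check.names = FALSE)
  rownames_ms <- ms$region
  ms <- as.matrix(ms[, -1, drop = FALSE])
  rownames(ms) <- rownames_ms
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  out <- list(rna_counts = rna, atac_counts = atac,
              regions = bed[, c("region", "chrom", "start", "end")],
              tss_table = rd("tss.tsv"), motif_scores = ms,
              motif_annotations = rd("motif_annotations.tsv"),
              cell_annotations = rd("cell_annotations.tsv"),
              n_clamped = NA_integer_, config = cfg)
  class(out) <- "egrnet_multiome"
  out
}
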