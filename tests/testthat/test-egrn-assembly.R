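test_that("edge dichotomization splits by the rho threshold", {
  tab <- data.frame(source = paste0("r", 1:4), target = "g",
                    rho = c(0.05, -0.05, 0.01, NA))
  s <- sign_edges(tab)
  expect_equal(s$activating$source, "r1")
  expect_equal(s$repressing$source, "r2")
  expect_equal(s$n_discarded, 1)
  expect_equal(s$n_undefined, 1)

  # negating a profile flips every retained edge's sign
  tab_neg <- tab
  tab_neg$rho <- -tab_neg$rho
  s_neg <- sign_edges(tab_neg)
  expect_equal(s_neg$activating$source, s$repressing$source)
  expect_equal(s_neg$repressing$source, s$activating$source)

  expect_error(sign_edges(tab, rho_threshold = 0), "> 0")
})

test_that("1-D split matches the exhaustive oracle", {
  expect_setequal(split_threshold_1d(c(1, 1, 1, 10, 10))$high, c(10, 10))
  expect_equal(split_threshold_1d(c(0, 5))$high, 5)
  expect_error(split_threshold_1d(rep(3, 4)), "all values equal")

  set.seed(13)
  for (i in 1:200) {
    v <- round(runif(sample(2:12, 1), 0, 10), 2)
    if (length(unique(v)) == 1) next
    expect_equal(split_threshold_1d(v)$threshold, brute_split_1d(v))
  }
})

test_that("pruning produces the nine expected subsets per sign class", {
  tab <- data.frame(
    source = paste0("r", 1:8),
    target = c(rep("g1", 4), rep("g2", 4)),
    importance = c(0.9, 0.5, 0.1, 0.05, 3, 2, 1, 0.5),
    rho = 0.5)
  pr <- prune_region_gene(tab)
  expect_setequal(names(pr),
                  c("basc", "q75", "q80", "q85", "q90", "q95",
                    "top5", "top10", "top15"))

  # quantile rule follows the type-7 interpolation
  v <- c(0.9, 0.5, 0.1, 0.05)
  cut75 <- quantile(v, 0.75, type = 7, names = FALSE)
  kept75 <- pr$q75[pr$q75$target == "g1", "source"]
  expect_setequal(kept75, tab$source[tab$target == "g1" &
                                       tab$importance >= cut75])

  # top-k exceeding group size keeps everything
  expect_equal(nrow(pr$top5), nrow(tab))

  # every subset is contained in the input edge set
  for (m in names(pr)) {
    expect_true(all(paste(pr[[m]]$source, pr[[m]]$target) %in%
                      paste(tab$source, tab$target)))
  }

  # BASC high group: exhaustive check on g1
  sp <- split_threshold_1d(v)
  expect_setequal(pr$basc[pr$basc$target == "g1", "source"],
                  tab$source[tab$target == "g1"][sp$high_idx])
})

test_that("GSEA running sum reproduces the unweighted worked example", {
  # universe of 5, set at ranks 1-2, p = 0:
  # running sum (0.5, 1.0, 2/3, 1/3, 0)
  rk <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  gs <- gsea_leading_edge(rk, c("g1", "g2"), weight_exponent = 0)
  expect_equal(gs$running_sum, c(0.5, 1.0, 2 / 3, 1 / 3, 0),
               tolerance = 1e-12)
  expect_equal(gs$ES, 1.0)
  expect_setequal(gs$leading_edge, c("g1", "g2"))

  # set at the bottom: ES < 0, empty leading edge
  gs2 <- gsea_leading_edge(rk, c("g4", "g5"))
  expect_lt(gs2$ES, 0)
  expect_length(gs2$leading_edge, 0)

  expect_error(gsea_leading_edge(rk, character()), "non-empty")
  expect_error(gsea_leading_edge(rk, names(rk)), "universe")
})

test_that("GSEA ES matches brute-force and fgsea oracles", {
  set.seed(17)
  for (i in 1:100) {
    N <- sample(10:50, 1)
    rk <- setNames(round(runif(N, 0, 5), 3), sprintf("gene%03d", 1:N))
    S <- sample(names(rk), sample(2:(N - 2), 1))
    gs <- gsea_leading_edge(rk, S)
    expect_equal(gs$ES, brute_gsea_es(rk, S), tolerance = 1e-12)
  }

  # independent library cross-check of the classic statistic (p = 1)
  skip_if_not_installed("fgsea")
  set.seed(18)
  rk <- setNames(sort(runif(40, 0.1, 4), decreasing = TRUE),
                 sprintf("g%02d", 1:40))
  S <- sample(names(rk), 8)
  ours <- gsea_leading_edge(rk, S)$ES
  theirs <- fgsea::calcGseaStat(stats = rk,
                                selectedStats = match(S, names(rk)),
                                gseaParam = 1, scoreType = "pos")
  expect_equal(ours, theirs, tolerance = 1e-6)
})

test_that("eGRN assembly unifies leading edges with provenance", {
  # two TFs, hand-built inputs: tfA activates g1/g2 via r1/r2; g3 is a
  # bystander with weak importance
  cis <- data.frame(tf = "tfA", class = "direct",
                    regions = I(list(c("r1", "r2"))),
                    motifs = I(list("mA")), stringsAsFactors = FALSE)
  rg <- data.frame(source = c("r1", "r2", "r9"),
                   target = c("g1", "g2", "g3"),
                   importance = c(5, 4, 0.1), rho = c(0.5, 0.4, 0.2))
  pruned <- list(activating = prune_region_gene(rg))
  tf_gene <- data.frame(
    source = "tfA", target = c("g1", "g2", "g3", "g4", "g5"),
    importance = c(10, 8, 0.2, 0.1, 0.05),
    rho = c(0.5, 0.4, 0.1, 0.05, 0.02))
  eg <- assemble_egrns(cis, pruned, tf_gene)
  expect_length(eg, 1)
  e <- eg[["tfA_direct_activating"]]
  expect_setequal(e$target_genes, c("g1", "g2"))
  expect_setequal(e$target_regions, c("r1", "r2"))
  expect_true(all(grepl("activating", e$edges$provenance)))

  # union monotonicity: removing a pruning method never adds an edge
  pruned_1 <- list(activating = pruned$activating["top5"])
  eg1 <- assemble_egrns(cis, pruned_1, tf_gene)
  expect_true(all(eg1[[1]]$edges$region %in% e$edges$region))

  # cistrome disjoint from pruned regions: no eGRN
  cis_far <- cis
  cis_far$regions <- I(list("r99"))
  expect_length(assemble_egrns(cis_far, pruned, tf_gene), 0)

  # sign consistency: no (region, gene) edge in both categories of one TF
  d <- small_dataset(seed = 7)
  # (checked on the hand example: the activating category holds all edges)
  expect_false(any(duplicated(paste(e$edges$region, e$edges$gene))))
})

test_that("edge list serialization is deterministic", {
  cis <- data.frame(tf = "tfA", class = "direct",
                    regions = I(list(c("r1", "r2"))),
                    motifs = I(list("mA")), stringsAsFactors = FALSE)
  rg <- data.frame(source = c("r1", "r2"), target = c("g1", "g2"),
                   importance = c(5, 4), rho = c(0.5, 0.4))
  tf_gene <- data.frame(source = "tfA", target = c("g1", "g2", "g3"),
                        importance = c(10, 8, 0.1), rho = c(0.5, 0.4, 0.01))
  eg <- assemble_egrns(cis, list(activating = prune_region_gene(rg)),
                       tf_gene)
  f1 <- tempfile(); f2 <- tempfile()
  egrn_edge_list(eg, f1)
  egrn_edge_list(eg, f2)
  expect_identical(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
  df <- egrn_edge_list(eg)
  expect_named(df, c("tf", "region", "gene", "sign", "class", "provenance"))
  unlink(c(f1, f2))
})
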