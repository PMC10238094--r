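test_that("AUCell matches its worked example and the brute-force loop", {
  # 10 features, set at per-cell ranks 1 and 4, R = 5: AUC = 7/9
  m <- matrix(10:1, 10, 1, dimnames = list(paste0("f", 1:10), "c1"))
  expect_equal(unname(aucell(m, c("f1", "f4"), top_fraction = 0.5)), 7 / 9)
  expect_equal(unname(aucell(m, c("f1", "f2"), top_fraction = 0.5)), 1)
  expect_equal(unname(aucell(m, c("f9", "f10"), top_fraction = 0.5)), 0)
  expect_error(aucell(m, character()), "empty")
  expect_error(aucell(m, "nope"), "subset")

  # brute-force oracle over random instances
  set.seed(31)
  for (i in 1:150) {
    nf <- sample(10:50, 1)
    mm <- matrix(runif(nf * 3), nf, 3,
                 dimnames = list(sprintf("f%02d", 1:nf), paste0("c", 1:3)))
    fs <- sample(rownames(mm), sample(2:5, 1))
    tf <- runif(1, 0.1, 0.6)
    got <- aucell(mm, fs, top_fraction = tf)
    R <- max(1, floor(tf * nf))
    want <- vapply(1:3, function(j) {
      rk <- order(-mm[, j], seq_len(nf))
      brute_recovery_auc(rk, match(fs, rownames(mm)), R)
    }, numeric(1))
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("pseudo-bulk profiles are reproducible means of sampled cells", {
  set.seed(5)
  m <- matrix(rnorm(30 * 60, mean = rep(c(0, 3), each = 30 * 30)), 30, 60,
              dimnames = list(paste0("f", 1:30), paste0("c", 1:60)))
  labels <- rep(c("A", "B"), each = 30)
  pb <- make_pseudobulks(m, labels, n_pseudobulks = 20,
                         cells_per_pseudobulk = 15, seed = 3)
  expect_equal(ncol(pb$profiles), 40)
  expect_false(any(pb$meta$with_replacement))

  # same seed, same sampling log
  pb2 <- make_pseudobulks(m, labels, n_pseudobulks = 20,
                          cells_per_pseudobulk = 15, seed = 3)
  expect_identical(pb$sampling_log, pb2$sampling_log)

  # profile = mean of its logged cells
  nm <- names(pb$sampling_log)[1]
  expect_equal(pb$profiles[, nm],
               rowMeans(m[, pb$sampling_log[[nm]]]), tolerance = 1e-12)

  # group of exactly 15 cells: all profiles equal the group mean
  m15 <- m[, 1:15]
  pb15 <- make_pseudobulks(m15, rep("A", 15), n_pseudobulks = 10,
                           cells_per_pseudobulk = 15, seed = 1)
  expect_true(all(apply(pb15$profiles, 1, function(x) diff(range(x))) <
                    1e-12))
  expect_equal(pb15$profiles[, 1], rowMeans(m15), tolerance = 1e-12)

  # undersized group switches to replacement and is logged
  pb_small <- make_pseudobulks(m[, 1:5], rep("A", 5), n_pseudobulks = 4,
                               cells_per_pseudobulk = 15, seed = 1)
  expect_true(all(pb_small$meta$with_replacement))

  # profile means concentrate around the group mean
  mu_hat <- sapply(1:10, function(s) {
    p <- make_pseudobulks(m[1, , drop = FALSE], labels,
                          n_pseudobulks = 50, cells_per_pseudobulk = 15,
                          seed = s)
    mean(p$profiles[1, p$meta$group == "A"])
  })
  se <- sd(m[1, labels == "A"]) / sqrt(15 * 50)
  expect_lt(abs(mean(mu_hat) - mean(m[1, labels == "A"])), 2 * se + 0.05)

  expect_error(make_pseudobulks(m, labels, n_pseudobulks = 2,
                                cells_per_pseudobulk = 2, seed = 1)$x,
               NA)
})

test_that("eGRN filtering applies the correlation floor and class rule", {
  set.seed(6)
  egrns <- list(
    tfA_direct_activating = list(tf = "tfA", class = "direct",
                                 sign = "activating",
                                 target_genes = "g1", target_regions = "r1",
                                 edges = data.frame(), es = c(m = 0.9)),
    tfA_extended_activating = list(tf = "tfA", class = "extended",
                                   sign = "activating",
                                   target_genes = "g1",
                                   target_regions = "r1",
                                   edges = data.frame(), es = c(m = 0.8)),
    tfB_direct_activating = list(tf = "tfB", class = "direct",
                                 sign = "activating",
                                 target_genes = "g2", target_regions = "r2",
                                 edges = data.frame(), es = c(m = 0.7)))
  x <- rnorm(100)
  tf_expr <- rbind(tfA = x, tfB = rnorm(100))
  # tfA activity tracks expression; the extended copy does too; tfB is at
  # exactly |rho| ~ 0.19 by construction via noise mixing
  auc <- rbind(tfA_direct_activating = x + rnorm(100, 0, 0.1),
               tfA_extended_activating = x + rnorm(100, 0, 0.1),
               tfB_direct_activating = rnorm(100))
  flt <- filter_egrns(egrns, tf_expr, auc, rho_min = 0.2)
  expect_true("tfA_direct_activating" %in% names(flt$egrns))
  # extended dropped because the direct eGRN of the same sign survives
  expect_false("tfA_extended_activating" %in% names(flt$egrns))
  expect_equal(flt$report$reason[flt$report$name ==
                                   "tfA_extended_activating"],
               "direct_preferred")
  expect_false("tfB_direct_activating" %in% names(flt$egrns))
  expect_equal(flt$egrns$tfA_direct_activating$call, "activator")

  # threshold behaviour around |rho| = 0.2: construct exact correlations
  r_pass <- 0.21; r_fail <- 0.19
  mk <- function(r) {
    z <- rnorm(100)
    y <- r * scale(x)[, 1] + sqrt(1 - r^2) * scale(resid(lm(z ~ x)))[, 1]
    y
  }
  auc2 <- rbind(tfA_direct_activating = mk(r_pass),
                tfA_extended_activating = mk(r_pass),
                tfB_direct_activating = mk(r_fail))
  # make tfB compare against x too
  tf_expr2 <- rbind(tfA = x, tfB = x)
  flt2 <- filter_egrns(egrns, tf_expr2, auc2, rho_min = 0.2)
  expect_true(flt2$report$kept[flt2$report$name == "tfA_direct_activating"])
  expect_false(flt2$report$kept[flt2$report$name ==
                                  "tfB_direct_activating"])

  # negative correlation records a repressor call
  auc3 <- rbind(tfA_direct_activating = -x + rnorm(100, 0, 0.1),
                tfA_extended_activating = rnorm(100),
                tfB_direct_activating = rnorm(100))
  flt3 <- filter_egrns(egrns, tf_expr, auc3, rho_min = 0.2)
  expect_equal(flt3$egrns$tfA_direct_activating$call, "repressor")

  # zero-variance activity is dropped and flagged
  auc4 <- auc
  auc4["tfB_direct_activating", ] <- 0.5
  flt4 <- filter_egrns(egrns, tf_expr, auc4, rho_min = 0.2)
  expect_equal(flt4$report$reason[flt4$report$name ==
                                    "tfB_direct_activating"],
               "zero_variance")
})

test_that("RSS matches hand-computed Jensen-Shannon values", {
  # identical distributions: RSS = 1
  auc <- rbind(e1 = c(0.5, 0.5, 0, 0))
  labels <- c("A", "A", "B", "B")
  r <- rss(auc, labels)
  expect_equal(r["e1", "A"], 1)
  # disjoint supports: RSS = 0
  expect_equal(r["e1", "B"], 0)

  # P = (0.5, 0, 0.5, 0) vs Q = (0.5, 0.5, 0, 0): JSD = 0.5
  auc2 <- rbind(e1 = c(0.5, 0, 0.5, 0))
  r2 <- rss(auc2, labels)
  expect_equal(r2["e1", "A"], 1 - sqrt(0.5), tolerance = 1e-12)

  # direct JSD oracle on random vectors
  set.seed(41)
  for (i in 1:100) {
    n <- sample(4:10, 1)
    a <- runif(n)
    lab <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    rr <- rss(rbind(e = a), lab)
    P <- a / sum(a)
    for (g in c("A", "B")) {
      Q <- as.numeric(lab == g)
      Q <- Q / sum(Q)
      expect_equal(rr["e", g], 1 - sqrt(brute_jsd(P, Q)),
                   tolerance = 1e-12)
    }
  }

  # permutation equivariance
  set.seed(42)
  a <- runif(8)
  lab <- rep(c("A", "B"), 4)
  perm <- sample(8)
  r_a <- rss(rbind(e = a), lab)
  r_b <- rss(rbind(e = a[perm]), lab[perm])
  expect_equal(r_a, r_b, tolerance = 1e-12)

  # all-zero activity is flagged
  expect_warning(rz <- rss(rbind(e = rep(0, 4)), labels), "undefined")
  expect_true(all(is.na(rz)))
})

test_that("signature tests and overlap tests match closed forms", {
  set.seed(51)
  scores <- c(rnorm(50), rnorm(50))
  labels <- rep(c("A", "B"), each = 50)
  cmp <- data.frame(group1 = "A", group2 = "B")

  # identical groups: t ~ 0, one-sided p ~ 0.5+
  s0 <- signature_enrichment(rep(c(1, 2), 50), labels, cmp)
  expect_gt(s0$p_value, 0.4)

  # planted +3 SD shift: tiny adjusted p
  scores2 <- scores
  scores2[labels == "A"] <- scores2[labels == "A"] + 3
  s1 <- signature_enrichment(scores2, labels, cmp)
  expect_lt(s1$p_adj, 1e-3)

  # Bonferroni with m = 5 multiplies the p-value
  cmp5 <- cmp[rep(1, 5), ]
  s5 <- signature_enrichment(scores2, labels, cmp5)
  expect_equal(s5$p_adj, pmin(1, 5 * s5$p_value))

  # degenerate variance flagged as NaN
  sdg <- signature_enrichment(rep(1, 100), labels, cmp)
  expect_true(is.nan(sdg$p_value))

  # Fisher overlap: table (3,1,1,3) in a universe of 8 -> p = 34/70
  u <- paste0("x", 1:8)
  a <- u[1:4]
  b <- u[c(1:3, 5)]
  ov <- overlap_test(a, b, u)
  expect_equal(ov$p_value, 34 / 70, tolerance = 1e-12)

  # identical half-universe sets: infinite odds ratio
  h <- u[1:4]
  ov2 <- overlap_test(h, h, u)
  expect_equal(ov2$odds_ratio, Inf)

  # complementary sets: odds ratio 0
  ov3 <- overlap_test(u[1:4], u[5:8], u)
  expect_equal(ov3$odds_ratio, 0)

  expect_error(overlap_test(a, b, character()), "empty universe")
})
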