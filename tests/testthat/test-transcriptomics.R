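# Single-cell spatial pipeline: QC, normalization, HVG, PCA/kNN, Leiden,
# gating, enrichment, DE, Gini markers, subclustering.

test_that("qc_filter keeps >= 20 totals and drops fewer-than-20 cells", {
  m <- matrix(0L, 3, 5)
  m[1, 1] <- 19L; m[2, ] <- 4L  # totals 19, 20, 0
  es <- make_expr(m)
  out <- qc_filter(es)
  expect_equal(nrow(out$counts), 1)
  expect_equal(unname(rowSums(out$counts)), 20)
  expect_equal(out$qc$n_removed, 2)
  # identity when everything passes
  m2 <- matrix(5L, 4, 5)
  expect_equal(nrow(qc_filter(make_expr(m2))$counts), 4)
  expect_error(qc_filter(make_expr(matrix(0L, 2, 2))), "empty after QC")
  # kept count equals the brute-force row-sum count
  set.seed(18)
  m3 <- matrix(rpois(600, 2), 30, 20)
  expect_equal(nrow(qc_filter(make_expr(m3), 20)$counts),
               sum(rowSums(m3) >= 20))
})

test_that("normalize_scale conserves totals and is cell-scale invariant", {
  set.seed(19)
  # equal per-cell totals so a raw-constant gene stays constant after the
  # total-count normalization
  m <- matrix(5L, 15, 20)
  delta <- sample(-3:3, 15, replace = TRUE)
  m[, 1] <- m[, 1] + delta
  m[, 2] <- m[, 2] - delta
  m[, 3] <- 2L  # constant gene (totals are constant too)
  es <- normalize_scale(qc_filter(make_expr(m), 1))
  target <- median(rowSums(es$counts))
  expect_equal(unname(rowSums(es$norm)), rep(target, nrow(es$norm)))
  expect_true(all(es$scaled[, 3] == 0))
  # doubling every count of one cell leaves its normalized row unchanged
  m2 <- m; m2[5, ] <- 2L * m2[5, ]
  es2 <- normalize_scale(qc_filter(make_expr(m2), 1))
  r1 <- es$norm[5, ] / sum(es$norm[5, ])
  r2 <- es2$norm[5, ] / sum(es2$norm[5, ])
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("select_hvg ranks structured genes above constant-proportion ones", {
  set.seed(20)
  n <- 400
  totals <- rpois(n, 200) + 50
  m <- matrix(0L, n, 10)
  # genes 1..8: constant proportion of the cell total (residual variance ~1)
  for (j in 1:8) m[, j] <- rbinom(n, totals, 0.05)
  # gene 9: bimodal across two planted cell states
  state <- rep(c(0, 1), each = n / 2)
  m[, 9] <- rpois(n, ifelse(state == 1, 0.3, 0.02) * totals)
  colnames(m) <- c(sprintf("cp%02d", 1:8), "bimodal", "allzero")
  es <- make_expr(m)
  expect_identical(select_hvg(es, 1), "bimodal")
  expect_false("allzero" %in% select_hvg(es, 9))
  expect_setequal(select_hvg(es, 10), colnames(m))
  expect_error(select_hvg(es, 11), "exceeds")
})

test_that("pca_knn embeds and matches the brute-force neighbour oracle", {
  set.seed(22)
  # data on a line: PC1 carries everything
  t <- rnorm(60)
  m <- matrix(round(50 + outer(t, c(3, 6, 9))), 60, 3)
  m[m < 0] <- 0
  es <- normalize_scale(qc_filter(make_expr(m), 1))
  es$scaled <- outer(t, c(1, 2, 3))  # bypass count noise: exact line
  dimnames(es$scaled) <- dimnames(es$counts)
  gr <- pca_knn(es, n_pcs = 2, k = 5)
  expect_equal(gr$var_explained[1], 1, tolerance = 1e-9)
  # duplicated cells are mutual nearest neighbours
  es$scaled[2, ] <- es$scaled[1, ]
  gr2 <- pca_knn(es, n_pcs = 2, k = 1)
  expect_true(any(gr2$edges[, 1] == 1 & gr2$edges[, 2] == 2))
  # exact agreement with the O(n^2) oracle
  set.seed(23)
  emb <- matrix(rnorm(200 * 5), 200, 5)
  got <- knn_edges_for_test(emb, 6)
  expect_identical(got, knn_oracle_edges(emb, 6))
  expect_error(pca_knn(es, n_pcs = 10, k = 3), "n_pcs")
  expect_error(pca_knn(es, n_pcs = 2, k = 100), "k must be")
})

test_that("leiden_cluster resolves components and planted blocks", {
  # two disconnected 20-cliques
  cl <- function(n, off) t(combn(n, 2)) + off
  g <- list(edges = rbind(cl(20, 0), cl(20, 20)), n = 40)
  lab <- leiden_cluster(g, seed = 1)
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:20])), 1)
  # single clique -> one cluster
  lab1 <- leiden_cluster(list(edges = cl(15, 0), n = 15), seed = 1)
  expect_equal(unique(lab1), 1L)
  expect_error(leiden_cluster(list(edges = cl(5, 0), n = 5), resolution = 0),
               "> 0")
  # planted 4-block SBM recovered exactly (scaled down to 10 seeds). At the
  # pipeline default gamma = 0.1 merging two planted blocks *increases*
  # RB-modularity (e12/m - gamma*k1*k2/(2m^2) > 0 here), so the optimizer is
  # exercised at gamma = 1 where the blocks are separable.
  ok <- vapply(1:10, function(s) {
    set.seed(s)
    g <- sbm_graph(rep(60, 4), 0.3, 0.01)
    adjusted_rand_index(leiden_cluster(g, resolution = 1, seed = s),
                        g$labels) == 1
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("gate_microglia keeps microglia and drops other lineages", {
  mix <- make_two_type_mix(150, 150, seed = 24)
  g <- gate_microglia(mix$es)
  truth_mg <- mix$truth$type == "homeostatic"
  recall <- sum(g$keep & truth_mg) / sum(truth_mg)
  precision <- sum(g$keep & truth_mg) / sum(g$keep)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
  # a cell with zero counts for all markers can never pass
  zeroed <- mix$es
  zeroed$counts[1, gate_spec()$inclusion] <- 0L
  g0 <- gate_microglia(zeroed)
  expect_false(g0$keep[1])
  expect_error(gate_microglia(mix$es, gate_spec(inclusion = c("Csf1r", "Nope1"))),
               "Nope1")
})

test_that("exclude_macrophages removes planted contamination", {
  cfg <- counts_config(seed = 25, n_genes = 120,
                       cells_per_region = list(
                         fimbria = c(homeostatic = 380, macrophage = 20)))
  sc <- list(regions = list(fimbria = matrix(c(0, 0, 100, 0, 100, 100, 0, 100),
                                             ncol = 2, byrow = TRUE)))
  sim <- simulate_counts(cfg, sc)
  es <- normalize_scale(qc_filter(sim$expr, 1))
  truth <- sim$truth[match(es$meta$cell_id, sim$truth$cell_id), ]
  ex <- exclude_macrophages(es)
  mac <- truth$type == "macrophage"
  expect_gte(sum(!ex$keep & mac) / sum(mac), 0.9)     # >= 90% of macrophages out
  expect_lte(sum(!ex$keep & !mac) / sum(!mac), 0.02)  # <= 2% microglia lost
})

test_that("classify_enriched applies the >= 2 raw-count rule", {
  m <- matrix(0L, 4, 3, dimnames = list(sprintf("c%d", 1:4),
                                        c("Lgals3", "Cdkn1a", "Cdkn2a")))
  m[1, "Lgals3"] <- 2L; m[2, "Lgals3"] <- 1L
  m[4, c("Cdkn1a", "Cdkn2a")] <- 1L
  meta <- data.frame(cell_id = rownames(m), x = 0, y = 0, fov = "F",
                     region = "r", stringsAsFactors = FALSE)
  es <- expr_set(m, meta)
  expect_identical(unname(classify_enriched(es, "Lgals3")),
                   c(TRUE, FALSE, FALSE, FALSE))
  # set mode: (1,1,0) sums to 2 -> enriched; "each" mode does not
  set_genes <- c("Cdkn1a", "Cdkn2a")
  expect_true(unname(classify_enriched(es, set_genes, mode = "set"))[4])
  expect_false(unname(classify_enriched(es, set_genes, mode = "each"))[4])
  expect_error(classify_enriched(es, "Trp53"), "absent")
  # invariant to normalization parameters by construction (raw counts)
  es2 <- normalize_scale(es_qc <- qc_filter(es, 1))
  expect_identical(classify_enriched(es2, "Lgals3"),
                   classify_enriched(es_qc, "Lgals3"))
})

test_that("de_wilcoxon: exact enumeration, BH adjustment, antisymmetry", {
  # A=[1,2] vs B=[3,4]: exact two-sided p over all C(4,2) labelings is 1/3
  m <- matrix(0L, 6, 2, dimnames = list(sprintf("c%d", 1:6), c("g1", "g2")))
  m[, 1] <- c(1L, 2L, 3L, 4L, 5L, 6L)
  m[, 2] <- 10L
  meta <- data.frame(cell_id = rownames(m), x = 0, y = 0, fov = "F",
                     region = "r", stringsAsFactors = FALSE)
  es <- expr_set(m, meta)
  es$norm <- m  # identity normalization for a transparent oracle check
  p <- senoglia:::wilcox_p(c(1, 2), c(3, 4))
  expect_equal(p, 1 / 3)
  # full enumeration oracle across all small sample splits
  set.seed(26)
  for (i in 1:20) {
    na <- sample(3:5, 1); nb <- sample(3:5, 1)
    x <- round(rnorm(na), 1); y <- round(rnorm(nb, 0.5), 1)
    r <- rank(c(x, y)); n <- na + nb
    ws <- colSums(matrix(r[combn(n, na)], nrow = na))
    e <- na * (n + 1) / 2
    w <- sum(r[1:na])
    oracle <- mean(abs(ws - e) >= abs(w - e) - 1e-9)
    expect_equal(senoglia:::wilcox_p(x, y), oracle)
  }
  # identical groups: log2FC 0
  de0 <- de_wilcoxon(es, c("c1", "c2", "c3"), c("c4", "c5", "c6"),
                     genes = "g2")
  expect_equal(de0$log2fc, 0)
  # BH step-up on (0.01, 0.04, 0.03) -> (0.03, 0.04, 0.04)
  expect_equal(p.adjust(c(0.01, 0.04, 0.03), "BH"), c(0.03, 0.04, 0.04))
  # antisymmetry
  a <- c("c1", "c2", "c3"); b <- c("c4", "c5", "c6")
  d1 <- de_wilcoxon(es, a, b); d2 <- de_wilcoxon(es, b, a)
  expect_equal(d1$log2fc, -d2$log2fc)
  expect_equal(d1$p, d2$p)
  expect_true(all(d1$padj >= d1$p - 1e-12 & d1$padj <= 1))
  expect_error(de_wilcoxon(es, a, c("c3", "c5", "c6")), "overlap")
})

test_that("gini_markers scores cluster-specific genes", {
  expect_equal(gini_coefficient(c(0, 0, 0, 1)), 0.75)
  expect_equal(gini_coefficient(c(1, 1, 1, 1)), 0)
  set.seed(27)
  x <- rlnorm(6)
  expect_equal(gini_coefficient(10 * x), gini_coefficient(x))
  expect_error(gini_coefficient(c(-1, 2)), "nonnegative")
  # bounded by 1 - 1/n for nonnegative vectors
  for (i in 1:50) {
    v <- rlnorm(sample(2:8, 1))
    expect_lte(gini_coefficient(v), 1 - 1 / length(v) + 1e-12)
  }
  # per-gene table over planted clusters
  mix <- make_two_type_mix(100, 100, seed = 28)
  lab <- ifelse(mix$truth$type == "homeostatic", 1L, 2L)
  gm <- gini_markers(mix$es, lab)
  plp1 <- gm[gm$gene == "Plp1", ]
  expect_equal(plp1$cluster, 2L)
  expect_gt(plp1$gini, 0.4)
  filler <- gm[startsWith(gm$gene, "Filler"), ]
  expect_lt(median(filler$gini), 0.2)
})

test_that("subcluster namespaces labels and recovers planted subtypes", {
  mix <- make_two_type_mix(120, 120, seed = 29,
                           type_a = "homeostatic", type_b = "dam")
  # treat everything as one parent cluster and subcluster it
  parent <- rep(1L, nrow(mix$es$counts))
  lab <- subcluster(mix$es, parent, 1L, n_hvg = 60, n_pcs = 10, k = 10,
                    seed = 5, prefix = "AC")
  expect_true(all(startsWith(lab, "AC-")))
  expect_gte(adjusted_rand_index(lab[mix$es$meta$cell_id], mix$truth$type), 0.9)
  expect_error(subcluster(mix$es, parent, 2L), "not present")
  expect_error(subcluster(mix$es, parent, 1L, k = 200), "too small")
})

test_that("clustering pipeline is deterministic under a fixed seed", {
  mix <- make_two_type_mix(80, 80, seed = 30)
  run <- function() {
    gr <- pca_knn(mix$es, select_hvg(mix$es, 50), n_pcs = 10, k = 8)
    leiden_cluster(gr, seed = 99)
  }
  expect_identical(run(), run())
})
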