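test_that("PCA: rank-1 data, permutation equivariance, eigen oracle", {
  set.seed(2)
  # rank-1 matrix: first PC carries all variance
  u <- rnorm(30); v <- abs(rnorm(8)) + 0.5
  e1 <- toy_expr(outer(u, v))
  p1 <- run_pca(e1, n_pcs = 3)
  expect_gt(p1$var_explained[1], 1 - 1e-10)

  xa <- abs(matrix(rnorm(200), 20, 10))
  dimnames(xa) <- list(sprintf("c%03d", 1:20), sprintf("g%03d", 1:10))
  p <- run_pca(toy_expr(xa), n_pcs = 4)
  perm <- sample(20)
  pp <- run_pca(toy_expr(xa[perm, ]), n_pcs = 4)
  expect_equal(pp$coords, p$coords[perm, ], tolerance = 1e-9)

  # explained variance against a direct eigendecomposition
  ev <- eigen(cov(scale(xa)), symmetric = TRUE)$values
  expect_equal(p$var_explained, (ev / sum(ev))[1:4], tolerance = 1e-9)

  # constant genes are dropped with a warning
  xc <- cbind(xa, const = 1)
  expect_warning(run_pca(toy_expr(xc), n_pcs = 4), "constant")
})

test_that("graph clustering separates blobs and is seeded-deterministic", {
  set.seed(10)
  blob <- function(cx, cy, n) cbind(rnorm(n, cx, 1), rnorm(n, cy, 1))
  two <- rbind(blob(0, 0, 100), blob(10, 0, 100))  # 10 SDs apart
  rownames(two) <- paste0("c", 1:200)
  lab <- cluster_graph(two, knn_k = 30, resolution = 0.45, seed = 3)
  expect_equal(length(unique(lab)), 2)
  expect_equal(rand_adjusted(lab, rep(1:2, each = 100)), 1)
  lab2 <- cluster_graph(two, knn_k = 30, resolution = 0.45, seed = 3)
  expect_identical(lab, lab2)

  one <- blob(0, 0, 120)
  rownames(one) <- paste0("c", 1:120)
  lab1 <- cluster_graph(one, knn_k = 20, resolution = 0.1, seed = 3)
  expect_equal(length(unique(lab1)), 1)
  expect_error(cluster_graph(one[1:10, ], knn_k = 20), "knn_k")
})

test_that("clustering recovers planted populations", {
  sim <- simulate_counts(sim_config(n_cells = 800, n_genes = 200, n_types = 4,
                                    markers_per_type = 12, seed = 9))
  e <- normalize_log(sim$matrix)
  hv <- select_hvg(e)
  emb <- run_pca(e, genes = hv$genes, n_pcs = 15)
  lab <- cluster_graph(emb, knn_k = 20, resolution = 0.45, seed = 4)
  expect_gte(rand_adjusted(lab, sim$truth$lineage), 0.9)
})

test_that("bimodal LRT flags constructed markers and matches a numeric MLE", {
  set.seed(12)
  n <- 60
  base <- matrix(rlnorm(n * 10, 0, 0.3), n, 10)
  base[, 1] <- c(rlnorm(30, 2, 0.3), rep(0, 30))    # high only in cluster A
  colnames(base) <- paste0("g", 1:10)
  rownames(base) <- paste0("c", 1:n)
  e <- toy_expr(log1p(base))
  labels <- rep(c("A", "B"), each = 30)
  tab <- rank_markers_lrt(e, labels)
  g1A <- tab[tab$cluster == "A" & tab$gene == "g1", ]
  expect_true(g1A$is_marker)
  expect_lt(g1A$p_value, 1e-6)
  expect_gt(g1A$log_fc, 0.25)

  # identical empirical distributions in both groups: exactly zero statistic
  half <- log1p(rlnorm(30, 0, 0.5))
  xnull <- matrix(rep(c(half, half), 3), n, 3)   # group A == group B
  colnames(xnull) <- paste0("h", 1:3)
  rownames(xnull) <- paste0("c", 1:n)
  tn <- rank_markers_lrt(toy_expr(xnull), labels)
  expect_false(any(tn$is_marker))
  expect_gt(min(tn$p_value), 0.999)

  # oracle: maximize the stated likelihood numerically for one gene
  x <- as.matrix(e$values)[, "g1"]
  nll <- function(par, xs) {
    p0 <- plogis(par[1]); mu <- par[2]; sig <- exp(par[3])
    n0 <- sum(xs == 0); xpos <- xs[xs > 0]
    -(n0 * log(p0 + 1e-300) + length(xpos) * log(1 - p0 + 1e-300) +
        sum(dnorm(xpos, mu, sig, log = TRUE)))
  }
  fit_grp <- function(xs) {
    o <- optim(c(0, mean(xs[xs > 0]), log(sd(xs[xs > 0]) + 0.1)), nll, xs = xs,
               method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    -o$value
  }
  xin <- x[labels == "A"]; xout <- x[labels == "B"]
  # cluster B has all zeros for g1: its likelihood is the binomial term only
  ll_out <- if (all(xout == 0)) 0 else fit_grp(xout)
  stat_oracle <- 2 * (fit_grp(xin) + ll_out - fit_grp(x))
  p_oracle <- pchisq(stat_oracle, df = 3, lower.tail = FALSE)
  expect_equal(g1A$p_value, p_oracle, tolerance = 1e-6)
})

test_that("LRT p-values are uniform under a no-signal null", {
  set.seed(99)
  n <- 300; G <- 1000
  p0 <- runif(G, 0.2, 0.7); mu <- runif(G, 1, 3); sig <- runif(G, 0.3, 0.8)
  x <- sapply(seq_len(G), function(g) {
    z <- rbinom(n, 1, 1 - p0[g])
    z * pmax(rnorm(n, mu[g], sig[g]), 0.01)
  })
  colnames(x) <- sprintf("g%04d", seq_len(G))
  rownames(x) <- paste0("c", seq_len(n))
  tab <- rank_markers_lrt(toy_expr(x), rep(c(1, 2), each = n / 2))
  p <- tab$p_value[tab$cluster == 1]
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("relatedness dendrogram follows 1 - r with average linkage", {
  set.seed(4)
  base <- matrix(rnorm(40 * 30, 5, 1), 40, 30)
  # clusters 1 and 2 identical in mean; cluster 3 anti-correlated trend
  x <- rbind(base, base, 10 - base + rnorm(40 * 30, 0, 0.01))
  rownames(x) <- paste0("c", seq_len(nrow(x)))
  colnames(x) <- paste0("g", 1:30)
  labels <- rep(1:3, each = 40)
  # duplicate cells make signatures 1 and 2 exactly identical
  rel <- cluster_relatedness(toy_expr(abs(x)), labels)
  expect_equal(rel$hclust$height[1], 0, tolerance = 1e-12)
  # anti-correlated cluster merges last
  expect_equal(rel$hclust$merge[2, ], c(-3, 1))

  # oracle: naive average-linkage agglomeration over 5 clusters
  sim <- simulate_counts(sim_config(n_cells = 250, n_genes = 80, n_types = 5,
                                    markers_per_type = 6, seed = 15))
  e <- normalize_log(sim$matrix)
  rel5 <- cluster_relatedness(e, sim$truth$lineage)
  expect_equal(sort(rel5$hclust$height),
               sort(brute_average_linkage_heights(rel5$distance)),
               tolerance = 1e-9)

  # invariance to relabeling
  relab <- c(L1 = "Z", L2 = "Y", L3 = "X", L4 = "W", L5 = "V")[sim$truth$lineage]
  rel5b <- cluster_relatedness(e, relab)
  expect_equal(sort(rel5$hclust$height), sort(rel5b$hclust$height),
               tolerance = 1e-12)

  expect_error(cluster_relatedness(toy_expr(matrix(1, 20, 5)), rep(1:2, 10)),
               "constant signature")
})

test_that("cell-cycle scoring assigns phases from set-vs-control contrast", {
  sets <- cell_cycle_genes()
  expect_length(sets$g1s, 43)
  expect_length(sets$g2m, 54)
  expect_length(intersect(sets$g1s, sets$g2m), 0)

  # uniform expression: both scores zero, phase G1
  genes <- c(sets$g1s, sets$g2m, sprintf("fill%03d", 1:200))
  n <- 40
  xu <- matrix(1, n, length(genes), dimnames = list(paste0("c", 1:n), genes))
  su <- score_cell_cycle(toy_expr(xu), seed = 3)
  expect_true(all(abs(su$s_score) < 1e-12))
  expect_true(all(su$phase == "G1"))

  # boosted G2/M set wins
  set.seed(7)
  xb <- matrix(rlnorm(n * length(genes), 0, 0.2), n, length(genes),
               dimnames = list(paste0("c", 1:n), genes))
  xb[, sets$g2m] <- xb[, sets$g2m] * 4
  sb <- score_cell_cycle(toy_expr(log1p(xb)), seed = 3)
  expect_true(all(sb$phase == "G2M"))

  # planted three-phase population recovered within 5 points; filler genes
  # span a broad expression range so average-matched controls exist
  set.seed(21)
  n2 <- 900
  fills <- sprintf("fill%03d", 1:300)
  genes2 <- c(sets$g1s, sets$g2m, fills)
  phase_true <- rep(c("G1", "S", "G2M"), each = n2 / 3)
  x3 <- matrix(rlnorm(n2 * length(genes2), 0, 0.25), n2, length(genes2),
               dimnames = list(paste0("c", 1:n2), genes2))
  x3[, fills] <- sweep(x3[, fills], 2, rlnorm(length(fills), 0, 0.8), `*`)
  # non-cycling cells express cycle genes below their population average;
  # cycling cells boost their phase set above it
  cyc <- c(sets$g1s, sets$g2m)
  x3[, cyc] <- x3[, cyc] * 0.3
  x3[phase_true == "S", sets$g1s] <- x3[phase_true == "S", sets$g1s] * 10
  x3[phase_true == "G2M", sets$g2m] <- x3[phase_true == "G2M", sets$g2m] * 10
  s3 <- score_cell_cycle(toy_expr(log1p(x3)), seed = 5)
  for (ph in c("G1", "S", "G2M")) {
    expect_lt(abs(mean(s3$phase == ph) - 1 / 3), 0.05)
  }

  expect_error(score_cell_cycle(toy_expr(xu[, 100:150]), seed = 1),
               "no G1/S genes")
})

test_that("signature cross-correlation matches closed-form Pearson", {
  g <- paste0("g", 1:5)
  sigA <- cbind(a1 = c(1, 2, 3, 4, 5), a2 = c(2, 1, 4, 3, 5))
  rownames(sigA) <- g
  sigB <- cbind(b1 = c(2, 4, 6, 8, 10), b2 = c(5, 4, 3, 2, 1))
  rownames(sigB) <- g
  cc <- cross_correlate_signatures(sigA, sigB, min_shared = 5)
  # hand computation for (a1, b2): perfectly anti-correlated
  expect_equal(cc$r["a1", "b2"], -1, tolerance = 1e-12)
  expect_equal(cc$r["a1", "b1"], 1, tolerance = 1e-12)
  hand <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(cc$r["a2", "b2"], hand(sigA[, 2], sigB[, 2]), tolerance = 1e-12)
  expect_identical(unname(cc$best_match["a1"]), "b1")
  # identical signatures: diagonal of ones
  cc2 <- cross_correlate_signatures(sigA, sigA, min_shared = 5)
  expect_equal(unname(diag(cc2$r)), c(1, 1), tolerance = 1e-12)
  expect_error(cross_correlate_signatures(sigA[1:3, , drop = FALSE], sigB),
               "shared genes")
})
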