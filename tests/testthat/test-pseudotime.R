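test_that("fallback pseudotime recovers position on a curve", {
  set.seed(6)
  tt <- sort(runif(120))
  line <- cbind(5 * tt, rep(0, 120)) + matrix(rnorm(240, 0, 1e-4), 120, 2)
  rownames(line) <- paste0("c", 1:120)
  pt <- estimate_pseudotime_fallback(line)
  expect_gt(cor(pt$t, tt), 0.999)
  expect_equal(pt$t, (line[, 1] - min(line[, 1])) / diff(range(line[, 1])),
               tolerance = 1e-2)
  ptr <- estimate_pseudotime_fallback(line, reverse = TRUE)
  expect_equal(ptr$t, 1 - pt$t, tolerance = 1e-9)
  expect_error(estimate_pseudotime_fallback(line[1:5, ]), "10 cells")

  # recovery of the planted ordering on simulated counts
  sim <- simulate_counts(sim_config(n_cells = 700, n_genes = 250, n_types = 1,
                                    markers_per_type = 0,
                                    frac_dep_genes = 0.3, dep_amplitude = 2.5,
                                    seed = 2))
  e <- normalize_log(sim$matrix)
  emb <- run_pca(e, n_pcs = 10)
  pt2 <- estimate_pseudotime_fallback(emb)
  rho <- cor(pt2$t, sim$truth$pseudotime, method = "spearman")
  expect_gte(abs(rho), 0.8)
})

test_that("pseudotime bins are equal-width with the stated boundary rules", {
  t <- c(0, 0.05, 0.5, 0.9999, 1)
  b <- bin_pseudotime(t, 10)
  expect_equal(b[1], 1)          # t = min -> first bin
  expect_equal(b[5], 10)         # t = max -> last bin (closed)
  expect_equal(attr(b, "edges"), seq(0, 1, length.out = 11), tolerance = 1e-15)
  set.seed(3)
  tu <- runif(10000)
  bu <- bin_pseudotime(tu, 10)
  expect_true(all(abs(tabulate(bu, 10) / 10000 - 0.1) < 0.02))
  expect_error(bin_pseudotime(rep(0.5, 4), 10), "identical")
})

test_that("trimean profiles equal quantile-rule hand computation", {
  vals <- c(0, 0, 0, 10)
  expect_equal(brute_trimean(vals), 0.625)   # Q1=0, Q2=0, Q3=2.5
  x <- cbind(g1 = c(vals, 1:5, rep(7, 4)), g2 = c(rep(2, 4), 5:1, rep(0, 4)))
  rownames(x) <- paste0("c", 1:13)
  e <- toy_expr(x)
  bins <- rep(1:3, c(4, 5, 4))
  p1 <- trimean_profile(e, "g1", bins)
  expect_equal(as.numeric(p1), c(0.625, 3, 7), tolerance = 1e-12) # symmetry: 3
  p2 <- trimean_profile(e, "g2", bins)
  expect_equal(as.numeric(p2)[c(1, 3)], c(2, 0), tolerance = 1e-12) # constants
  # empty bin is interpolated and flagged
  bins4 <- rep(c(1, 2, 4), c(4, 5, 4))
  p4 <- trimean_profile(e, "g2", bins4, n_bins = 4)
  expect_true(attr(p4, "imputed")[3])
  expect_equal(unname(p4[3]), mean(p4[c(2, 4)]), tolerance = 1e-12)
})

test_that("spline smoothing reproduces constants and lines, matches lm", {
  expect_equal(smooth_profile(rep(2.5, 10)), rep(2.5, 10), tolerance = 1e-9)
  lin <- seq(1, 4, length.out = 10)
  expect_equal(smooth_profile(lin), lin, tolerance = 1e-9)
  set.seed(8)
  y <- sin(seq(0, pi, length.out = 10)) + rnorm(10, 0, 0.1)
  ours <- smooth_profile(y, spline_df = 5)
  oracle <- unname(fitted(lm(y ~ splines::ns(x, df = 4),
                             data = list(y = y, x = 1:10))))
  expect_equal(ours, oracle, tolerance = 1e-9)
  expect_error(smooth_profile(c(1, NA, 3)), "finite")
})

test_that("dependence test: degenerate genes, p-value formula, equivariance", {
  set.seed(13)
  n <- 200
  tt <- runif(n)
  flat <- rep(3, n)
  strong <- log1p(50 / (1 + exp(-(tt - 0.5) / 0.05)) + rpois(n, 2))
  noise <- log1p(rpois(n, 5))
  x <- cbind(const = flat, dep = strong, null = noise,
             shifted = noise + 2, scaled = 3 * noise)
  rownames(x) <- paste0("c", 1:n)
  e <- toy_expr(x)
  fit <- suppressWarnings(
    test_pseudotime_dependence(e, tt, n_perms = 100, seed = 5))
  r <- fit$results
  # constant gene: zero statistic, never significant
  expect_equal(r$sd_obs[r$gene == "const"], 0)
  expect_false(r$significant[r$gene == "const"])
  # strong gene beats every permutation: p = 0 exactly, Bonferroni passes
  expect_equal(r$p_perm[r$gene == "dep"], 0)
  expect_equal(r$p_bonf[r$gene == "dep"], 0)
  expect_true(r$significant[r$gene == "dep"])
  # location shift leaves the statistic unchanged; scaling scales it
  expect_equal(r$sd_obs[r$gene == "shifted"], r$sd_obs[r$gene == "null"],
               tolerance = 1e-12)
  expect_equal(r$sd_obs[r$gene == "scaled"], 3 * r$sd_obs[r$gene == "null"],
               tolerance = 1e-12)
  # determinism
  fit2 <- suppressWarnings(
    test_pseudotime_dependence(e, tt, n_perms = 100, seed = 5))
  expect_identical(fit$results, fit2$results)
  expect_error(test_pseudotime_dependence(e, tt, n_perms = 0), "n_perms")
})

test_that("permutation p-values are super-uniform under the null", {
  # repeated tiny null datasets; P(p <= q) <= q + 1/n_perms (+ MC slack)
  set.seed(77)
  P <- 50
  ps <- replicate(300, {
    tt <- runif(40)
    x <- matrix(log1p(rpois(40, 8)), 40, 1,
                dimnames = list(paste0("c", 1:40), "g"))
    fit <- suppressWarnings(test_pseudotime_dependence(
      toy_expr(x), tt, n_bins = 5, n_perms = P, seed = sample.int(1e6, 1)))
    fit$results$p_perm
  })
  for (q in c(0.1, 0.25, 0.5)) {
    expect_lte(mean(ps <= q), q + 1 / P + 3 * sqrt(q * (1 - q) / 300))
  }
})

test_that("the Bonferroni-reachability warning fires when it should", {
  sim <- simulate_counts(sim_config(n_cells = 100, n_genes = 30, n_types = 2,
                                    markers_per_type = 3, seed = 4))
  e <- normalize_log(sim$matrix)
  expect_warning(test_pseudotime_dependence(e, sim$truth$pseudotime,
                                            n_perms = 50, seed = 1),
                 "Bonferroni")
})

test_that("gene clustering separates temporal waves and orders them by peak", {
  # synthetic fit: two wave shapes, a few genes each, slight jitter
  set.seed(9)
  bins <- 10
  early <- exp(-((1:bins) - 3)^2 / 3)
  late <- exp(-((1:bins) - 8)^2 / 3)
  prof <- cbind(sapply(1:6, function(i) early + rnorm(bins, 0, 0.02)),
                sapply(1:6, function(i) late + rnorm(bins, 0, 0.02)))
  colnames(prof) <- paste0("g", 1:12)
  fit <- structure(list(
    results = data.frame(gene = colnames(prof), sd_obs = 1, p_perm = 0,
                         p_bonf = 0, significant = TRUE),
    smoothed = prof), class = "ptdep_fit")
  cl <- cluster_dep_genes(fit, n_gene_clusters = 2)
  lab <- cl$clusters$cluster
  expect_true(all(lab[1:6] == lab[1]))        # duplicated shape: one cluster
  expect_true(all(lab[7:12] == lab[7]))
  expect_identical(lab[1], "pC1")             # early wave labeled first
  expect_identical(lab[7], "pC2")
  expect_error(cluster_dep_genes(fit, 20), "significant genes")
})

test_that("bin composition fractions are normalized and track planted halves", {
  # single label: all fractions one
  t1 <- seq(0, 1, length.out = 50)
  bc1 <- bin_composition(rep("A", 50), t1, 5)
  expect_true(all(bc1$fractions[, "A"] == 1))
  # two lineages on disjoint halves
  set.seed(2)
  tt <- c(runif(300, 0, 0.48), runif(300, 0.52, 1))
  lin <- rep(c("A", "B"), each = 300)
  bc <- bin_composition(lin, tt, 10)
  expect_true(all(abs(rowSums(bc$fractions) - 1) < 1e-12))
  expect_true(all(bc$fractions[1:5, "A"] == 1))
  expect_true(all(bc$fractions[6:10, "B"] == 1))
})
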