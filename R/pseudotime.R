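#' Principal-curve-style fallback pseudotime
#'
#' A lightweight 1D ordering for when no externally inferred trajectory is
#' supplied: initialized on PC1, a smooth curve is fit through PC space for a
#' few iterations (smoothing splines of each coordinate against the current
#' ordering), cells are projected onto the curve, and arc-length position is
#' rescaled to `[0, 1]`. Orientation follows PC1 unless a start marker is
#' given, in which case the orientation making that gene decrease is chosen.
#'
#' @param emb an `embedding` from [run_pca()] (>= 2 PCs) or a numeric matrix.
#' @param n_iter curve refinement iterations.
#' @param grid_n number of curve points used for projection.
#' @param start_marker optional gene symbol expected to decrease along the
#'   trajectory; requires `e`.
#' @param e the [expr_matrix] used to resolve `start_marker`.
#' @param reverse flip the final ordering (`t -> 1 - t`).
#' @return list of class `pseudotime`: `t` (named vector in `[0,1]`),
#'   `source = "fallback"`.
#' @export
estimate_pseudotime_fallback <- function(emb, n_iter = 3, grid_n = 100,
                                         start_marker = NULL, e = NULL,
                                         reverse = FALSE) {
  coords <- if (inherits(emb, "embedding")) emb$coords else as.matrix(emb)
  n <- nrow(coords)
  if (n < 10) stop("need at least 10 cells", call. = FALSE)
  if (ncol(coords) < 2) stop("need at least 2 embedding dimensions",
                             call. = FALSE)
  lambda <- coords[, 1]
  df <- max(4, min(8, floor(n / 4)))
  for (it in seq_len(n_iter)) {
    grid <- seq(min(lambda), max(lambda), length.out = grid_n)
    curve <- sapply(seq_len(ncol(coords)), function(j) {
      fit <- smooth.spline(lambda, coords[, j], df = df)
      predict(fit, grid)$y
    })
    seg <- sqrt(rowSums((curve[-1, , drop = FALSE] -
                           curve[-grid_n, , drop = FALSE])^2))
    arc <- c(0, cumsum(seg))
    # project each cell onto the polyline
    lam_new <- numeric(n)
    sq_curve <- rowSums(curve^2)
    d2 <- outer(rowSums(coords^2), sq_curve, "+") - 2 * coords %*% t(curve)
    nearest <- max.col(-d2)
    for (i in seq_len(n)) {
      k <- nearest[i]
      best <- arc[k]; bestd <- d2[i, k]
      for (kk in c(k - 1L, k)) {
        if (kk < 1L || kk >= grid_n) next
        a <- curve[kk, ]; b <- curve[kk + 1L, ]
        ab <- b - a; len2 <- sum(ab^2)
        if (len2 == 0) next
        u <- min(1, max(0, sum((coords[i, ] - a) * ab) / len2))
        p <- a + u * ab
        dd <- sum((coords[i, ] - p)^2)
        if (dd < bestd) { bestd <- dd; best <- arc[kk] + u * (arc[kk + 1L] - arc[kk]) }
      }
      lam_new[i] <- best
    }
    lambda <- lam_new
  }
  if (diff(range(lambda)) == 0)
    stop("degenerate embedding: all cells project to one point", call. = FALSE)
  t <- (lambda - min(lambda)) / diff(range(lambda))
  if (!is.null(start_marker)) {
    if (is.null(e)) stop("start_marker requires the expression matrix e",
                         call. = FALSE)
    g <- match_symbols(e, start_marker)
    if (cor(t, as_dense(e)[, g]) > 0) t <- 1 - t
  } else if (cor(t, coords[, 1]) < 0) t <- 1 - t
  if (reverse) t <- 1 - t
  structure(list(t = setNames(t, rownames(coords)), source = "fallback"),
            class = "pseudotime")
}

as_pt <- function(t) {
  if (inherits(t, "pseudotime")) t$t else t
}

#' Equal-width pseudotime bins
#'
#' Divides `[min(t), max(t)]` into `n_bins` equal-width bins, half-open
#' `[lo, hi)` except the last bin which is closed.
#'
#' @param t pseudotime values (numeric vector or a `pseudotime` object).
#' @param n_bins number of bins.
#' @return integer bin index per cell, in `1..n_bins`; bin edges as
#'   attribute `"edges"`.
#' @export
bin_pseudotime <- function(t, n_bins = 10) {
  t <- as_pt(t)
  if (length(t) < 1) stop("no cells", call. = FALSE)
  if (any(!is.finite(t))) stop("pseudotime must be finite", call. = FALSE)
  if (diff(range(t)) == 0)
    stop("all pseudotime values identical; cannot bin", call. = FALSE)
  edges <- seq(min(t), max(t), length.out = n_bins + 1)
  idx <- findInterval(t, edges, rightmost.closed = TRUE)
  idx <- pmin(idx, n_bins)
  attr(idx, "edges") <- edges
  idx
}

#' Binned Tukey trimean profile of one gene
#'
#' Summarizes a gene's log-normalized expression in each pseudotime bin by
#' the Tukey trimean `(Q1 + 2*Q2 + Q3) / 4`, quartiles by linear
#' interpolation. Empty bins are imputed by linear interpolation from the
#' nearest non-empty neighbours and flagged.
#'
#' @param e an [expr_matrix].
#' @param gene gene id (column name) or index.
#' @param bins integer bin assignment from [bin_pseudotime()].
#' @param n_bins number of bins.
#' @return numeric vector of length `n_bins`; attribute `"imputed"` marks
#'   bins that were empty.
#' @export
trimean_profile <- function(e, gene, bins, n_bins = max(bins)) {
  stopifnot(inherits(e, "expr_matrix"))
  x <- as_dense(e)[, gene, drop = FALSE]
  prof <- cpp_binned_trimean(x, as.integer(bins), as.integer(n_bins))[, 1]
  attr(prof, "imputed") <- !(seq_len(n_bins) %in% bins)
  prof
}

# hat matrix of a natural cubic regression spline with spline_df fitted
# parameters (intercept + spline_df - 1 basis functions) at n equally
# spaced points
spline_hat <- function(n_bins, spline_df) {
  if (spline_df < 2 || spline_df > n_bins)
    stop("spline_df must lie in [2, n_bins]", call. = FALSE)
  x <- seq_len(n_bins)
  X <- cbind(1, splines::ns(x, df = spline_df - 1))
  X %*% solve(crossprod(X), t(X))
}

#' Smooth a binned profile with a natural cubic regression spline
#'
#' Least-squares fit of a natural cubic spline basis (`spline_df` parameters
#' including the intercept) to the profile at its bin centers; returns fitted
#' values at those centers. Constants and straight lines are reproduced
#' exactly.
#'
#' @param profile numeric vector (one value per bin).
#' @param spline_df effective degrees of freedom of the fit.
#' @return fitted values, same length as `profile`.
#' @export
smooth_profile <- function(profile, spline_df = 5) {
  if (any(!is.finite(profile))) stop("profile must be finite", call. = FALSE)
  H <- spline_hat(length(profile), spline_df)
  as.numeric(H %*% profile)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Permutation test for pseudotime-dependent genes
#'
#' The central statistic: for each gene, expression is summarized by its
#' Tukey-trimean profile over `n_bins` equal-width pseudotime bins, smoothed
#' with a natural cubic regression spline, and scored by the standard
#' deviation (denominator `n_bins`) of the smoothed profile. The null
#' distribution is obtained by randomly permuting the cell-to-pseudotime
#' assignment `n_perms` times (one shared, seeded permutation set for all
#' genes) and recomputing the statistic. The permutation p-value is the
#' fraction of permuted statistics at or above the observed one (no add-one
#' correction, so `p = 0` is attainable and Bonferroni correction across
#' genes can be passed); a gene is significant when `sd_obs > sd_threshold`
#' and Bonferroni-corrected `p < alpha`.
#'
#' Genes expressed in fewer than `min_expr_frac` of cells are excluded
#' before testing. With `rescale_profiles = TRUE` each smoothed profile is
#' rescaled to `[0, 1]` before taking the SD (slower reference path).
#'
#' @param e an [expr_matrix].
#' @param t pseudotime (numeric vector aligned to cells, or a `pseudotime`
#'   object).
#' @param n_bins,n_perms,sd_threshold,alpha,spline_df test parameters.
#' @param min_expr_frac expression prevalence filter.
#' @param rescale_profiles rescale smoothed profiles to `[0, 1]` before the
#'   SD statistic.
#' @param seed RNG seed for the shared permutation set.
#' @return list of class `ptdep_fit`: `results` (data.frame: `gene`,
#'   `sd_obs`, `p_perm`, `p_bonf`, `significant`), `trimean` and `smoothed`
#'   (`n_bins` x genes profile matrices), `bins`, `n_genes_tested`,
#'   parameters.
#' @export
test_pseudotime_dependence <- function(e, t, n_bins = 10, n_perms = 1000,
                                       sd_threshold = 0.5, alpha = 0.01,
                                       spline_df = 5, min_expr_frac = 0.01,
                                       rescale_profiles = FALSE, seed = 1L) {
  stopifnot(inherits(e, "expr_matrix"))
  if (n_perms < 1) stop("n_perms must be >= 1", call. = FALSE)
  t <- as_pt(t)
  x <- as_dense(e)
  stopifnot(length(t) == nrow(x))
  keep <- colMeans(x > 0) >= min_expr_frac
  x <- x[, keep, drop = FALSE]
  G <- ncol(x)
  if (G == 0) stop("no genes pass the expression filter", call. = FALSE)
  if (G / n_perms >= alpha)
    warning("with ", G, " genes and ", n_perms, " permutations, Bonferroni ",
            "significance is only reachable at p_perm = 0")
  bins <- bin_pseudotime(t, n_bins)
  H <- spline_hat(n_bins, spline_df)

  tri <- cpp_binned_trimean(x, as.integer(bins), as.integer(n_bins))
  sm <- H %*% tri
  stat_of <- function(p) {
    if (rescale_profiles) {
      r <- diff(range(p))
      if (r == 0) return(0)
      pop_sd((p - min(p)) / r)
    } else pop_sd(p)
  }
  sd_obs <- apply(sm, 2, stat_of)

  set.seed(seed)
  perm_bins <- t(replicate(n_perms, sample(as.integer(bins))))
  if (rescale_profiles) {
    null_sd <- matrix(0, n_perms, G)
    for (p in seq_len(n_perms)) {
      trp <- cpp_binned_trimean(x, perm_bins[p, ], as.integer(n_bins))
      null_sd[p, ] <- apply(H %*% trp, 2, stat_of)
    }
  } else {
    null_sd <- cpp_perm_profile_sd(x, perm_bins, H)
  }
  p_perm <- colSums(null_sd >= rep(sd_obs, each = n_perms)) / n_perms
  p_bonf <- pmin(1, p_perm * G)
  res <- data.frame(gene = colnames(x), sd_obs = sd_obs, p_perm = p_perm,
                    p_bonf = p_bonf,
                    significant = sd_obs > sd_threshold & p_bonf < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  dimnames(tri) <- dimnames(sm) <- list(paste0("bin", seq_len(n_bins)),
                                        colnames(x))
  structure(list(results = res, trimean = tri, smoothed = sm, bins = bins,
                 n_genes_tested = G,
                 params = list(n_bins = n_bins, n_perms = n_perms,
                               sd_threshold = sd_threshold, alpha = alpha,
                               spline_df = spline_df, seed = seed,
                               rescale_profiles = rescale_profiles)),
            class = "ptdep_fit")
}

#' Cluster significant pseudotime-dependent genes
#'
#' Hierarchically clusters the z-scored smoothed profiles of significant
#' genes (distance `1 - Pearson r`, average linkage), cuts the tree at
#' `n_gene_clusters`, and orders clusters by the pseudotime position of
#' their mean-profile peak: the earliest-peaking cluster is `pC1`.
#'
#' @param fit a `ptdep_fit` from [test_pseudotime_dependence()].
#' @param n_gene_clusters number of gene clusters.
#' @return list: `clusters` (data.frame `gene`, `cluster`), `profiles`
#'   (mean z-scored profile per cluster), `counts`.
#' @export
cluster_dep_genes <- function(fit, n_gene_clusters = 5) {
  stopifnot(inherits(fit, "ptdep_fit"))
  sig <- fit$results$gene[fit$results$significant]
  if (length(sig) < n_gene_clusters)
    stop("only ", length(sig), " significant genes; need >= ",
         n_gene_clusters, call. = FALSE)
  prof <- fit$smoothed[, sig, drop = FALSE]
  z <- scale(prof)          # per-gene z-score across bins
  z[, attr(z, "scaled:scale") == 0] <- 0
  d <- as.dist(1 - cor(z))
  hc <- hclust(d, method = "average")
  raw <- cutree(hc, k = n_gene_clusters)
  peak <- vapply(seq_len(n_gene_clusters), function(k) {
    mean(apply(z[, raw == k, drop = FALSE], 2, which.max))
  }, numeric(1))
  ord <- order(peak)
  relabel <- integer(n_gene_clusters); relabel[ord] <- seq_len(n_gene_clusters)
  lab <- paste0("pC", relabel[raw])
  profiles <- sapply(paste0("pC", seq_len(n_gene_clusters)), function(k) {
    rowMeans(z[, lab == k, drop = FALSE])
  })
  list(clusters = data.frame(gene = sig, cluster = lab,
                             stringsAsFactors = FALSE),
       profiles = profiles,
       counts = table(factor(lab, paste0("pC", seq_len(n_gene_clusters)))))
}

#' Per-bin label composition along pseudotime
#'
#' Fraction of cells carrying each label within each equal-width pseudotime
#' bin. Fractions sum to 1 in every non-empty bin; empty bins are reported
#' with count 0.
#'
#' @param labels per-cell labels (cluster or lineage).
#' @param t pseudotime aligned to `labels`.
#' @param n_bins number of bins.
#' @return list: `fractions` (n_bins x labels matrix), `counts` (cells per
#'   bin).
#' @export
bin_composition <- function(labels, t, n_bins = 10) {
  t <- as_pt(t)
  labels <- as.vector(labels)
  stopifnot(length(labels) == length(t))
  bins <- bin_pseudotime(t, n_bins)
  labs <- sort(unique(labels))
  tab <- table(factor(bins, seq_len(n_bins)), factor(labels, labs))
  counts <- rowSums(tab)
  frac <- tab / ifelse(counts > 0, counts, 1)
  frac <- matrix(frac, n_bins, length(labs),
                 dimnames = list(paste0("bin", seq_len(n_bins)), labs))
  list(fractions = frac, counts = setNames(as.integer(counts),
                                           paste0("bin", seq_len(n_bins))))
}
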