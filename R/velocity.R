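#' k-nearest-neighbour pooling of spliced/unspliced counts
#'
#' Smooths both count matrices by summing each cell with its `knn_k` nearest
#' neighbours (Euclidean distance in the supplied PC embedding of the spliced
#' counts, self included). Summing rather than averaging is scale-free for
#' the downstream ratio fit.
#'
#' @param spliced,unspliced aligned [umi_matrix] objects (or plain matrices).
#' @param emb an `embedding` from [run_pca()] on the spliced counts, or a
#'   numeric cells x dims matrix.
#' @param knn_k neighbours pooled per cell; 0 returns the raw matrices.
#' @return list: `s`, `u` (dense pooled cells x genes matrices), `nn`
#'   (neighbour index matrix).
#' @export
pool_knn <- function(spliced, unspliced, emb, knn_k = 100) {
  s <- as_dense(spliced); u <- as_dense(unspliced)
  stopifnot(all(dim(s) == dim(u)))
  coords <- if (inherits(emb, "embedding")) emb$coords else as.matrix(emb)
  n <- nrow(s)
  if (knn_k >= n) stop("knn_k must be < number of cells", call. = FALSE)
  if (knn_k == 0) return(list(s = s, u = u, nn = NULL))
  nn <- knn_index(coords, knn_k)
  inc <- Matrix::sparseMatrix(i = rep(seq_len(n), knn_k + 1),
                              j = c(as.vector(nn), seq_len(n)),
                              x = 1, dims = c(n, n))
  list(s = as.matrix(inc %*% s), u = as.matrix(inc %*% u), nn = nn)
}

#' Steady-state degradation-rate fit (gene-relative model)
#'
#' For each gene, fits a regression through the origin of pooled unspliced
#' on pooled spliced counts restricted to the extreme cells — those in the
#' top and bottom `extreme_quantile` of pooled spliced expression, where
#' cells are closest to steady state: `gamma = sum(u * s) / sum(s^2)`.
#' Genes with fewer than `min_cells` cells having both counts nonzero are
#' dropped and reported.
#'
#' @param s,u pooled matrices from [pool_knn()].
#' @param extreme_quantile tail fraction used on each side (in (0, 0.5)).
#' @param min_cells minimum cells with nonzero `s` and `u`.
#' @return data.frame per gene: `gene`, `gamma`, `n_extreme`, `fitted`
#'   (logical), `degenerate` (`u` identically zero).
#' @export
fit_gamma <- function(s, u, extreme_quantile = 0.02, min_cells = 10) {
  stopifnot(all(dim(s) == dim(u)))
  if (extreme_quantile <= 0 || extreme_quantile >= 0.5)
    stop("extreme_quantile must lie in (0, 0.5)", call. = FALSE)
  G <- ncol(s)
  gene <- colnames(s) %||% paste0("g", seq_len(G))
  gamma <- rep(NA_real_, G); n_ext <- integer(G)
  fitted <- logical(G); degen <- logical(G)
  for (g in seq_len(G)) {
    sg <- s[, g]; ug <- u[, g]
    if (all(sg == 0)) next
    if (sum(sg > 0 & ug > 0) < min_cells && !all(ug == 0)) next
    lo <- quantile(sg, extreme_quantile)
    hi <- quantile(sg, 1 - extreme_quantile)
    sel <- sg <= lo | sg >= hi
    n_ext[g] <- sum(sel)
    denom <- sum(sg[sel]^2)
    if (denom == 0) next
    gamma[g] <- sum(ug[sel] * sg[sel]) / denom
    fitted[g] <- TRUE
    degen[g] <- all(ug == 0)
  }
  data.frame(gene = gene, gamma = gamma, n_extreme = n_ext, fitted = fitted,
             degenerate = degen, stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-cell, per-gene RNA velocity
#'
#' Steady-state residual `v = u - gamma * s` on the pooled matrices, for
#' genes with a fitted gamma.
#'
#' @param s,u pooled matrices from [pool_knn()].
#' @param gamma_fit data.frame from [fit_gamma()].
#' @return cells x fitted-genes velocity matrix.
#' @export
compute_velocity <- function(s, u, gamma_fit) {
  keep <- which(gamma_fit$fitted)
  if (length(keep) == 0) stop("no genes with fitted gamma", call. = FALSE)
  v <- u[, keep, drop = FALSE] -
    sweep(s[, keep, drop = FALSE], 2, gamma_fit$gamma[keep], `*`)
  colnames(v) <- gamma_fit$gene[keep]
  v
}

#' Project velocities onto a 2D embedding
#'
#' For each cell, the velocity vector is correlated with the
#' expression-displacement vectors toward its `n_sight` nearest embedding
#' neighbours; transition weights are an exponential kernel on the
#' correlations, and the cell's arrow is the weighted mean of unit
#' displacements minus the uniform-weight baseline (so a zero velocity gives
#' a zero arrow, and arrows are invariant to translating the embedding). A
#' `grid_n` x `grid_n` lattice field is aggregated with a Gaussian distance
#' kernel.
#'
#' @param v velocity matrix from [compute_velocity()].
#' @param s pooled spliced matrix (expression space for displacements);
#'   columns are matched to `v` by name.
#' @param emb2d cells x 2 embedding aligned to `v`.
#' @param n_sight neighbourhood size for projection; capped at `n_cells - 1`
#'   with a warning.
#' @param corr_sigma width of the exponential correlation kernel.
#' @param grid_n lattice resolution for the aggregated field.
#' @return list of class `velocity_field`: `arrows` (cells x 2), `grid`
#'   (data.frame `x`, `y`, `dx`, `dy`, `weight`), `params`.
#' @export
project_velocity <- function(v, s, emb2d, n_sight = 3500, corr_sigma = 0.05,
                             grid_n = 30) {
  emb2d <- as.matrix(emb2d)
  stopifnot(ncol(emb2d) == 2, nrow(emb2d) == nrow(v))
  n <- nrow(v)
  if (n_sight >= n) {
    warning("n_sight >= n_cells; capped at n_cells - 1")
    n_sight <- n - 1L
  }
  s <- s[, colnames(v), drop = FALSE]
  nn <- knn_index(emb2d, n_sight)
  arrows <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    nbrs <- nn[i, ]
    disp_e <- emb2d[nbrs, , drop = FALSE] -
      matrix(emb2d[i, ], n_sight, 2, byrow = TRUE)
    len <- sqrt(rowSums(disp_e^2))
    len[len == 0] <- 1
    unit_e <- disp_e / len
    delta <- s[nbrs, , drop = FALSE] -
      matrix(s[i, ], n_sight, ncol(s), byrow = TRUE)
    vi <- v[i, ]
    vc <- vi - mean(vi)
    vn <- sqrt(sum(vc^2))
    if (vn == 0) next                        # zero velocity: zero arrow
    dc <- delta - rowMeans(delta)
    dn <- sqrt(rowSums(dc^2))
    cc <- as.numeric(dc %*% vc) / (dn * vn)
    cc[!is.finite(cc)] <- 0
    w <- exp(cc / corr_sigma)
    w <- w / sum(w)
    arrows[i, ] <- colSums(w * unit_e) - colMeans(unit_e)
  }
  # grid aggregation with a Gaussian kernel
  gx <- seq(min(emb2d[, 1]), max(emb2d[, 1]), length.out = grid_n)
  gy <- seq(min(emb2d[, 2]), max(emb2d[, 2]), length.out = grid_n)
  sigma <- mean(c(diff(range(gx)), diff(range(gy)))) / grid_n
  grid <- expand.grid(x = gx, y = gy)
  d2 <- outer(grid$x, emb2d[, 1], "-")^2 + outer(grid$y, emb2d[, 2], "-")^2
  K <- exp(-d2 / (2 * sigma^2))
  wsum <- rowSums(K)
  grid$dx <- as.numeric(K %*% arrows[, 1]) / pmax(wsum, .Machine$double.eps)
  grid$dy <- as.numeric(K %*% arrows[, 2]) / pmax(wsum, .Machine$double.eps)
  grid$weight <- wsum
  structure(list(arrows = arrows, grid = grid,
                 params = list(n_sight = n_sight, corr_sigma = corr_sigma,
                               grid_n = grid_n)),
            class = "velocity_field")
}
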