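#' Principal component embedding of an expression matrix
#'
#' Centers and unit-scales each gene, then decomposes the cells x genes
#' matrix by SVD. Constant genes are dropped with a warning. Columns are
#' ordered by decreasing explained variance and given a deterministic sign:
#' the loading with the largest absolute value in each component is positive.
#'
#' @param e an [expr_matrix].
#' @param genes optional gene ids (typically the HVG list) to restrict to.
#' @param n_pcs number of components to keep.
#' @return list of class `embedding`: `coords` (cells x n_pcs), `loadings`,
#'   `var_explained` (fraction per kept PC), `genes` used.
#' @export
run_pca <- function(e, genes = NULL, n_pcs = 40) {
  stopifnot(inherits(e, "expr_matrix"))
  x <- as_dense(e)
  if (!is.null(genes)) {
    miss <- setdiff(genes, colnames(x))
    if (length(miss)) stop("genes not in matrix: ",
                           paste(head(miss, 3), collapse = ", "),
                           call. = FALSE)
    x <- x[, genes, drop = FALSE]
  }
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped before PCA")
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (n_pcs > min(dim(x)))
    stop("n_pcs exceeds min(cells, genes)", call. = FALSE)
  xs <- scale(x)
  sv <- svd(xs, nu = n_pcs, nv = n_pcs)
  coords <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  load <- sv$v
  for (j in seq_len(n_pcs)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]; coords[, j] <- -coords[, j]
    }
  }
  dimnames(coords) <- list(rownames(x), paste0("PC", seq_len(n_pcs)))
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(n_pcs)))
  ve <- sv$d^2 / sum(sv$d^2)
  structure(list(coords = coords, loadings = load,
                 var_explained = ve[seq_len(n_pcs)], genes = colnames(x)),
            class = "embedding")
}

# exact k-nearest neighbours (excluding self) by blocked brute force
knn_index <- function(coords, k, block = 512L) {
  n <- nrow(coords)
  if (k >= n) stop("k must be < number of cells", call. = FALSE)
  nn <- matrix(0L, n, k)
  sq <- rowSums(coords^2)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * coords[rows, , drop = FALSE] %*% t(coords)
    for (i in seq_along(rows)) {
      d2[i, rows[i]] <- Inf
      nn[rows[i], ] <- order(d2[i, ])[seq_len(k)]
    }
  }
  nn
}

#' Graph-based clustering of an embedding
#'
#' Builds a k-nearest-neighbour graph (Euclidean distance in PC space),
#' reweights edges by the Jaccard similarity of neighbourhoods (shared
#' nearest neighbours, self included), and optimizes modularity by Louvain
#' community detection at the given resolution. Labels are integers `1..K`
#' ordered by decreasing cluster size; the run is deterministic for a fixed
#' seed.
#'
#' @param emb an `embedding` from [run_pca()], or a numeric cells x dims
#'   matrix.
#' @param knn_k neighbours per cell.
#' @param resolution Louvain resolution parameter.
#' @param prune_snn minimum Jaccard weight retained (smaller edges dropped).
#' @param seed RNG seed for the modularity optimization.
#' @return integer vector of cluster labels, named by cell id.
#' @export
cluster_graph <- function(emb, knn_k = 30, resolution = 0.45,
                          prune_snn = 1 / 15, seed = 1L) {
  coords <- if (inherits(emb, "embedding")) emb$coords else as.matrix(emb)
  n <- nrow(coords)
  if (n < knn_k + 1) stop("need at least knn_k + 1 cells", call. = FALSE)
  nn <- knn_index(coords, knn_k)
  # neighbourhood incidence with self included
  inc <- Matrix::sparseMatrix(i = rep(seq_len(n), knn_k + 1),
                              j = c(as.vector(nn), seq_len(n)),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(inc)
  shared <- as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j
  i <- shared@i[keep] + 1L; j <- shared@j[keep] + 1L; s <- shared@x[keep]
  jac <- s / (2 * (knn_k + 1) - s)
  ok <- jac >= prune_snn
  g <- igraph::graph_from_data_frame(
    data.frame(from = i[ok], to = j[ok], weight = jac[ok]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(comm)[as.character(seq_len(n))]
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  out <- as.integer(relabel[as.character(memb)])
  names(out) <- rownames(coords)
  out
}

# log-likelihood pieces of the zero/positive-Gaussian mixture, vectorized
# over genes; x is a dense cells x genes block
bimod_ll <- function(x) {
  n <- nrow(x)
  pos <- x > 0
  n1 <- colSums(pos)
  n0 <- n - n1
  s1 <- colSums(x)
  s2 <- colSums(x^2)
  mu <- ifelse(n1 > 0, s1 / n1, 0)
  sig2 <- ifelse(n1 > 0, pmax(s2 / n1 - mu^2, 1e-6), 1e-6)
  ll_bin <- ifelse(n0 > 0, n0 * log(n0 / n), 0) +
    ifelse(n1 > 0, n1 * log(n1 / n), 0)
  ll_gauss <- ifelse(n1 > 0, -n1 / 2 * (log(2 * pi * sig2) + 1), 0)
  ll_bin + ll_gauss
}

#' Cluster marker genes by bimodal likelihood-ratio test
#'
#' One-vs-rest differential expression per cluster. Each gene's
#' log-normalized expression is modelled as a mixture of a point mass at zero
#' and a Gaussian on the positive values; the likelihood-ratio statistic
#' `2 * (ll_in + ll_out - ll_pooled)` is referred to a chi-squared
#' distribution with 3 degrees of freedom (zero fraction, mean, variance each
#' freed per group). The fold change is
#' `ln(mean(expm1(in)) + 1) - ln(mean(expm1(out)) + 1)`. A gene is reported
#' as a marker for a cluster when `p < max_p` and `log_fc > min_logfc`.
#'
#' @param e an [expr_matrix].
#' @param labels cluster labels aligned to cells.
#' @param min_logfc,max_p marker reporting cutoffs.
#' @return data.frame with one row per (cluster, gene): `cluster`, `gene`,
#'   `log_fc`, `p_value`, `p_adj` (Bonferroni within cluster), `pct_in`,
#'   `pct_out`, `is_marker`.
#' @export
rank_markers_lrt <- function(e, labels, min_logfc = 0.25, max_p = 0.01) {
  stopifnot(inherits(e, "expr_matrix"))
  x <- as_dense(e)
  labels <- as.vector(labels)
  stopifnot(length(labels) == nrow(x))
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("need at least 2 clusters", call. = FALSE)
  if (any(table(labels) < 3)) stop("each cluster needs >= 3 cells", call. = FALSE)
  out <- vector("list", length(cl))
  for (ci in seq_along(cl)) {
    inn <- labels == cl[ci]
    xi <- x[inn, , drop = FALSE]; xo <- x[!inn, , drop = FALSE]
    skip <- colSums(xi) == 0 & colSums(xo) == 0
    stat <- pmax(2 * (bimod_ll(xi) + bimod_ll(xo) - bimod_ll(x)), 0)
    p <- pchisq(stat, df = 3, lower.tail = FALSE)
    lfc <- log(colMeans(expm1(xi)) + 1) - log(colMeans(expm1(xo)) + 1)
    tab <- data.frame(cluster = cl[ci], gene = colnames(x), log_fc = lfc,
                      p_value = p,
                      p_adj = pmin(p * sum(!skip), 1),
                      pct_in = colMeans(xi > 0), pct_out = colMeans(xo > 0),
                      stringsAsFactors = FALSE, row.names = NULL)
    tab <- tab[!skip, , drop = FALSE]
    tab$is_marker <- tab$p_value < max_p & tab$log_fc > min_logfc
    out[[ci]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cluster relatedness dendrogram
#'
#' Averages expression per cluster (over the given genes) to form signatures,
#' computes `1 - Pearson r` distances between them, and agglomerates with
#' average linkage.
#'
#' @param e an [expr_matrix].
#' @param labels cluster labels aligned to cells.
#' @param genes optional gene subset (typically HVGs).
#' @return list: `hclust` (the tree), `newick` (Newick string), `signatures`
#'   (genes x clusters matrix), `distance` (the `dist` used).
#' @export
cluster_relatedness <- function(e, labels, genes = NULL) {
  stopifnot(inherits(e, "expr_matrix"))
  x <- as_dense(e)
  if (!is.null(genes)) x <- x[, genes, drop = FALSE]
  labels <- as.vector(labels)
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("need at least 2 clusters", call. = FALSE)
  sig <- sapply(cl, function(k) colMeans(x[labels == k, , drop = FALSE]))
  colnames(sig) <- as.character(cl)
  const <- apply(sig, 2, sd) == 0
  if (any(const)) stop("constant signature for cluster(s): ",
                       paste(colnames(sig)[const], collapse = ", "),
                       call. = FALSE)
  d <- as.dist(1 - cor(sig))
  hc <- hclust(d, method = "average")
  list(hclust = hc, newick = ape::write.tree(ape::as.phylo(hc)),
       signatures = sig, distance = d)
}

#' Core cell-cycle gene sets
#'
#' The published core sets of 43 G1/S and 54 G2/M phase genes, in mouse
#' symbol casing. User-replaceable: [score_cell_cycle()] accepts any pair of
#' disjoint symbol vectors.
#'
#' @return list with character vectors `g1s` (43 symbols) and `g2m` (54).
#' @export
cell_cycle_genes <- function() {
  list(
    g1s = c("Mcm5", "Pcna", "Tyms", "Fen1", "Mcm2", "Mcm4", "Rrm1", "Ung",
            "Gins2", "Mcm6", "Cdca7", "Dtl", "Prim1", "Uhrf1", "Cenpu",
            "Hells", "Rfc2", "Rpa2", "Nasp", "Rad51ap1", "Gmnn", "Wdr76",
            "Slbp", "Ccne2", "Ubr7", "Pold3", "Msh2", "Atad2", "Rad51",
            "Rrm2", "Cdc45", "Cdc6", "Exo1", "Tipin", "Dscc1", "Blm",
            "Casp8ap2", "Usp1", "Clspn", "Pola1", "Chaf1b", "Brip1", "E2f8"),
    g2m = c("Hmgb2", "Cdk1", "Nusap1", "Ube2c", "Birc5", "Tpx2", "Top2a",
            "Ndc80", "Cks2", "Nuf2", "Cks1b", "Mki67", "Tmpo", "Cenpf",
            "Tacc3", "Pimreg", "Smc4", "Ccnb2", "Ckap2l", "Ckap2", "Aurkb",
            "Bub1", "Kif11", "Anp32e", "Tubb4b", "Gtse1", "Kif20b", "Hjurp",
            "Cdca3", "Jpt1", "Cdc20", "Ttk", "Cdc25c", "Kif2c", "Rangap1",
            "Ncapd2", "Dlgap5", "Cdca2", "Cdca8", "Ect2", "Kif23", "Hmmr",
            "Aurka", "Psrc1", "Anln", "Lbr", "Ckap5", "Cenpe", "Ctcf",
            "Nek2", "G2e3", "Gas2l3", "Cbx5", "Cenpa"))
}

#' Cell-cycle phase scoring
#'
#' For each phase gene set, the score of a cell is the mean expression of the
#' set genes minus the mean of control genes drawn (seeded) from the same
#' average-expression bins: genes are binned by their population average into
#' `n_ctrl_bins` equal-count bins and each set gene contributes
#' `n_ctrl_per_gene` draws from its bin. Phase is `G1` when neither score is
#' positive, otherwise the phase of the larger score.
#'
#' @param e an [expr_matrix].
#' @param g1s_genes,g2m_genes phase gene symbol vectors; default the packaged
#'   core sets ([cell_cycle_genes()]).
#' @param n_ctrl_bins,n_ctrl_per_gene control-gene binning constants.
#' @param seed RNG seed for the control draws.
#' @return data.frame: `cell_id`, `s_score`, `g2m_score`, `phase`.
#' @export
score_cell_cycle <- function(e, g1s_genes = NULL, g2m_genes = NULL,
                             n_ctrl_bins = 25, n_ctrl_per_gene = 100,
                             seed = 1L) {
  stopifnot(inherits(e, "expr_matrix"))
  sets <- cell_cycle_genes()
  if (is.null(g1s_genes)) g1s_genes <- sets$g1s
  if (is.null(g2m_genes)) g2m_genes <- sets$g2m
  x <- as_dense(e)
  syms <- tolower(e$gene_symbols)
  resolve <- function(set, name) {
    idx <- match(tolower(set), syms)
    found <- idx[!is.na(idx)]
    if (length(found) == 0)
      stop("no ", name, " genes present in matrix", call. = FALSE)
    if (length(found) < length(set) / 2)
      warning("fewer than half of the ", name, " genes present (",
              length(found), "/", length(set), ")")
    found
  }
  g1s_idx <- resolve(g1s_genes, "G1/S")
  g2m_idx <- resolve(g2m_genes, "G2/M")
  avg <- colMeans(x)
  ord <- order(avg, colnames(x))
  bin <- integer(length(avg))
  bin[ord] <- as.integer(cut(seq_along(ord), breaks = n_ctrl_bins,
                             labels = FALSE))
  set.seed(seed)
  score_set <- function(idx) {
    ctrl <- unlist(lapply(idx, function(g) {
      pool <- which(bin == bin[g])
      pool[sample.int(length(pool), n_ctrl_per_gene, replace = TRUE)]
    }))
    ctrl <- unique(ctrl)
    rowMeans(x[, idx, drop = FALSE]) - rowMeans(x[, ctrl, drop = FALSE])
  }
  s_score <- score_set(g1s_idx)
  g2m_score <- score_set(g2m_idx)
  phase <- ifelse(s_score <= 0 & g2m_score <= 0, "G1",
                  ifelse(s_score >= g2m_score, "S", "G2M"))
  data.frame(cell_id = rownames(x), s_score = s_score, g2m_score = g2m_score,
             phase = phase, stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-correlate cluster signatures between datasets
#'
#' Pearson correlation between every pair of cluster signatures from two
#' datasets over their shared genes; the best-matching column for each row is
#' reported.
#'
#' @param sigA,sigB genes x clusters signature matrices with gene rownames.
#' @param min_shared minimum shared gene count (error below).
#' @return list: `r` (clusters_A x clusters_B Pearson matrix), `n_shared`,
#'   `best_match` (named vector, per row of `r`).
#' @export
cross_correlate_signatures <- function(sigA, sigB, min_shared = 10) {
  shared <- intersect(rownames(sigA), rownames(sigB))
  if (length(shared) < min_shared)
    stop("only ", length(shared), " shared genes (need >= ", min_shared, ")",
         call. = FALSE)
  r <- cor(sigA[shared, , drop = FALSE], sigB[shared, , drop = FALSE])
  best <- colnames(r)[apply(r, 1, which.max)]
  names(best) <- rownames(r)
  list(r = r, n_shared = length(shared), best_match = best)
}
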