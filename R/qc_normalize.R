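#' Quality-control thresholds
#'
#' Thresholds for the two QC dialects. Droplet cells are kept when total UMI
#' and detected genes are strictly below their cutoffs and the mitochondrial
#' fraction is at most `droplet_max_mito_frac` ("no more than"). Full-length
#' cells are removed when detected genes or mitochondrial fraction strictly
#' exceed their cutoffs, after which genes expressed in fewer than
#' `min_cells_per_gene` surviving cells are dropped.
#'
#' @param droplet_max_umi,droplet_max_genes,droplet_max_mito_frac droplet
#'   cutoffs.
#' @param fulllength_max_genes,fulllength_max_mito_frac full-length cutoffs.
#' @param min_cells_per_gene full-length gene filter.
#' @return list of class `qc_params`.
#' @export
qc_params <- function(droplet_max_umi = 8000, droplet_max_genes = 2500,
                      droplet_max_mito_frac = 0.08,
                      fulllength_max_genes = 11000,
                      fulllength_max_mito_frac = 0.15,
                      min_cells_per_gene = 3) {
  p <- list(droplet_max_umi = droplet_max_umi,
            droplet_max_genes = droplet_max_genes,
            droplet_max_mito_frac = droplet_max_mito_frac,
            fulllength_max_genes = fulllength_max_genes,
            fulllength_max_mito_frac = fulllength_max_mito_frac,
            min_cells_per_gene = min_cells_per_gene)
  if (any(unlist(p) <= 0)) stop("all thresholds must be > 0", call. = FALSE)
  structure(p, class = "qc_params")
}

qc_cell_stats <- function(m) {
  tot <- Matrix::rowSums(m$counts)
  list(total = tot,
       n_genes = Matrix::rowSums(m$counts > 0),
       mito_frac = ifelse(tot > 0,
                          Matrix::rowSums(m$counts[, m$mito_flag,
                                                   drop = FALSE]) / tot, 0))
}

subset_umi <- function(m, cells = NULL, genes = NULL) {
  counts <- m$counts
  gs <- m$gene_symbols; mf <- m$mito_flag
  if (!is.null(cells)) counts <- counts[cells, , drop = FALSE]
  if (!is.null(genes)) {
    counts <- counts[, genes, drop = FALSE]
    gs <- gs[genes]; mf <- mf[genes]
  }
  umi_matrix(counts, gene_symbols = gs, mito_flag = mf)
}

#' Droplet quality control
#'
#' Keeps a cell iff total UMI `< droplet_max_umi` (strict), detected genes
#' `< droplet_max_genes` (strict) and mitochondrial fraction
#' `<= droplet_max_mito_frac`. The gene set is unchanged.
#'
#' @param m a [umi_matrix].
#' @param params a [qc_params()].
#' @return list with `matrix` (filtered [umi_matrix]) and `report`, a
#'   data.frame (`cell_id`, `total_umi`, `n_genes`, `mito_frac`, `kept`,
#'   `reason`) where `reason` is the comma-joined set of violated rules among
#'   `umi`, `genes`, `mito`.
#' @export
apply_droplet_qc <- function(m, params = qc_params()) {
  stopifnot(inherits(m, "umi_matrix"))
  if (nrow(m$counts) == 0) stop("matrix has no cells", call. = FALSE)
  st <- qc_cell_stats(m)
  bad_umi <- st$total >= params$droplet_max_umi
  bad_genes <- st$n_genes >= params$droplet_max_genes
  bad_mito <- st$mito_frac > params$droplet_max_mito_frac
  kept <- !(bad_umi | bad_genes | bad_mito)
  reason <- vapply(seq_along(kept), function(i) {
    paste(c(if (bad_umi[i]) "umi", if (bad_genes[i]) "genes",
            if (bad_mito[i]) "mito"), collapse = ",")
  }, character(1))
  report <- data.frame(cell_id = rownames(m$counts), total_umi = st$total,
                       n_genes = st$n_genes, mito_frac = st$mito_frac,
                       kept = kept, reason = reason, stringsAsFactors = FALSE,
                       row.names = NULL)
  if (!any(kept)) warning("all cells removed by droplet QC")
  list(matrix = subset_umi(m, cells = which(kept)), report = report)
}

#' Full-length quality control
#'
#' Removes a cell iff detected genes `> fulllength_max_genes` or
#' mitochondrial fraction `> fulllength_max_mito_frac` (both strict), then
#' removes genes expressed in fewer than `min_cells_per_gene` of the
#' surviving cells.
#'
#' @inheritParams apply_droplet_qc
#' @return list with `matrix`, `report` (cell phase, as in
#'   [apply_droplet_qc()] with reasons among `genes`, `mito`) and
#'   `gene_report` (data.frame: `gene_id`, `n_cells_expressing`, `kept`).
#' @export
apply_fulllength_qc <- function(m, params = qc_params()) {
  stopifnot(inherits(m, "umi_matrix"))
  if (nrow(m$counts) == 0) stop("matrix has no cells", call. = FALSE)
  st <- qc_cell_stats(m)
  bad_genes <- st$n_genes > params$fulllength_max_genes
  bad_mito <- st$mito_frac > params$fulllength_max_mito_frac
  kept <- !(bad_genes | bad_mito)
  reason <- vapply(seq_along(kept), function(i) {
    paste(c(if (bad_genes[i]) "genes", if (bad_mito[i]) "mito"),
          collapse = ",")
  }, character(1))
  report <- data.frame(cell_id = rownames(m$counts), total_umi = st$total,
                       n_genes = st$n_genes, mito_frac = st$mito_frac,
                       kept = kept, reason = reason, stringsAsFactors = FALSE,
                       row.names = NULL)
  if (!any(kept)) warning("all cells removed by full-length QC")
  kept_m <- subset_umi(m, cells = which(kept))
  n_expr <- Matrix::colSums(kept_m$counts > 0)
  gene_kept <- n_expr >= params$min_cells_per_gene
  gene_report <- data.frame(gene_id = colnames(m$counts),
                            n_cells_expressing = n_expr, kept = gene_kept,
                            stringsAsFactors = FALSE, row.names = NULL)
  list(matrix = subset_umi(kept_m, genes = which(gene_kept)),
       report = report, gene_report = gene_report)
}

#' Library-size normalization and log transform
#'
#' `value = ln(1 + count * scale_factor / cell_total)`; zeros map to zero.
#'
#' @param m a [umi_matrix] (QC applied; every cell total must be > 0).
#' @param scale_factor per-cell target total (default 10000).
#' @return an [expr_matrix].
#' @export
normalize_log <- function(m, scale_factor = 10000) {
  stopifnot(inherits(m, "umi_matrix"))
  tot <- Matrix::rowSums(m$counts)
  if (any(tot == 0))
    stop("cells with zero total counts present; apply QC first", call. = FALSE)
  v <- m$counts * (scale_factor / tot)   # sparse row scaling
  v@x <- log1p(v@x)
  expr_matrix(v, scale_factor = scale_factor, log_base = "e",
              gene_symbols = m$gene_symbols, mito_flag = m$mito_flag)
}

#' Highly variable gene selection by binned dispersion
#'
#' Computes, per gene, the mean and dispersion (variance / mean) of
#' library-size-normalized counts (pre-log), bins genes into `n_expr_bins`
#' equal-count groups by mean expression (ties broken by gene id), divides
#' each gene's dispersion by its bin's median dispersion, and selects genes
#' with mean `> min_mean` and normalized dispersion `> min_dispersion` (both
#' strict). Setting `use_raw_dispersion = TRUE` applies the dispersion cutoff
#' to the raw variance/mean ratio instead.
#'
#' @param e an [expr_matrix] from [normalize_log()].
#' @param n_expr_bins number of mean-expression bins (>= 2).
#' @param min_mean,min_dispersion selection cutoffs.
#' @param use_raw_dispersion apply the cutoff to raw rather than
#'   bin-normalized dispersion.
#' @return list with `genes` (selected gene ids) and `table` (data.frame:
#'   `gene_id`, `mean`, `dispersion`, `norm_dispersion`, `bin`, `selected`).
#' @export
select_hvg <- function(e, n_expr_bins = 20, min_mean = 0.01,
                       min_dispersion = 1.0, use_raw_dispersion = FALSE) {
  stopifnot(inherits(e, "expr_matrix"))
  if (n_expr_bins < 2) stop("n_expr_bins must be >= 2", call. = FALSE)
  # back to normalized (pre-log) counts: expm1 of the stored values
  v <- e$values
  x <- if (is(v, "sparseMatrix")) {
    v@x <- expm1(v@x); v
  } else expm1(v)
  n <- nrow(x)
  mu <- Matrix::colMeans(x)
  if (sum(mu > 0) < n_expr_bins)
    stop("fewer genes with nonzero mean than bins", call. = FALSE)
  ex2 <- Matrix::colMeans(x^2)
  v_g <- (ex2 - mu^2) * n / (n - 1)
  disp <- ifelse(mu > 0, v_g / mu, 0)
  ord <- order(mu, colnames(e$values))
  bin <- integer(length(mu))
  bin[ord] <- as.integer(cut(seq_along(ord), breaks = n_expr_bins,
                             labels = FALSE))
  bin_med <- tapply(disp, bin, median)
  med <- as.numeric(bin_med[as.character(bin)])
  if (any(med == 0)) warning("bin with zero median dispersion; its genes get",
                             " normalized dispersion 0")
  norm_disp <- ifelse(med > 0, disp / med, 0)
  crit_disp <- if (use_raw_dispersion) disp else norm_disp
  sel <- mu > min_mean & crit_disp > min_dispersion
  tab <- data.frame(gene_id = colnames(e$values), mean = mu,
                    dispersion = disp, norm_dispersion = norm_disp,
                    bin = bin, selected = sel, stringsAsFactors = FALSE,
                    row.names = NULL)
  list(genes = colnames(e$values)[sel], table = tab)
}
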