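#' UMI count matrix container
#'
#' Canonical in-memory container for droplet or full-length single-cell count
#' data: a cells x genes matrix of non-negative integer UMI (or read) counts
#' plus gene/cell identifiers and a per-gene mitochondrial flag. All on-disk
#' genes x cells inputs are transposed to this orientation at the boundary.
#'
#' @param counts cells x genes matrix of non-negative integer counts; dense or
#'   sparse (coerced to `Matrix::dgCMatrix`).
#' @param cell_ids unique character vector, one per row of `counts`.
#' @param gene_ids unique character vector, one per column of `counts`.
#' @param gene_symbols character vector of display symbols, one per gene;
#'   defaults to `gene_ids`.
#' @param mito_flag logical per gene; if `NULL`, set from `gene_symbols` using
#'   `mito_regex`.
#' @param mito_regex case-insensitive regular expression identifying
#'   mitochondrial gene symbols (default the mouse `mt-` prefix).
#'
#' @return An object of class `umi_matrix`: a list with elements `counts`
#'   (dgCMatrix, dimnames = cell/gene ids), `gene_symbols`, `mito_flag`.
#' @export
umi_matrix <- function(counts, cell_ids = rownames(counts),
                       gene_ids = colnames(counts), gene_symbols = gene_ids,
                       mito_flag = NULL, mito_regex = "^mt-") {
  if (!is(counts, "Matrix"))
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(cell_ids) || is.null(gene_ids))
    stop("cell_ids and gene_ids are required", call. = FALSE)
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids", call. = FALSE)
  if (nrow(counts) != length(cell_ids) || ncol(counts) != length(gene_ids))
    stop("count matrix dimensions do not match id lists", call. = FALSE)
  x <- counts@x
  if (length(x)) {
    if (any(!is.finite(x))) stop("counts must be finite", call. = FALSE)
    if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
    if (any(x != round(x))) stop("counts must be integers", call. = FALSE)
  }
  if (is.null(mito_flag))
    mito_flag <- grepl(mito_regex, gene_symbols, ignore.case = TRUE)
  stopifnot(length(gene_symbols) == length(gene_ids),
            length(mito_flag) == length(gene_ids))
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, gene_symbols = as.character(gene_symbols),
                 mito_flag = as.logical(mito_flag)),
            class = "umi_matrix")
}

#' @export
print.umi_matrix <- function(x, ...) {
  cat(sprintf("umi_matrix: %d cells x %d genes (%d mitochondrial), %d nonzero\n",
              nrow(x$counts), ncol(x$counts), sum(x$mito_flag),
              length(x$counts@x)))
  invisible(x)
}

#' @export
dim.umi_matrix <- function(x) dim(x$counts)

cell_ids <- function(m) rownames(if (inherits(m, "umi_matrix")) m$counts else m$values)
gene_ids <- function(m) colnames(if (inherits(m, "umi_matrix")) m$counts else m$values)

#' Normalized expression matrix container
#'
#' Holds library-size-normalized, log-transformed expression values aligned to
#' a source [umi_matrix]. Produced by [normalize_log()]; consumed by the HVG,
#' clustering, pseudotime and gating stages.
#'
#' @param values cells x genes numeric matrix of normalized log expression.
#' @param scale_factor the per-cell scaling constant used.
#' @param log_base log base tag (`"e"` for natural log).
#' @param gene_symbols,mito_flag per-gene annotation carried over from the
#'   source counts.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, scale_factor, log_base = "e",
                        gene_symbols = colnames(values),
                        mito_flag = logical(ncol(values))) {
  vals <- if (is(values, "sparseMatrix")) values@x else values
  if (any(!is.finite(vals)))
    stop("expression values must be finite", call. = FALSE)
  structure(list(values = values, scale_factor = scale_factor,
                 log_base = log_base, gene_symbols = as.character(gene_symbols),
                 mito_flag = as.logical(mito_flag)),
            class = "expr_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d cells x %d genes (scale factor %g, log base %s)\n",
              nrow(x$values), ncol(x$values), x$scale_factor, x$log_base))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# Dense numeric cells x genes matrix from either container.
as_dense <- function(m) {
  v <- if (inherits(m, "umi_matrix")) m$counts else if (inherits(m, "expr_matrix")) m$values else m
  as.matrix(v)
}

# Resolve gene symbols to column indices, case-insensitively; errors on
# missing or ambiguous symbols.
match_symbols <- function(m, symbols) {
  tab <- tolower(m$gene_symbols)
  idx <- vapply(symbols, function(s) {
    hit <- which(tab == tolower(s))
    if (length(hit) == 0L) stop("marker not found: ", s, call. = FALSE)
    if (length(hit) > 1L) stop("ambiguous marker symbol: ", s, call. = FALSE)
    hit
  }, integer(1))
  unname(idx)
}
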