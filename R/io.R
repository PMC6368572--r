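#' Read a 10x-style MTX bundle
#'
#' Reads a directory containing `matrix.mtx`, `barcodes.tsv` and
#' `features.tsv` (or `genes.tsv`), each optionally gzipped, into a
#' [umi_matrix]. The on-disk matrix follows the 10x dialect (genes x cells);
#' it is transposed on read so the in-memory orientation is always cells x
#' genes. Mitochondrial genes are flagged by symbol prefix (`mt-`,
#' case-insensitive, configurable).
#'
#' @param path directory containing the bundle.
#' @param mito_regex regular expression applied (case-insensitively) to gene
#'   symbols to set the mitochondrial flag.
#' @return A [umi_matrix].
#' @export
read_mtx_bundle <- function(path, mito_regex = "^mt-") {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  locate <- function(names) {
    for (nm in names) {
      for (ext in c("", ".gz")) {
        f <- file.path(path, paste0(nm, ext))
        if (file.exists(f)) return(f)
      }
    }
    stop("missing file in MTX bundle: ", names[1], "[.gz] under ", path,
         call. = FALSE)
  }
  mtx_file <- locate("matrix.mtx")
  bc_file <- locate("barcodes.tsv")
  ft_file <- locate(c("features.tsv", "genes.tsv"))

  m <- tryCatch(Matrix::readMM(mtx_file),
                error = function(e) stop("malformed MatrixMarket file ",
                                         mtx_file, ": ", conditionMessage(e),
                                         call. = FALSE))
  if (any(m@x != round(m@x)))
    stop("non-integer entries in ", mtx_file, call. = FALSE)
  barcodes <- readLines(bc_file)
  feats <- read.delim(ft_file, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(m) != nrow(feats))
    stop(sprintf("matrix header declares %d genes but %s has %d rows",
                 nrow(m), basename(ft_file), nrow(feats)), call. = FALSE)
  if (ncol(m) != length(barcodes))
    stop(sprintf("matrix header declares %d cells but %s has %d barcodes",
                 ncol(m), basename(bc_file), length(barcodes)), call. = FALSE)
  symbols <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  umi_matrix(Matrix::t(m), cell_ids = barcodes, gene_ids = feats[[1]],
             gene_symbols = symbols, mito_regex = mito_regex)
}

#' Write a 10x-style MTX bundle
#'
#' Inverse of [read_mtx_bundle()]: writes `matrix.mtx` (genes x cells,
#' MatrixMarket coordinate integer), `barcodes.tsv` and `features.tsv` into
#' `path`.
#'
#' @param m a [umi_matrix].
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_mtx_bundle <- function(m, path) {
  stopifnot(inherits(m, "umi_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  gx <- Matrix::t(m$counts)
  Matrix::writeMM(gx, file.path(path, "matrix.mtx"))
  writeLines(rownames(m$counts), file.path(path, "barcodes.tsv"))
  feats <- data.frame(id = colnames(m$counts), symbol = m$gene_symbols,
                      type = "Gene Expression")
  write.table(feats, file.path(path, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Writes a rectangular table with a header row, tab-separated, stable column
#' order, floats rendered with at least 6 significant digits.
#'
#' @param table a data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  out <- table
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 8, format = "g"))
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' Read a table written by [write_results()]
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  read.delim(path, stringsAsFactors = FALSE)
}
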