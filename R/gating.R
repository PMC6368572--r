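#' Median-scaled normalized UMI counts
#'
#' nUMI: each cell's counts scaled by `median(cell totals) / cell total`, so
#' the typical cell is unchanged and zeros stay zero.
#'
#' @param m a [umi_matrix] (QC applied; no zero-total cells).
#' @return a cells x genes sparse numeric matrix of nUMI values, with the
#'   gene symbols attached as attribute `"symbols"`.
#' @export
normalize_numi <- function(m) {
  stopifnot(inherits(m, "umi_matrix"))
  tot <- Matrix::rowSums(m$counts)
  if (any(tot == 0)) stop("cells with zero total counts; apply QC first",
                          call. = FALSE)
  v <- m$counts * (median(tot) / tot)
  attr(v, "symbols") <- m$gene_symbols
  v
}

#' Multi-marker gate
#'
#' A cell is gated positive iff its nUMI value is strictly above the
#' threshold for every marker (AND rule). Marker symbols are matched
#' case-insensitively; missing or ambiguous markers raise an error.
#'
#' @param numi nUMI matrix from [normalize_numi()] (or a [umi_matrix] /
#'   [expr_matrix], in which case its values are used directly).
#' @param markers character vector of marker symbols.
#' @param thresholds numeric vector of per-marker thresholds, recycled;
#'   default 0 (strictly positive).
#' @return list of class `gate_result`: `positive` (logical per cell),
#'   `fraction` (overall positive fraction), `markers`, `thresholds`.
#' @export
gate_multi <- function(numi, markers, thresholds = 0) {
  if (inherits(numi, "umi_matrix") || inherits(numi, "expr_matrix")) {
    syms <- numi$gene_symbols
    numi <- if (inherits(numi, "umi_matrix")) numi$counts else numi$values
    attr(numi, "symbols") <- syms
  }
  syms <- attr(numi, "symbols") %||% colnames(numi)
  if (any(thresholds < 0)) stop("thresholds must be >= 0", call. = FALSE)
  thresholds <- rep_len(thresholds, length(markers))
  fake <- list(gene_symbols = syms)
  idx <- match_symbols(fake, markers)
  pos <- rep(TRUE, nrow(numi))
  for (k in seq_along(idx)) {
    pos <- pos & (as.numeric(numi[, idx[k]]) > thresholds[k])
  }
  structure(list(positive = setNames(pos, rownames(numi)),
                 fraction = mean(pos), markers = markers,
                 thresholds = thresholds),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("gate [%s > %s]: %d / %d cells positive (%.2f%%)\n",
              paste(x$markers, collapse = " & "),
              paste(x$thresholds, collapse = ","),
              sum(x$positive), length(x$positive), 100 * x$fraction))
  invisible(x)
}

#' Gated-cell enrichment by cluster
#'
#' Fraction of gated cells within each cluster, ranked descending.
#'
#' @param gate a `gate_result` from [gate_multi()].
#' @param labels cluster labels aligned to the gated cells.
#' @return data.frame (`cluster`, `n_cells`, `n_positive`, `fraction`),
#'   ordered by decreasing fraction.
#' @export
enrichment_by_cluster <- function(gate, labels) {
  stopifnot(inherits(gate, "gate_result"))
  labels <- as.vector(labels)
  stopifnot(length(labels) == length(gate$positive))
  cl <- sort(unique(labels))
  tab <- data.frame(
    cluster = cl,
    n_cells = as.integer(table(factor(labels, cl))),
    n_positive = as.integer(tapply(gate$positive, factor(labels, cl), sum)),
    stringsAsFactors = FALSE)
  tab$fraction <- tab$n_positive / tab$n_cells
  tab[order(-tab$fraction), , drop = FALSE]
}

#' Detect hybrid bins along a joint pseudotime
#'
#' For a joint trajectory over exactly two lineages, computes per-bin
#' lineage fractions and flags a bin as hybrid when its minority-lineage
#' fraction is at least `balance_min` ("almost equal mixing"). Flags are
#' invariant to swapping the lineage labels.
#'
#' @param t pseudotime aligned to cells.
#' @param lineage two-level label vector.
#' @param n_bins number of equal-width bins.
#' @param balance_min minority-fraction cutoff for flagging.
#' @return data.frame per bin: `bin`, `n_cells`, one fraction column per
#'   lineage, `minority_frac`, `hybrid`.
#' @export
detect_hybrid_bins <- function(t, lineage, n_bins = 10, balance_min = 0.4) {
  lineage <- as.vector(lineage)
  levs <- sort(unique(lineage))
  if (length(levs) != 2)
    stop("exactly 2 lineage labels required, got ", length(levs),
         call. = FALSE)
  comp <- bin_composition(lineage, t, n_bins)
  minority <- apply(comp$fractions, 1, min)
  minority[comp$counts == 0] <- 0
  out <- data.frame(bin = seq_len(n_bins), n_cells = as.integer(comp$counts),
                    comp$fractions, minority_frac = minority,
                    hybrid = minority >= balance_min & comp$counts > 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[3:4] <- levs
  out
}

#' Positive-cell percentage from counts
#'
#' @param n_pos,n_total non-negative counts with `n_pos <= n_total`,
#'   `n_total > 0`.
#' @return list: `percent` (`100 * n_pos / n_total`), `percent_rounded`
#'   (nearest integer), `n_pos`, `n_total`.
#' @export
fraction_positive <- function(n_pos, n_total) {
  if (n_total <= 0) stop("n_total must be > 0", call. = FALSE)
  if (n_pos < 0 || n_pos > n_total)
    stop("need 0 <= n_pos <= n_total", call. = FALSE)
  pct <- 100 * n_pos / n_total
  list(percent = pct, percent_rounded = round(pct), n_pos = n_pos,
       n_total = n_total)
}
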