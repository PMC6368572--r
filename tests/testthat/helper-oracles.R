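# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths.

# Tukey trimean via stats::quantile (type 7)
brute_trimean <- function(x) {
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  (q[1] + 2 * q[2] + q[3]) / 4
}

# naive average-linkage agglomeration on a symmetric distance matrix;
# returns the sequence of merge heights
brute_average_linkage_heights <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n + n - 1)
  active[(n + 1):(2 * n - 1)] <- FALSE
  heights <- numeric(n - 1)
  idx <- seq_len(n)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(members)) {
      if (is.null(members[[a]])) next
      for (b in seq_along(members)) {
        if (b <= a || is.null(members[[b]])) next
        d <- mean(D[members[[a]], members[[b]]])
        if (d < bestd) { bestd <- d; best <- c(a, b) }
      }
    }
    heights[step] <- bestd
    members[[best[1]]] <- c(members[[best[1]]], members[[best[2]]])
    members[best[2]] <- list(NULL)
  }
  heights
}

# wrap a dense cells x genes value matrix as an expr_matrix
toy_expr <- function(x, symbols = colnames(x)) {
  if (is.null(rownames(x))) rownames(x) <- sprintf("c%03d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("g%03d", seq_len(ncol(x)))
  if (is.null(symbols)) symbols <- colnames(x)
  expr_matrix(x, scale_factor = 1e4, gene_symbols = symbols)
}

# adjusted Rand index (independent of mclust, for use anywhere)
rand_adjusted <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}
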