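#' Configuration for the synthetic scRNA-seq generator
#'
#' Bundles and validates all knobs of [simulate_counts()]. The generator
#' emulates the statistical structure the downstream analyses assume:
#' negative-binomial UMI counts over distinct cell populations with marker
#' programs, a latent pseudotime in `[0, 1]` with planted pseudotime-dependent
#' genes, a planted fraction of hybrid dual-signature cells, and a controlled
#' mitochondrial count share.
#'
#' @param n_cells,n_genes matrix dimensions (both >= 1).
#' @param n_types number of cell populations (>= 1).
#' @param markers_per_type marker genes boosted per population.
#' @param marker_fold fold-change of a population's markers over baseline.
#' @param marker_off multiplier applied to a population's markers in every
#'   other population (markers are population-specific, so near zero
#'   elsewhere).
#' @param lib_size_mean expected UMI total per cell.
#' @param lib_size_shape gamma shape of the per-cell library-size multiplier;
#'   larger is less variable.
#' @param nb_dispersion negative-binomial dispersion `d` in
#'   `Var = mu + mu^2 * d`; 0 gives Poisson counts.
#' @param frac_dep_genes fraction of genes planted pseudotime-dependent.
#' @param dep_amplitude effect size of dependent genes on the natural-log
#'   mean scale.
#' @param dep_shape temporal shape of dependent genes: `"logistic"` (monotone
#'   switch), `"bump"` (transient Gaussian pulse) or `"linear"`.
#' @param dep_t0 optional vector of inflection/peak times for the dependent
#'   genes (recycled); by default drawn Uniform(0.2, 0.8) to keep dynamics
#'   inside the observed pseudotime range. Supplying e.g. `c(0.3, 0.7)`
#'   plants two temporal waves.
#' @param frac_hybrid fraction of cells given a dual-lineage signature (a
#'   convex mix of two population programs).
#' @param hybrid_mix_alpha symmetric Beta parameter for the hybrid mixing
#'   weight.
#' @param frac_mito_genes fraction of genes flagged mitochondrial.
#' @param mito_frac target share of each cell's counts on mitochondrial genes.
#' @param lineage_time `"uniform"` draws pseudotime independently of lineage;
#'   `"staggered"` (two populations only) places lineage 1 early and lineage 2
#'   late with an overlap window in the middle.
#' @param time_overlap width of the shared pseudotime window under
#'   `"staggered"`.
#' @param seed RNG seed; identical configs (including seed) give identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 2000, n_genes = 500, n_types = 4,
                       markers_per_type = 10, marker_fold = 8,
                       marker_off = 0.005,
                       lib_size_mean = 3000, lib_size_shape = 10,
                       nb_dispersion = 0.1,
                       frac_dep_genes = 0, dep_amplitude = 2,
                       dep_shape = c("logistic", "bump", "linear"),
                       dep_t0 = NULL,
                       frac_hybrid = 0, hybrid_mix_alpha = 5,
                       frac_mito_genes = 0.02, mito_frac = 0.05,
                       lineage_time = c("uniform", "staggered"),
                       time_overlap = 0.2, seed = 1L) {
  dep_shape <- match.arg(dep_shape)
  lineage_time <- match.arg(lineage_time)
  fracs <- c(frac_dep_genes = frac_dep_genes, frac_hybrid = frac_hybrid,
             frac_mito_genes = frac_mito_genes, mito_frac = mito_frac)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (n_cells < 1 || n_genes < 1)
    stop("n_cells and n_genes must be >= 1", call. = FALSE)
  if (n_types < 1) stop("n_types must be >= 1", call. = FALSE)
  if (lib_size_mean <= 0) stop("lib_size_mean must be > 0", call. = FALSE)
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  if (frac_dep_genes > 0 && frac_dep_genes * n_genes < 1)
    stop("frac_dep_genes * n_genes < 1: no whole dependent gene to plant",
         call. = FALSE)
  if (lineage_time == "staggered" && n_types != 2)
    stop("staggered pseudotime requires exactly 2 populations", call. = FALSE)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_types = as.integer(n_types),
                 markers_per_type = as.integer(markers_per_type),
                 marker_fold = marker_fold, marker_off = marker_off,
                 lib_size_mean = lib_size_mean,
                 lib_size_shape = lib_size_shape, nb_dispersion = nb_dispersion,
                 frac_dep_genes = frac_dep_genes, dep_amplitude = dep_amplitude,
                 dep_shape = dep_shape, dep_t0 = dep_t0,
                 frac_hybrid = frac_hybrid,
                 hybrid_mix_alpha = hybrid_mix_alpha,
                 frac_mito_genes = frac_mito_genes, mito_frac = mito_frac,
                 lineage_time = lineage_time, time_overlap = time_overlap,
                 seed = as.integer(seed)),
            class = "sim_config")
}

dep_shape_fun <- function(shape) {
  switch(shape,
         logistic = function(t, t0, w) 1 / (1 + exp(-(t - t0) / w)),
         bump = function(t, t0, w) exp(-(t - t0)^2 / (2 * w^2)),
         linear = function(t, t0, w) t)
}

#' Simulate a UMI count matrix with full ground truth
#'
#' Draws negative-binomial (gamma-Poisson) counts, `Var = mu + mu^2 * d`, over
#' `n_types` cell populations. Each population boosts its own marker genes;
#' hybrid cells mix the mean programs (not the counts) of two populations with
#' a Beta-distributed weight; planted pseudotime-dependent genes modulate
#' their log mean along a latent pseudotime; mitochondrial-flagged genes are
#' rescaled so their expected count share per cell equals `mito_frac`.
#' Per-cell gene means are renormalized so expected totals follow the
#' gamma-distributed library size.
#'
#' @param config a [sim_config()].
#' @return A list with elements `matrix` (a [umi_matrix]), `cell_meta` (a
#'   data.frame: `cell_id`, `lineage`, `pseudotime`, `is_hybrid`) and `truth`
#'   (ground-truth record: dependent genes and their dynamics parameters,
#'   marker genes per population, hybrid cell ids and mixing weights, the
#'   configuration).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nc <- config$n_cells; ng <- config$n_genes; K <- config$n_types

  gene_ids <- sprintf("gene%04d", seq_len(ng))
  n_mito <- round(config$frac_mito_genes * ng)
  mito_idx <- if (n_mito > 0) seq_len(n_mito) else integer(0)
  symbols <- gene_ids
  symbols[mito_idx] <- sprintf("mt-%s", gene_ids[mito_idx])
  cell_ids_ <- sprintf("cell%05d", seq_len(nc))

  # baseline relative expression, log-normal across genes
  base_w <- stats::rlnorm(ng, meanlog = 0, sdlog = 1)

  # marker genes per population, drawn outside the mitochondrial block
  free <- setdiff(seq_len(ng), mito_idx)
  n_mark <- K * config$markers_per_type
  if (n_mark > length(free))
    stop("not enough non-mitochondrial genes for the marker programs",
         call. = FALSE)
  mark_idx <- if (n_mark > 0) sample(free, n_mark) else integer(0)
  # lineage markers are well-expressed genes; keep them detectable
  if (n_mark > 0) base_w[mark_idx] <- pmax(base_w[mark_idx], median(base_w))
  marker_genes <- if (n_mark > 0) {
    split(mark_idx, rep(seq_len(K), each = config$markers_per_type))
  } else rep(list(integer(0)), K)

  # pseudotime-dependent genes, outside markers and mito
  n_dep <- round(config$frac_dep_genes * ng)
  dep_pool <- setdiff(free, mark_idx)
  if (n_dep > length(dep_pool))
    stop("not enough free genes to plant dependent genes", call. = FALSE)
  dep_idx <- if (n_dep > 0) sort(sample(dep_pool, n_dep)) else integer(0)
  # planted genes sit at the median baseline: detectable, equal footing,
  # and a small share of total counts so their planted dynamics do not
  # skew per-cell composition
  if (n_dep > 0) base_w[dep_idx] <- median(base_w)
  dep_t0 <- if (is.null(config$dep_t0)) runif(n_dep, 0.2, 0.8) else
    rep_len(config$dep_t0, n_dep)
  dep_w <- switch(config$dep_shape,
                  logistic = runif(n_dep, 0.05, 0.1),
                  bump = runif(n_dep, 0.08, 0.15),
                  linear = rep(1, n_dep))
  shape_f <- dep_shape_fun(config$dep_shape)

  # cell-level latent structure
  lineage <- sample.int(K, nc, replace = TRUE)
  if (config$lineage_time == "staggered") {
    ov <- config$time_overlap
    t_true <- ifelse(lineage == 1L,
                     runif(nc, 0, 0.5 + ov / 2),
                     runif(nc, 0.5 - ov / 2, 1))
  } else {
    t_true <- runif(nc)
  }
  n_hyb <- round(config$frac_hybrid * nc)
  hyb_idx <- if (n_hyb > 0) sort(sample.int(nc, n_hyb)) else integer(0)
  hyb_w <- rbeta(n_hyb, config$hybrid_mix_alpha, config$hybrid_mix_alpha)
  hyb_partner <- if (K > 1 && n_hyb > 0) {
    vapply(hyb_idx, function(i) {
      cands <- setdiff(seq_len(K), lineage[i])
      cands[sample.int(length(cands), 1L)]
    }, integer(1))
  } else integer(0)

  # population mean programs: own markers boosted, foreign markers nearly
  # silent (marker genes are population-specific, like Lyz2 in myeloid cells)
  prog <- matrix(rep(base_w, K), nrow = K, byrow = TRUE)
  for (k in seq_len(K)) {
    prog[k, mark_idx] <- prog[k, mark_idx] * config$marker_off
    own <- marker_genes[[k]]
    prog[k, own] <- base_w[own] * config$marker_fold
  }

  w_mat <- prog[lineage, , drop = FALSE]
  if (n_hyb > 0) {
    w_mat[hyb_idx, ] <- hyb_w * prog[lineage[hyb_idx], , drop = FALSE] +
      (1 - hyb_w) * prog[hyb_partner, , drop = FALSE]
  }

  # pseudotime modulation of the log mean
  if (n_dep > 0) {
    for (j in seq_len(n_dep)) {
      f <- shape_f(t_true, dep_t0[j], dep_w[j])
      # centered so the planted effects do not skew per-cell totals
      w_mat[, dep_idx[j]] <- w_mat[, dep_idx[j]] *
        exp(config$dep_amplitude * (f - 0.5))
    }
  }

  # pin the mitochondrial share of each cell's expected counts
  if (n_mito > 0 && config$mito_frac > 0) {
    mito_sum <- rowSums(w_mat[, mito_idx, drop = FALSE])
    rest_sum <- rowSums(w_mat) - mito_sum
    scale_m <- config$mito_frac / (1 - config$mito_frac) * rest_sum / mito_sum
    w_mat[, mito_idx] <- w_mat[, mito_idx, drop = FALSE] * scale_m
  }

  # renormalize per cell and apply gamma library sizes
  lib <- rgamma(nc, shape = config$lib_size_shape,
                scale = config$lib_size_mean / config$lib_size_shape)
  mu <- w_mat / rowSums(w_mat) * lib

  counts <- if (config$nb_dispersion > 0) {
    matrix(rnbinom(nc * ng, size = 1 / config$nb_dispersion, mu = mu), nc, ng)
  } else {
    matrix(rpois(nc * ng, lambda = mu), nc, ng)
  }

  m <- umi_matrix(counts, cell_ids = cell_ids_, gene_ids = gene_ids,
                  gene_symbols = symbols,
                  mito_flag = seq_len(ng) %in% mito_idx)
  meta <- data.frame(cell_id = cell_ids_,
                     lineage = paste0("L", lineage),
                     pseudotime = t_true,
                     is_hybrid = seq_len(nc) %in% hyb_idx,
                     stringsAsFactors = FALSE)
  truth <- list(
    dep_gene_ids = gene_ids[dep_idx],
    dep_params = data.frame(gene = gene_ids[dep_idx],
                            amplitude = rep(config$dep_amplitude,
                                            length.out = n_dep),
                            t0 = dep_t0, width = dep_w,
                            shape = rep(config$dep_shape, length.out = n_dep),
                            stringsAsFactors = FALSE),
    marker_genes = lapply(marker_genes, function(i) gene_ids[i]),
    hybrid_cell_ids = cell_ids_[hyb_idx],
    hybrid_weight = hyb_w,
    hybrid_partner = if (n_hyb > 0) paste0("L", hyb_partner) else character(0),
    lineage = setNames(paste0("L", lineage), cell_ids_),
    pseudotime = setNames(t_true, cell_ids_),
    config = config)
  list(matrix = m, cell_meta = meta, truth = truth)
}

#' Default transcription kinetics for the splicing simulator
#'
#' One row per gene: transcription rate when on (`alpha_on`), splicing rate
#' (`beta`), degradation rate (`gamma`), switch time on the pseudotime axis
#' (`t_switch`) and regime (`mode`): `"steady"` genes transcribe throughout
#' and sit at the fixed point, `"induced"` genes switch on at `t_switch`
#' starting from zero, `"repressed"` genes sit at steady state until
#' `t_switch` and then shut off.
#'
#' @param n_genes number of genes.
#' @param mode regime for every gene, recycled.
#' @param seed RNG seed.
#' @return data.frame of kinetic parameters.
#' @export
make_kinetics <- function(n_genes, mode = "steady", seed = 1L) {
  set.seed(seed)
  data.frame(gene = sprintf("gene%04d", seq_len(n_genes)),
             alpha_on = runif(n_genes, 20, 100),
             beta = runif(n_genes, 4, 8),
             gamma = runif(n_genes, 1, 4),
             t_switch = runif(n_genes, 0.2, 0.5),
             mode = rep(mode, length.out = n_genes),
             stringsAsFactors = FALSE)
}

# closed-form solution of du/dt = alpha(t) - beta u, ds/dt = beta u - gamma s
# for a step alpha; tau is time since the switch (or since 0 for steady)
splice_ode_solution <- function(tau, alpha, beta, gamma, mode) {
  if (abs(gamma - beta) < 1e-8) gamma <- gamma + 1e-6
  tau <- pmax(tau, 0)
  if (mode == "steady") {
    u <- rep(alpha / beta, length(tau))
    s <- rep(alpha / gamma, length(tau))
  } else if (mode == "induced") {
    u <- alpha / beta * (1 - exp(-beta * tau))
    s <- alpha / gamma * (1 - exp(-gamma * tau)) -
      alpha / (gamma - beta) * (exp(-beta * tau) - exp(-gamma * tau))
  } else if (mode == "repressed") {
    u0 <- alpha / beta; s0 <- alpha / gamma
    u <- u0 * exp(-beta * tau)
    s <- s0 * exp(-gamma * tau) +
      beta * u0 * (exp(-beta * tau) - exp(-gamma * tau)) / (gamma - beta)
  } else stop("unknown kinetic mode: ", mode, call. = FALSE)
  list(u = u, s = s)
}

#' Simulate paired spliced/unspliced count matrices
#'
#' Evaluates the two-stage transcription/splicing/degradation model
#' `du/dt = alpha(t) - beta*u`, `ds/dt = beta*u - gamma*s` in closed form at
#' each cell's latent pseudotime (with a step transcription rate per
#' [make_kinetics()]) and samples Poisson counts around `scale * u` and
#' `scale * s`.
#'
#' @param config a [sim_config()]; `n_cells`, `n_genes` and `seed` are used.
#' @param kinetics kinetic parameter table as from [make_kinetics()];
#'   defaults to steady-state kinetics for all genes.
#' @param scale count scale applied to molecular abundances before Poisson
#'   sampling.
#' @return A list with `spliced` and `unspliced` (both [umi_matrix]) and
#'   `truth` (pseudotime per cell, kinetics table, noise-free `u` and `s`
#'   matrices).
#' @export
simulate_spliced_unspliced <- function(config, kinetics = NULL, scale = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(kinetics)) kinetics <- make_kinetics(config$n_genes,
                                                   seed = config$seed)
  if (nrow(kinetics) != config$n_genes)
    stop("kinetics must have one row per gene", call. = FALSE)
  if (any(kinetics$gamma <= 0)) stop("gamma must be > 0", call. = FALSE)
  if (any(kinetics$beta <= 0)) stop("beta must be > 0", call. = FALSE)
  set.seed(config$seed)
  nc <- config$n_cells; ng <- config$n_genes
  t_true <- runif(nc)
  U <- matrix(0, nc, ng); S <- matrix(0, nc, ng)
  for (g in seq_len(ng)) {
    k <- kinetics[g, ]
    tau <- if (k$mode == "steady") t_true else t_true - k$t_switch
    sol <- splice_ode_solution(tau, k$alpha_on, k$beta, k$gamma, k$mode)
    U[, g] <- sol$u; S[, g] <- sol$s
  }
  us <- matrix(rpois(nc * ng, lambda = scale * U), nc, ng)
  ss <- matrix(rpois(nc * ng, lambda = scale * S), nc, ng)
  ids <- sprintf("cell%05d", seq_len(nc))
  gids <- kinetics$gene
  list(spliced = umi_matrix(ss, cell_ids = ids, gene_ids = gids),
       unspliced = umi_matrix(us, cell_ids = ids, gene_ids = gids),
       truth = list(pseudotime = setNames(t_true, ids), kinetics = kinetics,
                    u_mean = U, s_mean = S, scale = scale, config = config))
}

#' Construct a QC boundary-case fixture
#'
#' Builds a small count matrix whose cells deliberately probe every
#' quality-control rule of both dialects — droplet (total UMI, detected
#' genes, mitochondrial fraction) and full-length (detected genes,
#' mitochondrial fraction, minimum cells per gene) — including exact boundary
#' cells (total UMI exactly at the cutoff, mitochondrial fraction exactly at
#' the cutoff, a gene expressed in exactly the minimum number of surviving
#' cells, and a gene pushed below the minimum by a cell that itself fails
#' QC). The truth record carries per-cell expected pass/fail labels with
#' reasons for each dialect and the expected full-length gene-filter outcome.
#'
#' @param seed unused placeholder for API symmetry; the fixture is
#'   deterministic.
#' @return list with `matrix` (a [umi_matrix]) and `truth`.
#' @export
make_qc_fixture <- function(seed = 1L) {
  ng <- 12005L
  n_mito <- 5L
  gene_ids <- c(sprintf("mt-gene%05d", seq_len(n_mito)),
                sprintf("gene%05d", seq((n_mito + 1), ng)))
  mito <- seq_len(n_mito)

  rows <- list(); cells <- character(0)
  add_cell <- function(id, gene_index, count) {
    rows[[length(rows) + 1L]] <<- data.frame(cell = id, gene = gene_index,
                                             count = count)
    cells <<- c(cells, id)
  }

  core <- 6:295            # shared by all normal cells
  # 20 normal cells: 300 genes, total 2000, 2% mito
  for (j in seq_len(20)) {
    private <- 3000 + (j - 1) * 10 + 1:10
    genes <- c(mito[1:2], core, private)          # 302 genes
    cnt <- c(20, 20, rep(6, length(core)), rep(1, 10))
    cnt[3] <- cnt[3] + (2000 - sum(cnt))          # pin the total at 2000
    add_cell(sprintf("norm%02d", j), genes, cnt)
  }
  # total UMI exactly 8000 (droplet removes; strict <) vs 7999 (kept)
  add_cell("umi_eq", 400:899, rep(16, 500))
  add_cell("umi_under", 400:899, c(rep(16, 499), 15))
  # detected genes exactly 2500 (droplet removes) vs 2499 (kept)
  add_cell("genes_eq", 400:2899, rep(1, 2500))
  add_cell("genes_under", 400:2898, rep(1, 2499))
  # mito fraction exactly 8% (droplet keeps; "no more than") vs 10% (removed)
  add_cell("mito_eq", c(mito[1:2], 6:235), c(40, 40, rep(4, 230)))
  add_cell("mito_over", c(mito[1:2], 6:230), c(50, 50, rep(4, 225)))
  # full-length violations: > 11000 genes; > 15% mito
  add_cell("fl_genes_over", 1000:12000, rep(1, 11001))
  add_cell("fl_mito_over", c(mito[1:2], 6:205), c(100, 100, rep(4, 200)))
  # gene-filter probes: expressed in exactly 3 survivors (kept) and in 3
  # cells of which one fails cell-QC (removed: only 2 survive)
  add_cell("norm01", 12001L, 1L); add_cell("norm02", 12001L, 1L)
  add_cell("norm03", 12001L, 1L)
  add_cell("norm04", 12002L, 1L); add_cell("norm05", 12002L, 1L)
  add_cell("fl_genes_over", 12002L, 1L)

  trip <- do.call(rbind, rows)
  cells <- unique(cells)
  ci <- match(trip$cell, cells)
  counts <- Matrix::sparseMatrix(i = ci, j = trip$gene, x = trip$count,
                                 dims = c(length(cells), ng))
  m <- umi_matrix(counts, cell_ids = cells, gene_ids = gene_ids,
                  mito_flag = seq_len(ng) %in% mito)

  tot <- Matrix::rowSums(m$counts)
  ndet <- Matrix::rowSums(m$counts > 0)
  mfrac <- Matrix::rowSums(m$counts[, mito, drop = FALSE]) / tot
  droplet_reason <- vapply(seq_along(cells), function(i) {
    paste(c(if (tot[i] >= 8000) "umi", if (ndet[i] >= 2500) "genes",
            if (mfrac[i] > 0.08) "mito"), collapse = ",")
  }, character(1))
  fl_reason <- vapply(seq_along(cells), function(i) {
    paste(c(if (ndet[i] > 11000) "genes", if (mfrac[i] > 0.15) "mito"),
          collapse = ",")
  }, character(1))
  fl_survive <- fl_reason == ""
  gene_cells <- Matrix::colSums(m$counts[fl_survive, , drop = FALSE] > 0)
  truth <- list(
    droplet = data.frame(cell_id = cells, pass = droplet_reason == "",
                         reason = droplet_reason, stringsAsFactors = FALSE),
    fulllength = data.frame(cell_id = cells, pass = fl_survive,
                            reason = fl_reason, stringsAsFactors = FALSE),
    fulllength_gene_kept = setNames(gene_cells >= 3, gene_ids))
  list(matrix = m, truth = truth)
}
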