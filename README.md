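# fibrotraj

Trajectory, marker-gating and RNA-velocity analysis for wound-fibroblast
single-cell RNA-seq.

Healing skin wounds contain a heterogeneous fibroblast compartment:
subpopulations of extracellular-matrix-producing and contractile
(myofibroblast) cells, ordered along differentiation trajectories, and —
unexpectedly — rare *hybrid* cells that co-express myeloid markers such as
*Lyz2* together with fibroblast/contractile markers (*Col12a1*, *Acta2*,
*Tagln*), consistent with myeloid-to-fibroblast conversion. `fibrotraj`
provides the computational toolkit for this kind of analysis: it is aimed at
computational biologists who have UMI count matrices (10x-style MTX bundles
or dense tables) plus, optionally, a pseudotime and a 2D embedding from
their favourite trajectory tool, and who want reproducible, tested
implementations of the downstream statistics.

## What it computes

**The central statistic** is a permutation test for pseudotime-dependent
gene expression. For gene $g$ with log-normalized expression $x_{g}$ and
cell pseudotime $t \in [0,1]$:

1. divide $[\min t, \max t]$ into $B = 10$ equal-width bins;
2. summarize each bin by the Tukey trimean
   $\mathrm{TM} = (Q_1 + 2Q_2 + Q_3)/4$;
3. smooth the $B$-point profile with a natural cubic regression spline
   (5 fitted parameters);
4. score the gene by $\sigma_g$, the standard deviation (denominator $B$)
   of the smoothed profile;
5. build a null by permuting the cell-to-pseudotime assignment $P = 1000$
   times (one shared, seeded permutation set) and recomputing
   $\sigma_g^{(p)}$; then
   $p_g = \#\{\sigma_g^{(p)} \ge \sigma_g\} / P$ (no add-one correction,
   so Bonferroni across genes remains reachable);
6. call gene $g$ pseudotime-dependent iff $\sigma_g > 0.5$ and
   $P \cdot G$-corrected $p_g < \alpha = 0.01$;
7. cluster the significant genes' z-scored profiles (average linkage,
   $1 - r$ distance) into temporal programs `pC1..pCk`, ordered by peak
   time.

Around it sit the standard stages, each at documented boundary semantics:
droplet QC (keep iff UMI < 8000, genes < 2500, mitochondrial fraction
≤ 8%) and full-length QC (drop iff genes > 11,000 or mito > 15%, then drop
genes in < 3 surviving cells); log library-size normalization; binned
dispersion HVG selection (mean > 0.01, bin-normalized dispersion > 1.0);
PCA → shared-nearest-neighbour graph → Louvain clustering; bimodal
likelihood-ratio marker tests (p < 0.01, logFC > 0.25); average-linkage
cluster dendrograms on $1-r$; cell-cycle scoring against
expression-matched control genes (43 G1/S + 54 G2/M core sets shipped);
strict-AND multi-marker gating on median-scaled nUMI with per-cluster
enrichment and hybrid-bin detection; and steady-state RNA velocity
$v = u - \gamma s$ with $\gamma$ fit through the origin on the extreme 2%
quantiles of kNN-pooled ($k = 100$) spliced expression, projected onto a 2D
embedding via a correlation-kernel transition scheme (`n_sight = 3500`).

A fully seeded synthetic-data generator (`simulate_counts`,
`simulate_spliced_unspliced`, `make_qc_fixture`) plants populations, marker
programs, pseudotime-dependent genes, hybrid cells, mitochondrial content
and splicing kinetics with complete ground truth, so every claim above is
tested by parameter recovery.

## Worked example

```r
library(fibrotraj)

cfg <- sim_config(n_cells = 1000, n_genes = 300, n_types = 2,
                  markers_per_type = 5, frac_dep_genes = 0.1,
                  dep_amplitude = 2, frac_hybrid = 0.11, seed = 42)
sim <- simulate_counts(cfg)
sim$matrix
#> umi_matrix: 1000 cells x 300 genes (6 mitochondrial), 268552 nonzero

qc <- apply_droplet_qc(sim$matrix)
e  <- normalize_log(qc$matrix)   # 998 of 1000 cells pass droplet QC
tt <- sim$truth$pseudotime[rownames(qc$matrix$counts)]

fit <- test_pseudotime_dependence(e, tt, n_perms = 200, seed = 1)
head(fit$results[order(-fit$results$sd_obs), ], 3)
#>         gene sd_obs p_perm p_bonf significant
#> 185 gene0185  0.807      0      0        TRUE
#> 119 gene0119  0.794      0      0        TRUE
#> 129 gene0129  0.773      0      0        TRUE
```

30 of 300 genes are called pseudotime-dependent — exactly the 30 planted
ones. `sd_obs` is the SD of the smoothed trimean profile in log-normalized
units; `p_perm = 0` means the observed profile varied more than all 200
permuted reassignments, and `p_bonf` is the Bonferroni-corrected value the
significance call uses (together with `sd_obs > 0.5`).

```r
numi <- normalize_numi(qc$matrix)
mks  <- c(sim$truth$marker_genes[[1]][1:2], sim$truth$marker_genes[[2]][1:2])
gate_multi(numi, mks)
#> gate [gene0106 & gene0204 & gene0030 & gene0086 > 0,0,0,0]:
#>   114 / 998 cells positive (11.42%)
```

The quadruple gate recovers the planted 11% hybrid fraction. Count-based
worked examples use plain arithmetic:

```r
fraction_positive(77, 1293)$percent   # 5.955... -> reported as ~6%
```

## Layout

* `R/`, `src/` — implementation (R plus a small C++ permutation kernel)
* `tests/testthat/` — unit, property and end-to-end recovery tests
* `vignettes/fibrotraj-methods.Rmd` — the methods notes: model choices,
  boundary semantics, generator design, limitations
* `scripts/acceptance.R` — reproduction script (above)
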