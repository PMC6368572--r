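#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Type-7 (linear interpolation) quantile of a sorted buffer.
static double quantile7(const std::vector<double>& x, double p) {
    const int n = x.size();
    if (n == 1) return x[0];
    double h = (n - 1) * p;
    int lo = (int)std::floor(h);
    double frac = h - lo;
    if (lo + 1 >= n) return x[n - 1];
    return x[lo] * (1.0 - frac) + x[lo + 1] * frac;
}

// Tukey trimean (Q1 + 2*Q2 + Q3)/4 of a buffer; sorts in place.
static double trimean(std::vector<double>& buf) {
    std::sort(buf.begin(), buf.end());
    double q1 = quantile7(buf, 0.25);
    double q2 = quantile7(buf, 0.50);
    double q3 = quantile7(buf, 0.75);
    return (q1 + 2.0 * q2 + q3) / 4.0;
}

// Replace NaN entries (empty bins) by linear interpolation between the
// nearest non-empty bins; edge bins take the nearest non-empty value.
static void fill_empty(std::vector<double>& prof) {
    const int nb = prof.size();
    for (int b = 0; b < nb; ++b) {
        if (!std::isnan(prof[b])) continue;
        int lo = b - 1;
        while (lo >= 0 && std::isnan(prof[lo])) --lo;
        int hi = b + 1;
        while (hi < nb && std::isnan(prof[hi])) ++hi;
        if (lo >= 0 && hi < nb) {
            double w = (double)(b - lo) / (double)(hi - lo);
            prof[b] = prof[lo] * (1.0 - w) + prof[hi] * w;
        } else if (lo >= 0) {
            prof[b] = prof[lo];
        } else if (hi < nb) {
            prof[b] = prof[hi];
        }
    }
}

// Per-bin Tukey trimean profiles for every gene (column) of expr.
// expr: cells x genes; bin: 1-based bin index per cell.
// Empty bins are linearly interpolated from neighbours.
// [[Rcpp::export]]
NumericMatrix cpp_binned_trimean(NumericMatrix expr, IntegerVector bin, int n_bins) {
    const int n_cells = expr.nrow(), n_genes = expr.ncol();
    if (bin.size() != n_cells) stop("bin index length must equal number of cells");
    std::vector< std::vector<int> > idx(n_bins);
    for (int i = 0; i < n_cells; ++i) {
        int b = bin[i] - 1;
        if (b < 0 || b >= n_bins) stop("bin index out of range");
        idx[b].push_back(i);
    }
    NumericMatrix out(n_bins, n_genes);
    std::vector<double> buf, prof(n_bins);
    for (int g = 0; g < n_genes; ++g) {
        for (int b = 0; b < n_bins; ++b) {
            const std::vector<int>& ids = idx[b];
            if (ids.empty()) { prof[b] = NAN; continue; }
            buf.resize(ids.size());
            for (size_t k = 0; k < ids.size(); ++k) buf[k] = expr(ids[k], g);
            prof[b] = trimean(buf);
        }
        fill_empty(prof);
        for (int b = 0; b < n_bins; ++b) out(b, g) = prof[b];
    }
    return out;
}

// Permutation-null SD statistics for the pseudotime-dependence test.
// For each row of perm_bins (a permuted 1-based bin assignment), computes the
// per-gene trimean profile, smooths it with the hat matrix H (n_bins x
// n_bins), and returns the population SD (denominator n_bins) of the smoothed
// profile. Result: n_perms x n_genes.
// [[Rcpp::export]]
NumericMatrix cpp_perm_profile_sd(NumericMatrix expr, IntegerMatrix perm_bins,
                                  NumericMatrix H) {
    const int n_cells = expr.nrow(), n_genes = expr.ncol();
    const int n_perms = perm_bins.nrow();
    const int nb = H.nrow();
    if (perm_bins.ncol() != n_cells) stop("perm_bins must have one column per cell");
    if (H.ncol() != nb) stop("H must be square");
    NumericMatrix out(n_perms, n_genes);
    std::vector< std::vector<int> > idx(nb);
    std::vector<double> buf, prof(nb), sm(nb);
    for (int p = 0; p < n_perms; ++p) {
        for (int b = 0; b < nb; ++b) idx[b].clear();
        for (int i = 0; i < n_cells; ++i) {
            int b = perm_bins(p, i) - 1;
            if (b < 0 || b >= nb) stop("bin index out of range");
            idx[b].push_back(i);
        }
        for (int g = 0; g < n_genes; ++g) {
            for (int b = 0; b < nb; ++b) {
                const std::vector<int>& ids = idx[b];
                if (ids.empty()) { prof[b] = NAN; continue; }
                buf.resize(ids.size());
                for (size_t k = 0; k < ids.size(); ++k) buf[k] = expr(ids[k], g);
                prof[b] = trimean(buf);
            }
            fill_empty(prof);
            double mean = 0.0;
            for (int b = 0; b < nb; ++b) {
                double s = 0.0;
                for (int j = 0; j < nb; ++j) s += H(b, j) * prof[j];
                sm[b] = s;
                mean += s;
            }
            mean /= nb;
            double ss = 0.0;
            for (int b = 0; b < nb; ++b) ss += (sm[b] - mean) * (sm[b] - mean);
            out(p, g) = std::sqrt(ss / nb);
        }
    }
    return out;
}
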