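#include <Rcpp.h>
using namespace Rcpp;

// Trial-swap chain over binary matrices with fixed row and column totals.
// Each step draws a random 2x2 submatrix and swaps it iff it is a
// checkerboard (10/01 or 01/10). The proposal is symmetric, so the chain's
// stationary distribution is uniform over the set of matrices sharing the
// observed marginals. Uses R's RNG (unif_rand) so set.seed() governs.
static inline void trial_swaps(IntegerMatrix M, int n, int S, int P) {
  for (int t = 0; t < n; ++t) {
    int r1 = (int)(unif_rand() * S);
    int r2 = (int)(unif_rand() * (S - 1)); if (r2 >= r1) ++r2;
    int c1 = (int)(unif_rand() * P);
    int c2 = (int)(unif_rand() * (P - 1)); if (c2 >= c1) ++c2;
    int a = M(r1, c1), b = M(r1, c2), c = M(r2, c1), d = M(r2, c2);
    if (a == 1 && d == 1 && b == 0 && c == 0) {
      M(r1, c1) = 0; M(r2, c2) = 0; M(r1, c2) = 1; M(r2, c1) = 1;
    } else if (a == 0 && d == 0 && b == 1 && c == 1) {
      M(r1, c1) = 1; M(r2, c2) = 1; M(r1, c2) = 0; M(r2, c1) = 0;
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_swap_chain(IntegerMatrix m, int n_swaps) {
  IntegerMatrix M = clone(m);
  int S = M.nrow(), P = M.ncol();
  if (S < 2 || P < 2 || n_swaps <= 0) return M;
  trial_swaps(M, n_swaps, S, P);
  return M;
}

// For every unordered species pair, count null replicates whose C-score is
// <= (le) or >= (ge) the observed C-score. With row totals fixed by the
// null, C is strictly decreasing in the shared-site count D, so the
// comparisons reduce to exact integer comparisons on D:
//   null C <= obs C  <=>  null D >= obs D
//   null C >= obs C  <=>  null D <= obs D
// [[Rcpp::export]]
List cpp_pair_null_counts(IntegerMatrix m, IntegerMatrix obs_d,
                          int n_null, int burn_in, int thin) {
  IntegerMatrix M = clone(m);
  int S = M.nrow(), P = M.ncol();
  IntegerMatrix le(S, S), ge(S, S);
  bool can_swap = (S >= 2 && P >= 2);
  if (can_swap) trial_swaps(M, burn_in, S, P);
  for (int rep = 0; rep < n_null; ++rep) {
    if (can_swap) trial_swaps(M, thin, S, P);
    for (int i = 0; i < S - 1; ++i) {
      for (int j = i + 1; j < S; ++j) {
        int D = 0;
        for (int k = 0; k < P; ++k) D += M(i, k) * M(j, k);
        if (D >= obs_d(i, j)) ++le(i, j);
        if (D <= obs_d(i, j)) ++ge(i, j);
      }
    }
  }
  return List::create(_["le"] = le, _["ge"] = ge);
}

// C-score draws for one species pair (0-based row indices) along the chain;
// used to compare the sampled null against exhaustive enumeration.
// [[Rcpp::export]]
NumericVector cpp_pair_null_samples(IntegerMatrix m, int i, int j,
                                    int n_null, int burn_in, int thin) {
  IntegerMatrix M = clone(m);
  int S = M.nrow(), P = M.ncol();
  NumericVector out(n_null);
  double Ri = 0, Rj = 0;
  for (int k = 0; k < P; ++k) { Ri += M(i, k); Rj += M(j, k); }
  bool can_swap = (S >= 2 && P >= 2);
  if (can_swap) trial_swaps(M, burn_in, S, P);
  for (int rep = 0; rep < n_null; ++rep) {
    if (can_swap) trial_swaps(M, thin, S, P);
    double D = 0;
    for (int k = 0; k < P; ++k) D += M(i, k) * M(j, k);
    out[rep] = (Ri - D) * (Rj - D) / (Ri * Rj);
  }
  return out;
}
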