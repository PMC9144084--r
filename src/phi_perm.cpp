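#include <Rcpp.h>
using namespace Rcpp;

// Permutation null for the PHI statistic.
//
// incompat: n x n 0/1 matrix of pairwise four-gamete incompatibility among
// informative sites (site order = alignment order). ai, bi: 0-based indices
// of the site pairs that are "nearby" (alignment distance <= w); these index
// positions, which stay fixed while site patterns are permuted across them.
// Uses R's RNG so results follow set.seed().
//
// Returns the number of permutation statistics <= and >= the observed mean
// incompatibility, plus the permutation mean.
// [[Rcpp::export]]
List phi_permute(IntegerMatrix incompat, IntegerVector ai, IntegerVector bi,
                 int n_perm, double observed) {
  const int n = incompat.nrow();
  const int npair = ai.size();
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  int count_le = 0, count_ge = 0;
  double sum_stat = 0.0;
  const double eps = 1e-12;
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates with R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    long hits = 0;
    for (int k = 0; k < npair; ++k) {
      hits += incompat(perm[ai[k]], perm[bi[k]]);
    }
    double stat = (double)hits / npair;
    sum_stat += stat;
    if (stat <= observed + eps) ++count_le;
    if (stat >= observed - eps) ++count_ge;
  }
  return List::create(_["count_le"] = count_le,
                      _["count_ge"] = count_ge,
                      _["mean_perm"] = sum_stat / n_perm);
}
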