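#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Genotype matrix under Hardy-Weinberg equilibrium: entry (i, j) is the sum
// of two Bernoulli(maf[j]) allele draws, so P(0,1,2) = ((1-q)^2, 2q(1-q), q^2).
// Uses R's RNG stream, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix genotype_matrix_cpp(int N, int K, NumericVector maf) {
  NumericMatrix G(N, K);
  for (int j = 0; j < K; ++j) {
    double q = maf[j];
    NumericMatrix::Column col = G(_, j);
    for (int i = 0; i < N; ++i) {
      double g = (unif_rand() < q ? 1.0 : 0.0) + (unif_rand() < q ? 1.0 : 0.0);
      col[i] = g;
    }
  }
  return G;
}

// Null enrichment scores for the weighted KS running-sum statistic.
// w_ranked: per-gene weights |t|^expo in ranked order (largest statistic
// first). Each replicate draws L of K rank positions without replacement
// (partial Fisher-Yates on a persistent permutation; after the random swaps
// the array is still a uniform permutation, so no reset is needed) and
// evaluates the running-sum maximum. The maximum of the full K-step walk is
// attained immediately after a hit, so only hit positions are visited.
// [[Rcpp::export]]
NumericVector gsea_null_es_cpp(NumericVector w_ranked, int L, int B) {
  int K = w_ranked.size();
  if (L <= 0 || L >= K) stop("pathway must have >= 1 hit and >= 1 miss");
  std::vector<int> perm(K);
  for (int i = 0; i < K; ++i) perm[i] = i;
  std::vector<int> idx(L);
  NumericVector out(B);
  double miss = 1.0 / (double)(K - L);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < L; ++t) {
      int j = t + (int)(unif_rand() * (K - t));
      if (j >= K) j = K - 1;
      std::swap(perm[t], perm[j]);
      idx[t] = perm[t];
    }
    std::sort(idx.begin(), idx.end());
    double NR = 0.0;
    for (int t = 0; t < L; ++t) NR += w_ranked[idx[t]];
    double cum = 0.0, es = R_NegInf;
    for (int t = 0; t < L; ++t) {
      cum += (NR > 0.0) ? w_ranked[idx[t]] / NR : 1.0 / (double)L;
      double v = cum - (double)(idx[t] - t) * miss;
      if (v > es) es = v;
    }
    out[b] = es;
  }
  return out;
}
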