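# Shared fixtures built in code.

# Score table with uniform p-values (the complete null: every gene-label
# subset is then a uniform draw of scaled ranks).
make_scores <- function(K, seed = 1) {
  set.seed(seed)
  gene_scores(data.frame(
    gene_id = sprintf("g%05d", seq_len(K)),
    pvalue = runif(K)
  ))
}

# Small scenario helpers (reduced K keeps unit tests fast; acceptance tests
# use the full study dimensions).
small_null_scenario <- function(K = 2000, L = 20, M = 50, s2 = 2) {
  scenario("null", L = L, M = M, N = 100, K = K, sigma2_null = s2)
}

small_alt_scenario <- function(K = 2000, L = 20, M = 50, pi = 0.4,
                               s1 = 4, s2 = 1) {
  scenario("alternative", L = L, M = M, N = 100, K = K,
           pi = pi, sigma1_sq = s1, sigma2_sq = s2)
}

# Naive two-level ARTP oracle: evaluates the observed pathway against the
# given first-level replicate set (pooled add-one convention, as in the
# package), but estimates each first-level replicate's per-j p-values from
# its own fresh brute-force second-level permutation set instead of Ge's
# pooled single level.
artp_two_level_oracle <- function(scores, pathway, first_logW, B2) {
  K <- nrow(scores)
  u_all <- scores$u
  L <- ncol(first_logW)
  B <- nrow(first_logW)
  lw_obs <- cumsum(log(sort(u_all[match(pathway, scores$gene_id)])))
  phat_vs <- function(lw, ref) {
    vapply(seq_len(L), function(j) {
      (1 + sum(ref[, j] <= lw[j])) / (nrow(ref) + 1)
    }, numeric(1))
  }
  minstat_obs <- min(phat_vs(lw_obs, first_logW))
  minstat_null <- vapply(seq_len(B), function(b) {
    second <- t(vapply(seq_len(B2), function(i) {
      cumsum(log(sort(u_all[sample.int(K, L)])))
    }, numeric(L)))
    min(phat_vs(first_logW[b, ], second))
  }, numeric(1))
  (1 + sum(minstat_null <= minstat_obs)) / (B + 1)
}

# Paired comparison of the single-level scheme with the two-level oracle:
# m independent first-level replicate sets are shared by both procedures and
# the two mean p-values are returned. Averaging removes most of the
# first-level Monte-Carlo noise from the comparison while leaving the
# procedural difference (pooled single level vs fresh second level) intact.
artp_oracle_comparison <- function(scores, pathway, B, B2, m, seed) {
  set.seed(seed)
  pair <- vapply(seq_len(m), function(i) {
    null <- artp_null(sum(scores$gene_id %in% pathway), B = B,
                      source = "permutation", K = nrow(scores))
    impl <- artp_test(scores, pathway, null = null)$pvalue
    oracle <- artp_two_level_oracle(scores, pathway, null$logW, B2 = B2)
    c(impl = impl, oracle = oracle)
  }, numeric(2))
  rowMeans(pair)
}

# Exhaustive hypergeometric oracle: enumerate every size-n significant list
# from a K-gene universe and count those sharing >= k genes with a fixed
# size-L pathway. Only feasible for tiny K.
hyper_enumeration_oracle <- function(K, L, n, k) {
  pathway <- seq_len(L)
  lists <- utils::combn(K, n)
  hits <- colSums(matrix(lists %in% pathway, nrow = n))
  mean(hits >= k)
}
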