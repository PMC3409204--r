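# Weighted KS-like enrichment score.
#
# Gene statistics are t_k = -ln(p_k), ranked from largest to smallest (ties
# by input order). Walking down the ranked list, the running sum gains
# |t_j|^expo / N_R at pathway hits (N_R = sum of hit weights) and loses
# 1/(K - N_H) at misses; ES is the maximum of the walk. The signed maximum
# (not max-absolute) makes this a one-sided enrichment-at-top test.

# Ranked weights |t|^expo and the rank position of each input gene.
gsea_prepare <- function(pvalues, weight_exponent = 1) {
  p <- pmax(pvalues, .Machine$double.xmin) # p = 0 clamped before the log
  t_stat <- -log(p)
  ord <- order(t_stat, decreasing = TRUE) # stable: ties keep input order
  list(w_ranked = abs(t_stat[ord])^weight_exponent, ord = ord)
}

# ES from hit positions in the ranked list. The walk's maximum is attained
# immediately after a hit, so only hit positions are evaluated.
gsea_es_core <- function(w_ranked, hits, K) {
  L <- length(hits)
  w <- w_ranked[hits]
  NR <- sum(w)
  inc <- if (NR > 0) w / NR else rep(1 / L, L)
  max(cumsum(inc) - (hits - seq_len(L)) / (K - L))
}

#' Weighted KS enrichment score of a pathway
#'
#' @param scores A `pr_scores` tibble.
#' @param pathway Character vector of member gene ids; the pathway must have
#'   at least one member and one non-member in the universe.
#' @param weight_exponent Exponent on the `-ln p` gene statistics weighting
#'   the hit increments (default 1; 0 reduces to the classical KS statistic).
#' @return The enrichment score (at most 1, reached when all pathway genes
#'   occupy the top of the ranked list).
#' @export
gsea_es <- function(scores, pathway, weight_exponent = 1) {
  idx <- pathway_index(scores, pathway)
  K <- nrow(scores)
  L <- length(idx)
  if (L < 1 || L >= K) {
    abort("pathway must have at least one member and one non-member in the universe.")
  }
  prep <- gsea_prepare(scores$pvalue, weight_exponent)
  member <- logical(K)
  member[idx] <- TRUE
  hits <- which(member[prep$ord])
  gsea_es_core(prep$w_ranked, hits, K)
}

#' GSEA-style competitive pathway test
#'
#' Computes the weighted KS enrichment score of the pathway and compares it
#' to the scores of B random same-size gene subsets (gene-label
#' permutation), large scores being extreme. Unlike the rank-combination
#' tests, the ES depends on the magnitudes of the `-ln p` statistics, but
#' the label-permutation null keeps the p-value calibrated.
#'
#' @inheritParams gsea_es
#' @param B Number of random gene subsets (>= 100).
#' @param seed Optional integer seed.
#' @param pathway_name Optional label for the result row.
#' @return One-row `pr_enrich` tibble; `extras` carries the hit positions.
#' @export
gsea_test <- function(scores, pathway, B = 1000, weight_exponent = 1,
                      seed = NULL, pathway_name = NULL) {
  if (B < 100) abort("B must be at least 100.")
  idx <- pathway_index(scores, pathway)
  K <- nrow(scores)
  L <- length(idx)
  if (L < 1 || L >= K) {
    abort("pathway must have at least one member and one non-member in the universe.")
  }
  maybe_seed(seed)
  prep <- gsea_prepare(scores$pvalue, weight_exponent)
  member <- logical(K)
  member[idx] <- TRUE
  hits <- which(member[prep$ord])
  es <- gsea_es_core(prep$w_ranked, hits, K)
  nulls <- gsea_null_es_cpp(prep$w_ranked, L, as.integer(B))
  p <- permutation_pvalue(es, nulls, direction = "greater")
  result_row(pathway_name, "gsea", L, es, p,
             extras = list(hits = hits, B = B, weight_exponent = weight_exponent))
}
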