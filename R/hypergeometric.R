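#' One-sided hypergeometric over-representation p-value
#'
#' Upper-tail probability that a pathway of size L contains at least k of the
#' n study-wide significant genes when the significant list is a uniform draw
#' from the K-gene universe:
#' \deqn{p = \sum_{i=k}^{\min(L,n)} \binom{L}{i}\binom{K-L}{n-i} / \binom{K}{n}.}
#'
#' @param K Universe size.
#' @param L Pathway size.
#' @param n Significant-list length.
#' @param k Number of significant genes inside the pathway.
#' @return The enrichment p-value.
#' @examples
#' hypergeometric_pvalue(K = 10, L = 4, n = 5, k = 3) # 66/252
#' @export
hypergeometric_pvalue <- function(K, L, n, k) {
  vals <- c(K = K, L = L, n = n, k = k)
  if (any(vals != round(vals)) || any(vals < 0)) {
    abort("K, L, n, k must be nonnegative integers.")
  }
  if (L > K || n > K || k > min(L, n)) {
    abort(sprintf("inconsistent counts: need k <= min(L, n), L <= K, n <= K (got K=%d, L=%d, n=%d, k=%d).",
                  K, L, n, k))
  }
  phyper(k - 1, m = L, n = K - L, k = n, lower.tail = FALSE)
}

#' Significant-gene list
#'
#' Returns the study's significant genes either by a p-value threshold
#' (`p < alpha`) or as the `top_n` genes with the smallest p-values (ties
#' broken by input order, as in [scaled_ranks()]).
#'
#' @param scores A `pr_scores` tibble.
#' @param alpha Significance threshold (exclusive); give exactly one of
#'   `alpha` / `top_n`.
#' @param top_n Number of top-ranked genes to select.
#' @return Character vector of gene ids; its length is the `n` entering the
#'   hypergeometric test.
#' @export
significant_genes <- function(scores, alpha = NULL, top_n = NULL) {
  if (is.null(alpha) == is.null(top_n)) {
    abort("give exactly one of `alpha` or `top_n`.")
  }
  K <- nrow(scores)
  if (!is.null(alpha)) {
    return(scores$gene_id[scores$pvalue < alpha])
  }
  if (top_n < 1 || top_n > K) {
    abort(sprintf("`top_n` must be in 1..K = %d (got %s).", K, format(top_n)))
  }
  ranks <- round(scores$u * K)
  scores$gene_id[ranks <= top_n]
}

# Fast core: k from pathway row indices and the rank cut.
hyper_pvalue_from_ranks <- function(u_path, K, top_n) {
  L <- length(u_path)
  k <- sum(round(u_path * K) <= top_n)
  list(pvalue = phyper(k - 1, m = L, n = K - L, k = top_n, lower.tail = FALSE), k = k)
}

#' Hypergeometric over-representation pathway test
#'
#' Counts pathway members within the study's significant-gene list and
#' applies the one-sided hypergeometric test. The default list is the 2000
#' smallest gene p-values, the calibrated variant whose type-I error is close
#' to nominal at genome scale; fixed small thresholds make the test
#' conservative because its null is discrete.
#'
#' @inheritParams fisher_test
#' @param top_n Length of the significant list (default 2000).
#' @param alpha Alternative threshold rule (`p < alpha`); give one of the two.
#' @return One-row `pr_enrich` tibble; `extras` carries `n` and `k`.
#' @export
hypergeometric_test <- function(scores, pathway, top_n = 2000, alpha = NULL,
                                pathway_name = NULL) {
  idx <- pathway_index(scores, pathway)
  L <- length(idx)
  if (L < 1) abort("pathway has no genes in the score universe.")
  K <- nrow(scores)
  sig <- if (is.null(alpha)) {
    significant_genes(scores, top_n = min(top_n, K))
  } else {
    significant_genes(scores, alpha = alpha)
  }
  n <- length(sig)
  k <- sum(scores$gene_id[idx] %in% sig)
  p <- hypergeometric_pvalue(K, L, n, k)
  result_row(pathway_name, if (is.null(alpha)) "hyper" else "hyper_t",
             L, statistic = k, pvalue = p, extras = list(n = n, k = k))
}
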