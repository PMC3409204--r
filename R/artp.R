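#' Rank truncated product statistic
#'
#' Product of the j smallest scaled ranks of a pathway,
#' \eqn{W(j) = \prod_{k=1}^{j} u_{(k)}}; smaller values indicate enrichment.
#' At the full truncation point j = L, `-2 * log(W(L))` is exactly the Fisher
#' combination statistic.
#'
#' @param u_sorted Pathway scaled ranks sorted ascending.
#' @param j Truncation point, 1 <= j <= length(u_sorted).
#' @return W(j).
#' @examples
#' rtp_statistic(c(0.1, 0.2), 2) # 0.02
#' @export
rtp_statistic <- function(u_sorted, j) {
  check_pvalues(u_sorted, "u_sorted")
  L <- length(u_sorted)
  if (is.unsorted(u_sorted)) abort("`u_sorted` must be sorted ascending.")
  if (j < 1 || j > L || j != round(j)) {
    abort(sprintf("truncation point j must be an integer in 1..%d.", L))
  }
  prod(u_sorted[seq_len(j)])
}

#' Null replicates for the adaptive rank truncated product
#'
#' Builds the B replicate rank-vectors of Ge's single-level permutation
#' scheme, pre-sorted and reduced to cumulative log-products
#' \eqn{\log W^{(b)}(j)}, along with the per-truncation-point order
#' statistics needed to evaluate observed pathways quickly. With
#' `source = "permutation"` each replicate draws L of the K scaled ranks
#' without replacement (gene-label permutation); with
#' `source = "empirical_uniform"` it draws L i.i.d. Uniform(0,1) values
#' (the ARTP_E variant). Because scaled ranks of a full study are always the
#' fixed set \{1/K, ..., 1\}, both nulls depend only on (K, L) and can be
#' reused across studies of the same size.
#'
#' @param L Pathway size.
#' @param B Number of replicates (>= 100).
#' @param source Null-generation scheme.
#' @param K Universe size (required for `"permutation"`).
#' @param seed Optional integer seed.
#' @return A `pr_artp_null` object.
#' @export
artp_null <- function(L, B = 1000, source = c("permutation", "empirical_uniform"),
                      K = NULL, seed = NULL) {
  source <- match.arg(source)
  if (B < 100) abort("B must be at least 100.")
  maybe_seed(seed)
  if (source == "permutation") {
    if (is.null(K)) abort("`K` is required for the permutation null.")
    if (L > K) abort("pathway size L cannot exceed the universe size K.")
    draws <- vapply(seq_len(B), function(b) {
      log(sort.int(sample.int(K, L)) / K)
    }, numeric(L))
    logu <- if (L == 1) matrix(draws, ncol = 1) else t(draws)
  } else {
    logu <- log(sorted_uniform_matrix(B, L))
  }
  logW <- logu
  if (L > 1) {
    for (j in 2:L) logW[, j] <- logW[, j - 1] + logu[, j]
  }
  # Per-j machinery: sorted null log-products (for counting against an
  # observed pathway) and each replicate's rank among the nulls (ties high).
  sortedW <- apply(logW, 2, sort)
  rmax <- apply(logW, 2, rank, ties.method = "max")
  dim(sortedW) <- dim(logW)
  dim(rmax) <- dim(logW)
  structure(list(logW = logW, sortedW = sortedW, rmax = rmax,
                 B = B, L = L, K = K, source = source),
            class = "pr_artp_null")
}

#' @export
print.pr_artp_null <- function(x, ...) {
  cat(sprintf("<pr_artp_null: L = %d, B = %d, source = %s>\n", x$L, x$B, x$source))
  invisible(x)
}

# Ge single-level evaluation of one observed pathway against a null set.
#
# Pooled p-hat convention: every replicate (observed b = 0 and nulls
# b = 1..B) is compared against all B+1 replicates including itself,
#   p_hat_j(b) = #{b' : W_{b'}(j) <= W_b(j)} / (B + 1),
# so observed and null replicates stay exchangeable. The ARTP statistic of a
# replicate is min_j p_hat_j and the final p-value is
#   #{b' : minstat(b') <= minstat(0)} / (B + 1).
artp_eval <- function(logW_obs, null) {
  L <- null$L
  B <- null$B
  stopifnot(length(logW_obs) == L)
  cnt_obs <- vapply(seq_len(L), function(j) {
    count_leq(logW_obs[j], null$sortedW[, j])
  }, numeric(1))
  phat_obs <- (1 + cnt_obs) / (B + 1)
  # Null replicates gain one count where the observed product undercuts them.
  ind <- null$logW >= matrix(logW_obs, nrow = B, ncol = L, byrow = TRUE)
  cnt_null <- null$rmax + ind
  minstat_null <- do.call(pmin, lapply(seq_len(L), function(j) cnt_null[, j]))
  minstat_null <- minstat_null / (B + 1)
  minstat_obs <- min(phat_obs)
  pvalue <- (1 + sum(minstat_null <= minstat_obs)) / (B + 1)
  j_hat <- which.min(phat_obs) # smallest j on ties
  list(pvalue = pvalue, statistic = minstat_obs, j_hat = j_hat, phat = phat_obs)
}

#' Adaptive rank truncated product pathway test
#'
#' Evaluates the rank truncated product W(j) of the pathway's scaled ranks at
#' every truncation point j = 1..L, estimates each W(j)'s significance
#' against B null replicates, and takes the minimum estimated p-value over j
#' as the adaptive statistic. Its own significance is assessed with Ge's
#' single-level algorithm, which pools the observed pathway with the same B
#' replicates instead of nesting a second permutation layer. Null replicates
#' come from gene-label permutation (`"permutation"`) or from i.i.d.
#' Uniform(0,1) draws (`"empirical_uniform"`, the ARTP_E variant).
#'
#' @inheritParams fisher_test
#' @param null_source Null replicate scheme (see [artp_null()]).
#' @param null Optional precomputed `pr_artp_null` (must match L, and K for
#'   the permutation scheme).
#' @return One-row `pr_enrich` tibble; `extras` carries the selected
#'   truncation point `j_hat` and the per-j `p_hat` vector.
#' @export
artp_test <- function(scores, pathway, B = 1000,
                      null_source = c("permutation", "empirical_uniform"),
                      seed = NULL, null = NULL, pathway_name = NULL) {
  null_source <- match.arg(null_source)
  idx <- pathway_index(scores, pathway)
  L <- length(idx)
  if (L < 1) abort("pathway has no genes in the score universe.")
  u_path <- sort(scores$u[idx])
  logW_obs <- cumsum(log(u_path))
  if (is.null(null)) {
    maybe_seed(seed)
    null <- artp_null(L, B = B, source = null_source, K = nrow(scores))
  } else {
    if (!inherits(null, "pr_artp_null") || null$L != L) {
      abort("`null` must be a pr_artp_null built for this pathway size.")
    }
    null_source <- null$source
  }
  ans <- artp_eval(logW_obs, null)
  method <- if (null_source == "permutation") "artp" else "artp_e"
  result_row(pathway_name, method, L, ans$statistic, ans$pvalue,
             extras = list(j_hat = ans$j_hat, phat = ans$phat, B = null$B))
}
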