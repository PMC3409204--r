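#' Fisher combination statistic on scaled ranks
#'
#' \eqn{T = -2 \sum_{k=1}^{L} \ln u_k} over the pathway's scaled ranks. With
#' independent continuous Uniform(0,1) inputs T is chi-square with 2L degrees
#' of freedom; scaled ranks are discrete but the chi-square reference remains
#' accurate for genome-scale K.
#'
#' @param u Numeric vector of scaled ranks (entries in (0, 1\]).
#' @return The statistic T >= 0.
#' @examples
#' fisher_statistic(c(0.1, 0.2)) # 7.824046
#' @export
fisher_statistic <- function(u) {
  check_pvalues(u, "u")
  if (any(u == 0)) {
    abort("zero entries are not valid Fisher inputs (scaled ranks are always > 0).")
  }
  if (length(u) < 1) abort("at least one gene is required.")
  -2 * sum(log(u))
}

# Fast cores used by both the user-facing test and the scenario driver.
fm_pvalue_asymptotic <- function(u_path) {
  pchisq(-2 * sum(log(u_path)), df = 2 * length(u_path), lower.tail = FALSE)
}

fm_perm_nulls <- function(u_all, L, B) {
  vapply(seq_len(B), function(b) {
    -2 * sum(log(u_all[sample.int(length(u_all), L)]))
  }, numeric(1))
}

#' Fisher's method as a competitive pathway test
#'
#' Combines the pathway genes' scaled ranks with Fisher's statistic and
#' assesses significance either against the asymptotic chi-square(2L)
#' reference or against a gene-label permutation null (L genes redrawn
#' uniformly without replacement from the K-gene universe, B times).
#'
#' @param scores A `pr_scores` tibble (the study universe).
#' @param pathway Character vector of member gene ids.
#' @param mode `"asymptotic"` or `"permutation"`.
#' @param B Number of permutation replicates (>= 100) in permutation mode.
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @param pathway_name Optional label for the result row.
#' @return One-row `pr_enrich` tibble: `pathway`, `method`, `L`, `statistic`,
#'   `pvalue`, `extras`.
#' @export
fisher_test <- function(scores, pathway, mode = c("asymptotic", "permutation"),
                        B = 1000, seed = NULL, pathway_name = NULL) {
  mode <- match.arg(mode)
  idx <- pathway_index(scores, pathway)
  L <- length(idx)
  if (L < 1) abort("pathway has no genes in the score universe.")
  u <- scores$u[idx]
  statistic <- fisher_statistic(u)
  if (mode == "asymptotic") {
    p <- pchisq(statistic, df = 2 * L, lower.tail = FALSE)
    method <- "fm"
    extras <- list(df = 2 * L)
  } else {
    if (B < 100) abort("B must be at least 100 in permutation mode.")
    maybe_seed(seed)
    nulls <- fm_perm_nulls(scores$u, L, B)
    p <- permutation_pvalue(statistic, nulls, direction = "greater")
    method <- "fm_perm"
    extras <- list(B = B)
  }
  result_row(pathway_name, method, L, statistic, p, extras)
}
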