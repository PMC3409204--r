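#' Reference null distribution for an enrichment statistic
#'
#' A sorted Monte-Carlo sample of a test statistic under a stated
#' null-generation scheme, together with the direction in which extreme
#' values indicate enrichment. Every permutation/empirical p-value in the
#' package is computed against one of these.
#'
#' @param values Numeric sample of the statistic under the null.
#' @param scheme One of `"permutation"` (gene-label randomization),
#'   `"empirical_uniform"` (statistics of i.i.d. Uniform(0,1) draws) or
#'   `"analytic"`.
#' @param direction `"greater"` if large statistics indicate enrichment,
#'   `"less"` if small ones do.
#' @return A `pr_null` object (list with sorted `values`, `scheme`,
#'   `direction`, sample size `B`).
#' @export
null_distribution <- function(values,
                              scheme = c("permutation", "empirical_uniform", "analytic"),
                              direction = c("greater", "less")) {
  scheme <- match.arg(scheme)
  direction <- match.arg(direction)
  if (length(values) == 0 || !is.numeric(values)) {
    abort("`values` must be a nonempty numeric sample.")
  }
  structure(
    list(values = sort(values), scheme = scheme,
         direction = direction, B = length(values)),
    class = "pr_null"
  )
}

#' @export
print.pr_null <- function(x, ...) {
  cat(sprintf("<pr_null: %d %s draws, extreme = %s>\n", x$B, x$scheme, x$direction))
  invisible(x)
}

#' Permutation p-value with add-one correction
#'
#' Computes `(1 + c) / (1 + B)` where `c` counts null draws at least as
#' extreme as the observed statistic ("as extreme" follows the null's
#' direction; ties count as extreme). The add-one convention never returns 0
#' and corresponds to pooling the observed statistic with its own null
#' sample, so the result is bounded below by `1/(B+1)`.
#'
#' @param observed Observed statistic (scalar).
#' @param nulls A `pr_null` object, or a numeric vector of null draws.
#' @param direction Required when `nulls` is a bare numeric vector.
#' @return A p-value in `[1/(B+1), 1]`.
#' @examples
#' permutation_pvalue(10, null_distribution(rnorm(999), "permutation", "greater"))
#' @export
permutation_pvalue <- function(observed, nulls, direction = NULL) {
  if (inherits(nulls, "pr_null")) {
    values <- nulls$values
    direction <- nulls$direction
  } else {
    values <- nulls
    if (is.null(direction)) {
      abort("`direction` must be given when `nulls` is a plain numeric vector.")
    }
    direction <- match.arg(direction, c("greater", "less"))
  }
  if (length(values) == 0) abort("empty null sample.")
  if (!is.numeric(observed) || length(observed) != 1 || !is.finite(observed)) {
    abort("`observed` must be a single finite number.")
  }
  c_extreme <- if (direction == "greater") sum(values >= observed) else sum(values <= observed)
  (1 + c_extreme) / (1 + length(values))
}

# Internal: count of sorted null values <= x (ties included), via findInterval.
count_leq <- function(x, sorted_values) findInterval(x, sorted_values)

# One-row result tibble shared by all tests.
result_row <- function(pathway, method, L, statistic, pvalue, extras = list()) {
  out <- tibble(
    pathway = pathway %||% NA_character_,
    method = method,
    L = as.integer(L),
    statistic = statistic,
    pvalue = pvalue,
    extras = list(extras)
  )
  class(out) <- c("pr_enrich", class(out))
  out
}

# Matrix of n rows of sorted Uniform(0,1) samples of length L, generated
# column-wise by the backward order-statistics recursion
#   U_(L) = V_L^(1/L),  U_(k) = U_(k+1) * V_k^(1/k),
# which avoids sorting each row. Used for empirical-uniform nulls.
sorted_uniform_matrix <- function(n, L) {
  U <- matrix(0, nrow = n, ncol = L)
  U[, L] <- runif(n)^(1 / L)
  if (L > 1) {
    for (k in (L - 1):1) {
      U[, k] <- U[, k + 1] * runif(n)^(1 / k)
    }
  }
  U
}
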