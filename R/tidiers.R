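# broom-style views of the result containers.

#' Tidy an enrichment result table
#'
#' Flat per-(pathway, method) rows without the list-column of
#' method-specific extras; the ARTP truncation point is kept as `j_hat`.
#'
#' @param x A `pr_enrich` tibble.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.pr_enrich <- function(x, ...) {
  out <- as_tibble(x[, c("pathway", "method", "L", "statistic", "pvalue")])
  out$j_hat <- vapply(x$extras, function(e) {
    if (!is.null(e$j_hat)) as.integer(e$j_hat) else NA_integer_
  }, integer(1))
  out
}

#' One-line summary of an enrichment result table
#'
#' @param x A `pr_enrich` tibble.
#' @param alpha Nominal level (default 0.05).
#' @param ... Unused.
#' @return One-row tibble: pathway count, method count, number of
#'   (pathway, method) pairs below `alpha`, smallest p-value.
#' @export
glance.pr_enrich <- function(x, alpha = 0.05, ...) {
  tibble(
    n_pathways = length(unique(x$pathway)),
    n_methods = length(unique(x$method)),
    n_significant = sum(x$pvalue < alpha),
    min_pvalue = min(x$pvalue)
  )
}

#' Tidy a simulation-study result
#'
#' @param x A `pr_study` tibble.
#' @param ... Unused.
#' @return A plain tibble of per-(scenario, method) rejection rates.
#' @export
tidy.pr_study <- function(x, ...) {
  as_tibble(x)
}

#' One-line summary of a simulation study
#'
#' @param x A `pr_study` tibble.
#' @param ... Unused.
#' @return One-row tibble: scenario and method counts, total replicates, and
#'   the pooled mean rejection rate per the unweighted-scenario convention.
#' @export
glance.pr_study <- function(x, ...) {
  tibble(
    n_scenarios = nrow(dplyr::distinct(as_tibble(x)[, intersect(
      c("kind", "L", "M", "N", "K", "sigma2_null", "pi", "sigma1_sq", "sigma2_sq"),
      names(x)
    )])),
    n_methods = length(unique(x$method)),
    total_reps = sum(x$n_reps),
    mean_rate = mean(x$rate)
  )
}
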