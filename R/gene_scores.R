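#' Scaled ranks of gene p-values
#'
#' Converts per-gene association p-values into the competitive gene statistic
#' \eqn{u_k = \mathrm{rank}(p_k)/K}: the rank of each p-value among all K
#' study genes (smallest p gets rank 1), divided by K. Under the competitive
#' null hypothesis the statistics of a random pathway are a uniform draw from
#' the discrete set \eqn{\{1/K, 2/K, \dots, 1\}}, which is what lets any
#' p-value combination test be reused as an enrichment test.
#'
#' Ties are broken by input order (ordinal ranking), so the result is always
#' a permutation of \eqn{\{1/K, \dots, 1\}}; ties have probability zero for
#' continuous association statistics.
#'
#' @param pvalues Numeric vector of per-gene p-values in \[0, 1\], length >= 2.
#' @return Numeric vector of scaled ranks, same length and order as the input.
#' @examples
#' scaled_ranks(c(0.9, 0.01, 0.5))
#' @export
scaled_ranks <- function(pvalues) {
  check_pvalues(pvalues)
  K <- length(pvalues)
  if (K < 2) {
    abort("at least two genes are required to form scaled ranks.")
  }
  rank(pvalues, ties.method = "first") / K
}

#' Build a gene-score table
#'
#' Wraps a data frame of per-gene association p-values into the study-wide
#' score container used by all enrichment tests: a tibble with one row per
#' gene carrying `gene_id`, `pvalue` and the scaled rank `u` (see
#' [scaled_ranks()]). The full table defines the competitive background (the
#' gene universe of size K).
#'
#' @param x Data frame with columns `gene_id` and `pvalue` (one row per gene,
#'   ids unique).
#' @return A `pr_scores` tibble with columns `gene_id`, `pvalue`, `u`.
#' @examples
#' gene_scores(data.frame(gene_id = c("a", "b", "c"), pvalue = c(0.9, 0.01, 0.5)))
#' @export
gene_scores <- function(x) {
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame with columns `gene_id` and `pvalue`.")
  }
  missing_cols <- setdiff(c("gene_id", "pvalue"), names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("`x` is missing column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  ids <- as.character(x$gene_id)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    abort(sprintf("gene ids must be unique (duplicated: '%s').", dup))
  }
  out <- tibble(
    gene_id = ids,
    pvalue = as.numeric(x$pvalue),
    u = scaled_ranks(as.numeric(x$pvalue))
  )
  class(out) <- c("pr_scores", class(out))
  out
}

#' Read a gene p-value table
#'
#' Reads a TSV with header columns `gene_id` and `pvalue` (the shared format
#' written by the simulator export and consumed by the tests) and returns the
#' score container of [gene_scores()].
#'
#' @param path Path to a tab-separated file with columns `gene_id`, `pvalue`.
#' @return A `pr_scores` tibble.
#' @export
read_gene_pvalues <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  gene_scores(x)
}

#' Write a gene p-value table
#'
#' Writes the `gene_id` / `pvalue` columns as TSV — the shared format read
#' back by [read_gene_pvalues()], so simulated ([sim_scores()]) and real
#' studies flow through one front door.
#'
#' @param scores A `pr_scores` tibble (or any data frame with `gene_id`,
#'   `pvalue`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_pvalues <- function(scores, path) {
  readr::write_tsv(as.data.frame(scores)[, c("gene_id", "pvalue")], path)
  invisible(path)
}

#' @export
print.pr_scores <- function(x, ...) {
  cat(sprintf("# Gene scores: K = %d genes\n", nrow(x)))
  NextMethod()
}

# Positions (row indices) of a pathway's genes in the score table.
# Genes absent from the universe are dropped silently here; callers decide
# whether the remaining size is acceptable.
pathway_index <- function(scores, pathway) {
  stopifnot(is.character(pathway))
  which(scores$gene_id %in% pathway)
}
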