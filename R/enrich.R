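#' Test a gene-set collection for enrichment
#'
#' Computes the scaled ranks once over the study universe, restricts the
#' collection to that universe, and runs each requested method on each
#' pathway. Empirical and permutation ARTP/TSM nulls are cached per pathway
#' size, so large collections do not rebuild them per set.
#'
#' @param scores A `pr_scores` tibble (see [gene_scores()]).
#' @param sets A `pr_sets` collection ([read_gmt()], [gene_sets()]) or a
#'   named list of gene-id vectors.
#' @param methods Method labels; any of `"fm"`, `"fm_perm"`, `"tsm"`,
#'   `"tsm_e"`, `"gsea"`, `"artp"`, `"artp_e"`, `"hyper"`.
#' @param B Permutation replicates (default 1000).
#' @param R Empirical null sample size for `tsm_e` (default 1e5).
#' @param top_n Significant-list length for `hyper`.
#' @param hyper_alpha Significance threshold for the `hyper_t` label
#'   (threshold-rule hypergeometric).
#' @param weight_exponent GSEA hit-weight exponent.
#' @param min_size Minimum post-intersection pathway size (default 2).
#' @param seed Optional integer seed for all randomized nulls.
#' @return A `pr_enrich` tibble, one row per (pathway, method), with
#'   `statistic`, `pvalue` and method-specific `extras`.
#' @export
enrich_pathways <- function(scores, sets,
                            methods = c("fm", "tsm_e", "gsea", "artp_e", "hyper"),
                            B = 1000, R = 1e5, top_n = 2000, hyper_alpha = NULL,
                            weight_exponent = 1, min_size = 2, seed = NULL) {
  bad <- setdiff(methods, study_method_labels)
  if (length(bad) > 0) {
    abort(sprintf("unknown method(s): %s. Valid labels: %s.",
                  paste(bad, collapse = ", "),
                  paste(study_method_labels, collapse = ", ")))
  }
  if (is.list(sets) && !is.data.frame(sets)) sets <- gene_sets(sets)
  sets <- restrict_to_universe(sets, scores, min_size = min_size)
  set_list <- as_set_list(sets)
  if (length(set_list) == 0) abort("no gene sets remain after universe restriction.")
  maybe_seed(seed)

  tsm_cache <- new.env(parent = emptyenv())
  artp_cache <- new.env(parent = emptyenv())
  rows <- purrr::imap(set_list, function(genes, nm) {
    purrr::map(methods, function(m) {
      switch(
        m,
        fm = fisher_test(scores, genes, mode = "asymptotic", pathway_name = nm),
        fm_perm = fisher_test(scores, genes, mode = "permutation", B = B,
                              pathway_name = nm),
        tsm = tsm_test(scores, genes, mode = "normal", pathway_name = nm),
        tsm_e = {
          L <- length(pathway_index(scores, genes))
          key <- as.character(L)
          if (is.null(tsm_cache[[key]])) tsm_cache[[key]] <- tsm_null(L, R = R)
          tsm_test(scores, genes, mode = "empirical", null = tsm_cache[[key]],
                   pathway_name = nm)
        },
        gsea = gsea_test(scores, genes, B = B, weight_exponent = weight_exponent,
                         pathway_name = nm),
        artp = {
          L <- length(pathway_index(scores, genes))
          key <- paste0("p", L)
          if (is.null(artp_cache[[key]])) {
            artp_cache[[key]] <- artp_null(L, B = B, source = "permutation",
                                           K = nrow(scores))
          }
          artp_test(scores, genes, null = artp_cache[[key]], pathway_name = nm)
        },
        artp_e = {
          L <- length(pathway_index(scores, genes))
          key <- paste0("e", L)
          if (is.null(artp_cache[[key]])) {
            artp_cache[[key]] <- artp_null(L, B = B, source = "empirical_uniform")
          }
          artp_test(scores, genes, null = artp_cache[[key]], pathway_name = nm)
        },
        hyper = hypergeometric_test(scores, genes, top_n = top_n, pathway_name = nm),
        hyper_t = {
          if (is.null(hyper_alpha)) abort("method 'hyper_t' needs `hyper_alpha`.")
          hypergeometric_test(scores, genes, alpha = hyper_alpha, pathway_name = nm)
        }
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  class(out) <- c("pr_enrich", class(out))
  out
}

#' Write an enrichment results table
#'
#' TSV with one row per (pathway, method); the method-specific `extras` are
#' JSON-encoded in the last column.
#'
#' @param results A `pr_enrich` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  flat <- dplyr::mutate(
    results,
    extras = vapply(.data$extras, function(e) {
      as.character(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA))
    }, character(1))
  )
  # JSON never contains tabs or newlines, so quoting can be disabled and the
  # extras column round-trips verbatim
  readr::write_tsv(flat, path, quote = "none", escape = "none")
  invisible(path)
}

#' Count nominally significant pathways per method
#'
#' The per-database summary: how many pathways each method calls enriched at
#' a nominal level.
#'
#' @param results A `pr_enrich` tibble.
#' @param alpha Nominal level (default 0.05).
#' @return Tibble with `method`, `n_pathways`, `n_significant`.
#' @export
count_significant <- function(results, alpha = 0.05) {
  dplyr::summarise(
    dplyr::group_by(results, .data$method),
    n_pathways = dplyr::n(),
    n_significant = sum(.data$pvalue < alpha),
    .groups = "drop"
  )
}
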