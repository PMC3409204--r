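# Front-end for per-SNP inputs: SNP-to-gene mapping by distance, minimum-p
# gene statistics, and permutation-based gene-size adjustment.

#' Map SNPs to their nearest gene
#'
#' Assigns each SNP to the closest gene whose coding start lies within
#' `window_bp` of the SNP position, on the same chromosome. The coding start
#' is strand-aware: `start` for `+` (or missing) strand, `end` for `-`.
#' Distance ties go to the lexicographically smaller gene id. SNPs with no
#' gene in range stay unmapped; SNPs on chromosomes absent from the gene
#' table are unmapped with a warning.
#'
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos` (1-based).
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   and optionally `strand`. With `format = "bed"` the columns are
#'   interpreted as 0-based half-open and converted on read.
#' @param window_bp Maximum SNP-to-coding-start distance (default 10000).
#'   The mapping window is study-specific, so it is an argument, not a
#'   constant.
#' @param format `"tsv"` (1-based inclusive) or `"bed"` (0-based half-open).
#' @return A `pr_snp_map` tibble with columns `snp_id`, `gene_id` (NA when
#'   unmapped), `distance`; attribute `unmapped` counts unassigned SNPs.
#' @export
map_snps_to_genes <- function(snps, genes, window_bp = 10000,
                              format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (window_bp <= 0) abort("`window_bp` must be positive.")
  need_s <- setdiff(c("snp_id", "chrom", "pos"), names(snps))
  need_g <- setdiff(c("gene_id", "chrom", "start", "end"), names(genes))
  if (length(need_s) > 0 || length(need_g) > 0) {
    abort(sprintf("missing columns: %s.", paste(c(need_s, need_g), collapse = ", ")))
  }
  genes <- as_tibble(genes)
  if (format == "bed") {
    genes$start <- genes$start + 1 # half-open 0-based -> 1-based inclusive
  }
  if (!"strand" %in% names(genes)) genes$strand <- "+"
  genes$coding_start <- ifelse(genes$strand == "-", genes$end, genes$start)

  off_chrom <- !(snps$chrom %in% genes$chrom)
  if (any(off_chrom)) {
    warn(sprintf("%d SNP(s) on chromosomes absent from the gene table are unmapped.",
                 sum(off_chrom)))
  }
  by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
  assign_one <- function(chrom, pos) {
    gi <- by_chrom[[as.character(chrom)]]
    if (is.null(gi)) return(c(NA_integer_, NA_real_))
    d <- abs(genes$coding_start[gi] - pos)
    ok <- which(d <= window_bp)
    if (length(ok) == 0) return(c(NA_integer_, NA_real_))
    dmin <- min(d[ok])
    cand <- gi[ok[d[ok] == dmin]]
    pick <- cand[order(genes$gene_id[cand])[1]]
    c(pick, dmin)
  }
  hit <- vapply(seq_len(nrow(snps)),
                function(i) assign_one(snps$chrom[i], snps$pos[i]),
                numeric(2))
  out <- tibble(
    snp_id = as.character(snps$snp_id),
    gene_id = ifelse(is.na(hit[1, ]), NA_character_, genes$gene_id[hit[1, ]]),
    distance = hit[2, ]
  )
  attr(out, "window_bp") <- window_bp
  attr(out, "unmapped") <- sum(is.na(out$gene_id))
  class(out) <- c("pr_snp_map", class(out))
  out
}

#' Minimum-p gene statistic
#'
#' Assigns each gene the minimum p-value of its mapped SNPs. Genes without
#' any mapped SNP are absent from the output.
#'
#' @param snp_pvalues Data frame with columns `snp_id`, `pvalue`.
#' @param map A `pr_snp_map` from [map_snps_to_genes()].
#' @return Tibble with columns `gene_id`, `pvalue`, `n_snps`.
#' @export
gene_min_p <- function(snp_pvalues, map) {
  joined <- dplyr::inner_join(
    tibble(snp_id = as.character(snp_pvalues$snp_id),
           pvalue = as.numeric(snp_pvalues$pvalue)),
    map[!is.na(map$gene_id), c("snp_id", "gene_id")],
    by = "snp_id"
  )
  miss <- setdiff(map$snp_id[!is.na(map$gene_id)], snp_pvalues$snp_id)
  if (length(miss) > 0) {
    abort(sprintf("%d mapped SNP(s) have no p-value (first: %s).",
                  length(miss), miss[1]))
  }
  check_pvalues(joined$pvalue, "pvalue")
  dplyr::summarise(
    dplyr::group_by(joined, .data$gene_id),
    pvalue = min(.data$pvalue),
    n_snps = dplyr::n(),
    .groups = "drop"
  )
}

#' Adjust gene p-values for gene size by phenotype permutation
#'
#' Genes with many SNPs are mechanically more likely to receive a small
#' minimum p-value. Given the observed per-gene minimum p-values and a matrix
#' of the same statistic recomputed under B phenotype-label permutations, the
#' adjusted p-value of gene g is
#' \deqn{p_g^{adj} = \frac{1 + \#\{b : p_g^{(b)} \le p_g\}}{1 + B},}
#' which calibrates each gene against its own permutation distribution and so
#' removes the size bias.
#'
#' @param observed Data frame with columns `gene_id`, `pvalue`.
#' @param permuted Numeric matrix, B rows (permutations) by genes; column
#'   names must match `observed$gene_id` (any order).
#' @return Tibble with `gene_id`, `pvalue` (adjusted), `raw_pvalue`.
#' @export
adjusted_gene_p <- function(observed, permuted) {
  if (nrow(permuted) < 100) abort("at least 100 permutations are required.")
  if (is.null(colnames(permuted)) ||
      !setequal(colnames(permuted), observed$gene_id) ||
      ncol(permuted) != length(observed$gene_id)) {
    abort("`permuted` columns must match `observed$gene_id` exactly.")
  }
  perm <- permuted[, observed$gene_id, drop = FALSE]
  B <- nrow(perm)
  cnt <- colSums(perm <= matrix(observed$pvalue, nrow = B,
                                ncol = ncol(perm), byrow = TRUE))
  tibble(
    gene_id = observed$gene_id,
    pvalue = (1 + unname(cnt)) / (1 + B),
    raw_pvalue = observed$pvalue
  )
}

#' Run every method over a gene-set database
#'
#' Convenience wrapper for real-data style analyses: builds the score
#' container from a gene p-value table, runs [enrich_pathways()], and
#' attaches the per-method count of nominally significant pathways.
#'
#' @param gene_pvalues Data frame with columns `gene_id`, `pvalue`.
#' @param sets Gene-set collection (see [enrich_pathways()]).
#' @param methods,B,R,top_n,min_size,seed Passed to [enrich_pathways()].
#' @param alpha Nominal level for the significance count.
#' @return A `pr_enrich` tibble with attribute `significant` (the
#'   [count_significant()] table).
#' @export
run_database <- function(gene_pvalues, sets,
                         methods = c("fm", "tsm_e", "gsea", "artp_e", "hyper"),
                         B = 1000, R = 1e5, top_n = 2000, min_size = 2,
                         alpha = 0.05, seed = NULL) {
  scores <- if (inherits(gene_pvalues, "pr_scores") && "u" %in% names(gene_pvalues)) {
    gene_pvalues
  } else {
    gene_scores(as.data.frame(gene_pvalues)[, c("gene_id", "pvalue")])
  }
  out <- enrich_pathways(scores, sets, methods = methods, B = B, R = R,
                         top_n = top_n, min_size = min_size, seed = seed)
  attr(out, "significant") <- count_significant(out, alpha = alpha)
  out
}
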