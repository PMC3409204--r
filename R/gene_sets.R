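#' Read gene sets from a GMT file
#'
#' Parses the MSigDB GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then member gene ids. Duplicate gene ids within a
#' line are dropped. Ids are matched verbatim downstream; no alias
#' translation is attempted.
#'
#' @param path Path to a `.gmt` file.
#' @param source Free-text provenance label stored with the collection;
#'   defaults to the file name.
#' @return A `pr_sets` tibble in long format with columns `set`,
#'   `description`, `gene` (one row per set-gene pair).
#' @export
read_gmt <- function(path, source = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("no gene sets found in '%s'.", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 fields (name, description, genes).", short[1]))
  }
  rows <- purrr::map(parts, function(f) {
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    tibble(set = f[1], description = f[2], gene = genes)
  })
  out <- dplyr::bind_rows(rows)
  gene_sets(out, source = source)
}

#' Construct a gene-set collection
#'
#' Accepts either a named list of character vectors or a long data frame with
#' columns `set` and `gene` (optionally `description`), and validates it:
#' unique set names, no empty sets.
#'
#' @param x Named list of gene-id vectors, or a long data frame.
#' @param source Free-text provenance label (e.g. database name).
#' @return A `pr_sets` tibble with columns `set`, `description`, `gene`.
#' @export
gene_sets <- function(x, source = NULL) {
  if (is.list(x) && !is.data.frame(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      abort("gene-set lists must be named.")
    }
    x <- dplyr::bind_rows(purrr::imap(x, function(g, nm) {
      tibble(set = nm, description = "", gene = unique(as.character(g)))
    }))
  }
  if (!is.data.frame(x)) abort("`x` must be a named list or a data frame.")
  if (!all(c("set", "gene") %in% names(x))) {
    abort("`x` must have columns `set` and `gene`.")
  }
  if (!"description" %in% names(x)) x$description <- ""
  out <- as_tibble(x[, c("set", "description", "gene")])
  out <- dplyr::distinct(out, .data$set, .data$gene, .keep_all = TRUE)
  sizes <- table(out$set)
  if (any(sizes == 0) || nrow(out) == 0) abort("empty gene sets are not allowed.")
  attr(out, "source") <- source
  class(out) <- c("pr_sets", class(out))
  out
}

#' Restrict a gene-set collection to a study universe
#'
#' Drops member genes that are absent from the score table's gene universe
#' and then drops sets that fall below the minimum size. Pathway size L used
#' by every test is the post-intersection size. Counts of dropped genes and
#' sets are recorded in attributes and reported via warnings.
#'
#' @param sets A `pr_sets` tibble (see [gene_sets()], [read_gmt()]).
#' @param scores A `pr_scores` tibble defining the universe.
#' @param min_size Minimum post-intersection set size to keep. Default 2:
#'   the combination tests are defined (if degenerate) at size 1, but the
#'   KS-type test needs at least one hit and one miss.
#' @return A filtered `pr_sets` tibble with attributes `dropped_genes`
#'   (count) and `dropped_sets` (character vector of removed set names).
#' @export
restrict_to_universe <- function(sets, scores, min_size = 2) {
  stopifnot(is.data.frame(sets), is.data.frame(scores))
  inside <- sets$gene %in% scores$gene_id
  n_dropped <- sum(!inside)
  kept <- sets[inside, , drop = FALSE]
  sizes <- table(kept$set)
  small <- names(sizes)[sizes < min_size]
  gone <- union(small, setdiff(unique(sets$set), unique(kept$set)))
  if (length(gone) > 0) {
    warn(sprintf(
      "%d set(s) dropped below min_size = %d after universe restriction: %s",
      length(gone), min_size, paste(utils::head(gone, 5), collapse = ", ")
    ))
    kept <- kept[!(kept$set %in% gone), , drop = FALSE]
  }
  out <- as_tibble(kept)
  attr(out, "source") <- attr(sets, "source")
  attr(out, "dropped_genes") <- n_dropped
  attr(out, "dropped_sets") <- gone
  class(out) <- c("pr_sets", class(out))
  out
}

# Named list view of a collection (used by the per-pathway test loops).
as_set_list <- function(sets) {
  if (is.list(sets) && !is.data.frame(sets)) {
    return(lapply(sets, as.character))
  }
  split(as.character(sets$gene), sets$set)
}
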