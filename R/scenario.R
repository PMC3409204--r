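#' Define a simulation scenario
#'
#' One configuration of the simulation study. Null scenarios place M effect
#' SNPs at random, independent of the (also random) pathway; alternative
#' scenarios concentrate a proportion `pi` of the pathway in the effect set
#' with a larger effect variance than the non-pathway effect SNPs.
#'
#' @param kind `"null"` or `"alternative"`.
#' @param L Pathway size.
#' @param M Total number of SNPs with effects.
#' @param N Number of individuals (default 100).
#' @param K Number of SNPs/genes (default 20000).
#' @param sigma2_null Effect variance for null scenarios.
#' @param pi Proportion of pathway genes with effects (alternative only).
#' @param sigma1_sq,sigma2_sq Pathway / non-pathway effect variances
#'   (alternative only; must satisfy `sigma1_sq > sigma2_sq`).
#' @return A one-row tibble describing the scenario.
#' @export
scenario <- function(kind = c("null", "alternative"), L, M, N = 100, K = 20000,
                     sigma2_null = NULL, pi = NULL,
                     sigma1_sq = NULL, sigma2_sq = NULL) {
  kind <- match.arg(kind)
  scn <- tibble(
    kind = kind, L = as.integer(L), M = as.integer(M),
    N = as.integer(N), K = as.integer(K),
    sigma2_null = if (kind == "null") as.numeric(sigma2_null) else NA_real_,
    pi = if (kind == "alternative") as.numeric(pi) else NA_real_,
    sigma1_sq = if (kind == "alternative") as.numeric(sigma1_sq) else NA_real_,
    sigma2_sq = if (kind == "alternative") as.numeric(sigma2_sq) else NA_real_
  )
  validate_scenario(scn)
}

validate_scenario <- function(scn) {
  scn <- as_tibble(as.list(scn))
  stopifnot(nrow(scn) == 1)
  if (scn$K < 2 || scn$L < 1 || scn$L > scn$K || scn$M < 1 || scn$M > scn$K) {
    abort("need 1 <= L <= K and 1 <= M <= K.")
  }
  if (scn$kind == "null") {
    if (!is.finite(scn$sigma2_null) || scn$sigma2_null <= 0) {
      abort("null scenarios need a positive `sigma2_null`.")
    }
  } else {
    if (!is.finite(scn$pi) || scn$pi <= 0 || scn$pi > 1) {
      abort("alternative scenarios need `pi` in (0, 1].")
    }
    if (!is.finite(scn$sigma1_sq) || !is.finite(scn$sigma2_sq) ||
        scn$sigma1_sq <= scn$sigma2_sq) {
      abort("alternative scenarios need sigma1_sq > sigma2_sq > 0.")
    }
    if (round(scn$pi * scn$L) > scn$M) {
      abort("round(pi * L) cannot exceed M.")
    }
  }
  scn
}

#' Read or write a scenario configuration
#'
#' Scenarios serialize to YAML or JSON (by file extension) using the same
#' field names as [scenario()], so simulation configurations can live in
#' version-controlled config files.
#'
#' @param scn A scenario row.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns a validated one-row scenario tibble.
#' @export
write_scenario <- function(scn, path) {
  scn <- validate_scenario(scn)
  fields <- as.list(scn)
  fields <- fields[!vapply(fields, function(x) is.na(x) %in% TRUE, logical(1))]
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(fields, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  } else {
    abort("`path` must end in .yaml, .yml or .json.")
  }
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  fields <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path)
  } else {
    abort("`path` must end in .yaml, .yml or .json.")
  }
  fields$scenario_id <- NULL
  do.call(scenario, fields)
}

#' The null scenario grid
#'
#' Full factorial over pathway size L in \{20, 60, 100\}, effect-SNP count M
#' in \{50, 100, 200\} and effect variance in \{1, 2, 4\} — 27 scenarios,
#' all with N = 100 individuals and K = 20000 SNPs/genes. Pooled rejection
#' rates over this grid at alpha = 0.05 estimate each method's type-I error
#' under the competitive null.
#'
#' @param N,K Study dimensions (defaults 100 and 20000).
#' @return Tibble of 27 scenario rows with a `scenario_id` column,
#'   deterministically ordered.
#' @export
null_grid <- function(N = 100, K = 20000) {
  g <- tidyr::crossing(L = c(20L, 60L, 100L), M = c(50L, 100L, 200L),
                       sigma2_null = c(1, 2, 4))
  g <- dplyr::mutate(g, kind = "null", N = as.integer(N), K = as.integer(K),
                     pi = NA_real_, sigma1_sq = NA_real_, sigma2_sq = NA_real_)
  g <- dplyr::select(g, "kind", "L", "M", "N", "K", "sigma2_null",
                     "pi", "sigma1_sq", "sigma2_sq")
  dplyr::mutate(g, scenario_id = dplyr::row_number(), .before = 1)
}

#' Alternative (power) scenario grid
#'
#' Enrichment scenarios over pathway size, effect-SNP count, the proportion
#' `pi` of pathway genes with effects, and (pathway, non-pathway) effect
#' variance pairs. Defaults follow the power-study axes: pi in
#' \{0.4, 0.6, 1.0\} and variance pairs (4,2), (4,1), (2,1). Combinations
#' with `round(pi * L) > M` are dropped.
#'
#' @param L,M,pi Vectors of pathway sizes, effect counts and proportions.
#' @param var_pairs List of `c(sigma1_sq, sigma2_sq)` pairs.
#' @param N,K Study dimensions.
#' @return Tibble of scenario rows with a `scenario_id` column.
#' @export
alt_grid <- function(L = c(20L, 60L, 100L), M = c(50L, 100L, 200L),
                     pi = c(0.4, 0.6, 1.0),
                     var_pairs = list(c(4, 2), c(4, 1), c(2, 1)),
                     N = 100, K = 20000) {
  vp <- tibble(
    sigma1_sq = vapply(var_pairs, `[`, numeric(1), 1),
    sigma2_sq = vapply(var_pairs, `[`, numeric(1), 2)
  )
  g <- tidyr::crossing(L = as.integer(L), M = as.integer(M), pi = pi, vp)
  g <- dplyr::filter(g, round(.data$pi * .data$L) <= .data$M)
  g <- dplyr::mutate(g, kind = "alternative", N = as.integer(N), K = as.integer(K),
                     sigma2_null = NA_real_)
  g <- dplyr::select(g, "kind", "L", "M", "N", "K", "sigma2_null",
                     "pi", "sigma1_sq", "sigma2_sq")
  dplyr::mutate(g, scenario_id = dplyr::row_number(), .before = 1)
}
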