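# Scenario driver: replicate loop, per-method rejection rates.

study_method_labels <- c("fm", "fm_perm", "tsm", "tsm_e", "gsea",
                         "artp", "artp_e", "hyper", "hyper_t")

#' Estimate rejection rates for one scenario
#'
#' Simulates `n_reps` datasets from the scenario, computes scaled ranks, runs
#' each requested method on the simulated pathway, and counts rejections at
#' `alpha`. Under a null scenario the rate estimates type-I error; under an
#' alternative scenario it estimates power.
#'
#' Method labels: `"fm"` (Fisher, asymptotic chi-square), `"fm_perm"`
#' (Fisher, gene-label permutation), `"tsm"` (tail strength, normal
#' approximation), `"tsm_e"` (tail strength, empirical-uniform null),
#' `"gsea"` (weighted KS, label permutation), `"artp"` (adaptive rank
#' truncated product, label permutation), `"artp_e"` (ARTP,
#' empirical-uniform null), `"hyper"` (hypergeometric, top-`top_n` list),
#' `"hyper_t"` (hypergeometric, threshold list `p < hyper_alpha`; its null is
#' very discrete, making the test conservative at small thresholds).
#'
#' The empirical and permutation null samples depend only on (K, L), so they
#' are built once per scenario and shared across its replicates; each
#' replicate then costs one simulated GWAS plus the per-pathway statistics.
#' Per-replicate seeds are derived from `(seed, scenario_id, replicate)`, so
#' scenarios are reproducible independently of one another.
#'
#' @param scn A scenario row ([scenario()], or one row of [null_grid()] /
#'   [alt_grid()]).
#' @param methods Character vector of method labels (see above).
#' @param n_reps Number of simulated datasets (>= 50).
#' @param alpha Nominal significance level (default 0.05).
#' @param seed Master integer seed.
#' @param B Permutation replicates for `fm_perm`, `gsea`, `artp`, `artp_e`.
#' @param R Empirical null sample size for `tsm_e`.
#' @param top_n Significant-list length for `hyper` (default 2000).
#' @param hyper_alpha Significance threshold for `hyper_t`.
#' @return A `pr_study` tibble: scenario fields plus `method`, `n_reps`,
#'   `rejections`, `rate`, `se` (binomial standard error).
#' @export
run_scenario <- function(scn, methods = c("fm", "tsm_e", "gsea", "artp_e", "hyper"),
                         n_reps = 1000, alpha = 0.05, seed = 1,
                         B = 1000, R = 1e5, top_n = 2000, hyper_alpha = NULL) {
  scn <- validate_scenario(scn)
  bad <- setdiff(methods, study_method_labels)
  if (length(bad) > 0) {
    abort(sprintf("unknown method(s): %s. Valid labels: %s.",
                  paste(bad, collapse = ", "),
                  paste(study_method_labels, collapse = ", ")))
  }
  if (n_reps < 50) abort("n_reps must be at least 50.")
  if ("hyper_t" %in% methods && is.null(hyper_alpha)) {
    abort("method 'hyper_t' needs `hyper_alpha`.")
  }
  sid <- if ("scenario_id" %in% names(scn)) scn$scenario_id else 0L
  K <- scn$K
  L <- scn$L
  n_top <- min(top_n, K)

  # Shared null machinery (depends only on K and L).
  set.seed(derive_seed(seed, sid, 0L))
  tsm_null_obj <- if ("tsm_e" %in% methods) tsm_null(L, R = R) else NULL
  artp_perm_null <- if ("artp" %in% methods) artp_null(L, B = B, source = "permutation", K = K) else NULL
  artp_emp_null <- if ("artp_e" %in% methods) artp_null(L, B = B, source = "empirical_uniform") else NULL
  fm_perm_null <- if ("fm_perm" %in% methods) {
    sort(fm_perm_nulls(seq_len(K) / K, L, B))
  } else NULL

  rej <- stats::setNames(numeric(length(methods)), methods)
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, sid, r))
    sim <- simulate_gwas(scn)
    u_path <- sort(sim$u[sim$pathway_idx])
    pv <- replicate_pvalues(sim, u_path, methods, K, L, B, n_top,
                            tsm_null_obj, artp_perm_null, artp_emp_null,
                            fm_perm_null, hyper_alpha)
    rej <- rej + (pv <= alpha)
  }
  out <- tidyr::crossing(scn, tibble(method = methods))
  out$n_reps <- as.integer(n_reps)
  out$rejections <- as.integer(rej[out$method])
  out$rate <- out$rejections / n_reps
  out$se <- sqrt(out$rate * (1 - out$rate) / n_reps)
  out$alpha <- alpha
  class(out) <- c("pr_study", class(out))
  out
}

# Per-replicate p-values for all requested methods (internal fast paths;
# the exported *_test() functions compute identical values on score tables).
replicate_pvalues <- function(sim, u_path, methods, K, L, B, n_top,
                              tsm_null_obj, artp_perm_null, artp_emp_null,
                              fm_perm_null, hyper_alpha = NULL) {
  pv <- stats::setNames(numeric(length(methods)), methods)
  for (m in methods) {
    pv[m] <- switch(
      m,
      fm = fm_pvalue_asymptotic(u_path),
      fm_perm = {
        stat <- -2 * sum(log(u_path))
        (1 + length(fm_perm_null) - findInterval(stat, fm_perm_null, left.open = TRUE)) /
          (1 + length(fm_perm_null))
      },
      tsm = tsm_pvalue_normal(tsm_statistic(u_path), L),
      tsm_e = tsm_pvalue_empirical(tsm_statistic(u_path), tsm_null_obj),
      gsea = {
        prep <- gsea_prepare(sim$pvalues)
        member <- logical(K)
        member[sim$pathway_idx] <- TRUE
        hits <- which(member[prep$ord])
        es <- gsea_es_core(prep$w_ranked, hits, K)
        nulls <- gsea_null_es_cpp(prep$w_ranked, L, as.integer(B))
        (1 + sum(nulls >= es)) / (1 + B)
      },
      artp = artp_eval(cumsum(log(u_path)), artp_perm_null)$pvalue,
      artp_e = artp_eval(cumsum(log(u_path)), artp_emp_null)$pvalue,
      hyper = hyper_pvalue_from_ranks(u_path, K, n_top)$pvalue,
      hyper_t = {
        n_sig <- sum(sim$pvalues < hyper_alpha)
        k_sig <- sum(sim$pvalues[sim$pathway_idx] < hyper_alpha)
        phyper(k_sig - 1, m = L, n = K - L, k = n_sig, lower.tail = FALSE)
      }
    )
  }
  pv
}

#' Run a grid of scenarios
#'
#' Applies [run_scenario()] to every row of a scenario grid and binds the
#' results.
#'
#' @param grid Tibble of scenario rows ([null_grid()], [alt_grid()]).
#' @param ... Passed to [run_scenario()] (`methods`, `n_reps`, `alpha`, `B`,
#'   `R`, `top_n`).
#' @param seed Master integer seed shared by all scenarios (per-scenario
#'   streams are derived from it).
#' @param verbose Print one progress line per scenario.
#' @return A `pr_study` tibble with one row per (scenario, method).
#' @export
run_grid <- function(grid, ..., seed = 1, verbose = FALSE) {
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    if (verbose) {
      message(sprintf("scenario %d/%d", i, nrow(grid)))
    }
    run_scenario(grid[i, ], ..., seed = seed)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pr_study", class(out))
  out
}

#' Summarize rejection rates across scenarios
#'
#' Unweighted mean of per-scenario rejection rates within each method-by-group
#' cell (each scenario contributes equally), with the number of scenarios and
#' total replicates per cell.
#'
#' @param results A `pr_study` tibble from [run_scenario()] / [run_grid()].
#' @param group_by Extra grouping columns besides `method` (e.g. `"L"`,
#'   `"pi"`); default none, giving one pooled mean per method.
#' @return Tibble with columns `method`, the grouping columns, `mean_rate`,
#'   `n_scenarios`, `total_reps`, `se` (of the pooled mean, treating
#'   replicates as independent Bernoulli draws).
#' @export
summarize_study <- function(results, group_by = character()) {
  stopifnot(is.data.frame(results))
  grp <- c("method", group_by)
  out <- dplyr::summarise(
    dplyr::group_by(results, dplyr::across(dplyr::all_of(grp))),
    mean_rate = mean(.data$rate),
    n_scenarios = dplyr::n(),
    total_reps = sum(.data$n_reps),
    se = sqrt(.data$mean_rate * (1 - .data$mean_rate) / .data$total_reps),
    .groups = "drop"
  )
  dplyr::arrange(out, dplyr::desc(.data$mean_rate))
}
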