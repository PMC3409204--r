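# ggplot2 views of the two result types.

#' Plot rejection rates of a simulation study
#'
#' Power (or type-I error) by method. When the results span several values of
#' `x` (e.g. `pi` or `L`), rates are drawn as lines over `x`, one colour per
#' method, with 3-SE ribbons; otherwise a bar per method.
#'
#' @param object A `pr_study` tibble from [run_scenario()] / [run_grid()].
#' @param x Optional scenario column to put on the x axis (`"pi"`, `"L"`, ...).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pr_study <- function(object, x = NULL, ...) {
  alpha <- unique(object$alpha)[1]
  if (!is.null(x) && length(unique(object[[x]])) > 1) {
    dat <- dplyr::summarise(
      dplyr::group_by(object, .data$method, dplyr::across(dplyr::all_of(x))),
      rate = mean(.data$rate),
      se = sqrt(.data$rate * (1 - .data$rate) / sum(.data$n_reps)),
      .groups = "drop"
    )
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data[[x]], y = .data$rate,
                                           colour = .data$method)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$rate - 3 * .data$se, 0),
                                        ymax = pmin(.data$rate + 3 * .data$se, 1),
                                        fill = .data$method),
                           alpha = 0.15, colour = NA) +
      ggplot2::geom_line() +
      ggplot2::geom_point()
  } else {
    dat <- dplyr::summarise(
      dplyr::group_by(object, .data$method),
      rate = mean(.data$rate), .groups = "drop"
    )
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$method, y = .data$rate)) +
      ggplot2::geom_col(fill = "grey35")
  }
  p +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2, colour = "grey50") +
    ggplot2::labs(y = "rejection rate", x = x %||% "method") +
    ggplot2::theme_minimal()
}

#' Plot enrichment results
#'
#' Dot plot of -log10 p-values per pathway, one colour per method, with the
#' nominal 0.05 level marked.
#'
#' @param object A `pr_enrich` tibble.
#' @param alpha Nominal level to mark (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pr_enrich <- function(object, alpha = 0.05, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = -log10(.data$pvalue),
                                       y = stats::reorder(.data$pathway, -.data$pvalue),
                                       colour = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = 2, colour = "grey50") +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL) +
    ggplot2::theme_minimal()
}

#' Running-sum profile of the weighted KS statistic
#'
#' Draws the full K-step running sum for one pathway, with hit positions
#' marked; the enrichment score is the maximum of the walk.
#'
#' @param scores A `pr_scores` tibble.
#' @param pathway Character vector of member gene ids.
#' @param weight_exponent Hit-weight exponent (default 1).
#' @return A ggplot object.
#' @export
plot_running_sum <- function(scores, pathway, weight_exponent = 1) {
  idx <- pathway_index(scores, pathway)
  K <- nrow(scores)
  L <- length(idx)
  if (L < 1 || L >= K) abort("pathway must have >= 1 member and >= 1 non-member.")
  prep <- gsea_prepare(scores$pvalue, weight_exponent)
  member <- logical(K)
  member[idx] <- TRUE
  hits <- which(member[prep$ord])
  inc <- rep(-1 / (K - L), K)
  w <- prep$w_ranked[hits]
  NR <- sum(w)
  inc[hits] <- if (NR > 0) w / NR else 1 / L
  walk <- tibble(position = seq_len(K), running_sum = cumsum(inc))
  ggplot2::ggplot(walk, ggplot2::aes(x = .data$position, y = .data$running_sum)) +
    ggplot2::geom_line() +
    ggplot2::geom_rug(data = tibble(position = hits), sides = "b",
                      ggplot2::aes(x = .data$position), inherit.aes = FALSE,
                      alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::labs(y = "running sum") +
    ggplot2::theme_minimal()
}
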