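#' Draw minor allele frequencies
#'
#' K i.i.d. draws from Uniform(0, 0.5), one per SNP.
#'
#' @param K Number of SNPs.
#' @param seed Optional integer seed.
#' @return Numeric vector of length K.
#' @export
sample_maf <- function(K, seed = NULL) {
  if (K < 1) abort("K must be at least 1.")
  maybe_seed(seed)
  runif(K, 0, 0.5)
}

#' Simulate a genotype matrix under Hardy-Weinberg equilibrium
#'
#' Entries of column j are i.i.d. over \{0, 1, 2\} with probabilities
#' \eqn{((1-q_j)^2,\; 2q_j(1-q_j),\; q_j^2)} where \eqn{q_j} is the SNP's
#' minor allele frequency. SNPs are independent (no linkage disequilibrium).
#'
#' @param N Number of individuals (rows).
#' @param K Number of SNPs (columns).
#' @param maf Length-K vector of allele frequencies in (0, 0.5].
#' @param seed Optional integer seed.
#' @return An N x K numeric matrix with entries 0, 1, 2.
#' @export
genotype_matrix <- function(N, K, maf, seed = NULL) {
  if (length(maf) != K) abort("`maf` must have length K.")
  if (any(!is.finite(maf) | maf <= 0 | maf > 0.5)) {
    abort("all `maf` entries must lie in (0, 0.5].")
  }
  maybe_seed(seed)
  genotype_matrix_cpp(as.integer(N), as.integer(K), as.numeric(maf))
}

#' Assign sparse random SNP effects
#'
#' Under a null scenario, M effect SNPs are drawn uniformly from the K study
#' SNPs with effects \eqn{\beta \sim N(0, \sigma^2)}, and the L pathway
#' members are drawn independently, so pathway membership carries no signal.
#' Under an alternative scenario the pathway is drawn first;
#' `round(pi * L)` of its members receive effects from \eqn{N(0, \sigma_1^2)}
#' and the remaining `M - round(pi * L)` effect SNPs are drawn from outside
#' the pathway with \eqn{N(0, \sigma_2^2)}, \eqn{\sigma_1^2 > \sigma_2^2}
#' encoding the enrichment. All draws are without replacement.
#'
#' @param scn A scenario row from [scenario()], [null_grid()] or [alt_grid()].
#' @param seed Optional integer seed.
#' @return List with `beta` (length-K effect vector, M nonzeros) and
#'   `pathway_idx` (L SNP indices).
#' @export
assign_effects <- function(scn, seed = NULL) {
  scn <- as.list(scn)
  maybe_seed(seed)
  K <- scn$K; L <- scn$L; M <- scn$M
  beta <- numeric(K)
  if (scn$kind == "null") {
    eff <- sample.int(K, M)
    beta[eff] <- rnorm(M, 0, sqrt(scn$sigma2_null))
    pathway_idx <- sample.int(K, L)
  } else {
    m1 <- round(scn$pi * L)
    if (m1 > M) abort("round(pi * L) cannot exceed M.")
    pathway_idx <- sample.int(K, L)
    in_path <- pathway_idx[sample.int(L, m1)]
    outside <- seq_len(K)[-pathway_idx]
    out_eff <- outside[sample.int(K - L, M - m1)]
    beta[in_path] <- rnorm(m1, 0, sqrt(scn$sigma1_sq))
    beta[out_eff] <- rnorm(M - m1, 0, sqrt(scn$sigma2_sq))
  }
  list(beta = beta, pathway_idx = pathway_idx)
}

#' Additive quantitative phenotype
#'
#' \eqn{y_i = \sum_j \beta_j g_{ij} + \epsilon_i} with
#' \eqn{\epsilon_i \sim N(0, \mathrm{noise\_sd}^2)}. The default
#' `noise_sd = 0` makes the non-pathway effect SNPs the only noise
#' background, so y = G beta exactly.
#'
#' @param genotypes N x K genotype matrix.
#' @param beta Length-K effect vector.
#' @param noise_sd Environmental noise standard deviation (default 0).
#' @param seed Optional integer seed.
#' @return Numeric phenotype vector of length N.
#' @export
phenotype <- function(genotypes, beta, noise_sd = 0, seed = NULL) {
  if (ncol(genotypes) != length(beta)) abort("`beta` must have one entry per SNP.")
  maybe_seed(seed)
  nz <- which(beta != 0)
  y <- if (length(nz) > 0) {
    as.vector(genotypes[, nz, drop = FALSE] %*% beta[nz])
  } else {
    numeric(nrow(genotypes))
  }
  if (noise_sd > 0) y <- y + rnorm(nrow(genotypes), 0, noise_sd)
  y
}

#' Single-SNP association p-values
#'
#' Two-sided p-value of the slope t-test in the simple linear regression of
#' the phenotype on each genotype column (equivalently the Pearson
#' correlation t-test with N - 2 degrees of freedom), computed for all K
#' columns at once. Monomorphic columns get p = 1 by convention.
#'
#' @param genotypes N x K genotype matrix.
#' @param y Phenotype vector of length N (non-constant).
#' @return Numeric vector of K p-values.
#' @export
single_snp_pvalues <- function(genotypes, y) {
  N <- nrow(genotypes)
  if (N < 3) abort("at least 3 individuals are required.")
  if (length(y) != N) abort("`y` must have one entry per individual.")
  yc <- y - mean(y)
  ssy <- sum(yc^2)
  if (ssy == 0) abort("`y` is constant; association is undefined.")
  Gy <- as.vector(crossprod(genotypes, yc))
  cs <- .colSums(genotypes, N, ncol(genotypes))
  cs2 <- .colSums(genotypes * genotypes, N, ncol(genotypes))
  ssG <- cs2 - cs^2 / N
  mono <- ssG <= 0
  r2 <- numeric(length(ssG))
  ok <- !mono
  r2[ok] <- Gy[ok]^2 / (ssG[ok] * ssy)
  r2 <- pmin(r2, 1)
  tt <- sqrt(r2 * (N - 2) / pmax(1 - r2, .Machine$double.xmin))
  p <- 2 * pt(tt, df = N - 2, lower.tail = FALSE)
  p[mono] <- 1
  p
}

#' Simulate one GWAS dataset from a scenario
#'
#' Runs the full generative chain of the simulation study: MAFs from
#' Uniform(0, 0.5), Hardy-Weinberg genotypes, sparse random effects, additive
#' phenotype, and per-SNP regression p-values. One SNP is one gene, so the
#' p-value vector feeds the enrichment tests directly.
#'
#' @param scn A scenario row (see [scenario()]).
#' @param seed Optional integer seed; the whole dataset is a deterministic
#'   function of (scenario, seed).
#' @param noise_sd Environmental noise passed to [phenotype()].
#' @param keep_genotypes Keep the N x K genotype matrix in the result
#'   (default `FALSE` to save memory).
#' @return A `pr_sim` list: `maf`, `beta`, `pathway_idx`, `pvalues`, `u`
#'   (scaled ranks), `scenario`, and optionally `genotypes`.
#' @export
simulate_gwas <- function(scn, seed = NULL, noise_sd = 0, keep_genotypes = FALSE) {
  scn <- validate_scenario(scn)
  maybe_seed(seed)
  maf <- runif(scn$K, 0, 0.5)
  G <- genotype_matrix_cpp(as.integer(scn$N), as.integer(scn$K), maf)
  eff <- assign_effects(scn)
  y <- phenotype(G, eff$beta, noise_sd = noise_sd)
  p <- single_snp_pvalues(G, y)
  out <- list(
    maf = maf, beta = eff$beta, pathway_idx = eff$pathway_idx,
    pvalues = p, u = rank(p, ties.method = "first") / scn$K,
    y = y, scenario = scn
  )
  if (keep_genotypes) out$genotypes <- G
  structure(out, class = "pr_sim")
}

#' @export
print.pr_sim <- function(x, ...) {
  s <- x$scenario
  cat(sprintf("<pr_sim: %s scenario, N = %d, K = %d, L = %d, M = %d>\n",
              s$kind, s$N, s$K, s$L, s$M))
  invisible(x)
}

#' Gene p-value table of a simulated study
#'
#' Exports a simulated study to the shared `gene_id` / `pvalue` format, so
#' simulated and real inputs flow through the same front door.
#'
#' @param sim A `pr_sim` object.
#' @return A `pr_scores` tibble (gene ids `g000001`, ...).
#' @export
sim_scores <- function(sim) {
  stopifnot(inherits(sim, "pr_sim"))
  gene_scores(tibble(
    gene_id = sprintf("g%06d", seq_along(sim$pvalues)),
    pvalue = sim$pvalues
  ))
}
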