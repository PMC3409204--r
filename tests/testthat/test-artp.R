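test_that("rank truncated products are running products of sorted ranks", {
  expect_equal(rtp_statistic(c(0.1, 0.2), 1), 0.1)
  expect_equal(rtp_statistic(c(0.1, 0.2), 2), 0.02, tolerance = 1e-12)
  expect_error(rtp_statistic(c(0.2, 0.1), 1), "sorted")
  expect_error(rtp_statistic(c(0.1, 0.2), 3), "1..2")
})

test_that("-2 log W(L) is exactly the Fisher statistic", {
  set.seed(61)
  for (i in 1:20) {
    u <- sort(runif(sample(2:30, 1)))
    expect_equal(-2 * log(rtp_statistic(u, length(u))), fisher_statistic(u),
                 tolerance = 1e-12)
  }
})

test_that("with a single truncation point ARTP equals the shared-draw permutation p", {
  set.seed(62)
  sc <- make_scores(500)
  pathway <- sample(sc$gene_id, 6)
  u_path <- sort(sc$u[match(pathway, sc$gene_id)])
  # Shared null draws, full-product column only: ARTP must reduce to the
  # permutation p-value of the Fisher statistic computed on the same draws.
  B <- 500
  draws <- t(vapply(1:B, function(b) sort(sc$u[sample.int(500, 6)]), numeric(6)))
  logW_full <- matrix(rowSums(log(draws)), ncol = 1)
  null1 <- structure(list(
    logW = logW_full,
    sortedW = matrix(sort(logW_full), ncol = 1),
    rmax = matrix(rank(logW_full, ties.method = "max"), ncol = 1),
    B = B, L = 1L, K = 500L, source = "permutation"
  ), class = "pr_artp_null")
  artp_p <- pathrank:::artp_eval(sum(log(u_path)), null1)$pvalue
  fm_obs <- -2 * sum(log(u_path))
  fm_nulls <- -2 * rowSums(log(draws))
  expect_equal(artp_p, permutation_pvalue(fm_obs, fm_nulls, "greater"),
               tolerance = 1e-12)
})

test_that("for L = 1 the ARTP p-value is the permutation p of the smallest rank", {
  set.seed(63)
  sc <- make_scores(200)
  gene <- sc$gene_id[which.min(sc$pvalue)]
  res <- artp_test(sc, gene, B = 400, null_source = "permutation", seed = 64)
  set.seed(64)
  null <- artp_null(1, B = 400, source = "permutation", K = 200)
  u_obs <- min(sc$u)
  expect_equal(res$pvalue,
               (1 + sum(exp(null$logW[, 1]) <= u_obs + 1e-12)) / 401,
               tolerance = 1e-9)
  expect_equal(res$extras[[1]]$j_hat, 1L)
})

test_that("Ge's single-level scheme matches a naive two-level oracle", {
  # Oracle: each first-level replicate gets its own fresh second-level
  # permutation set for estimating its per-j p-values; the package reuses one
  # pooled set. Both target the same ARTP p-value.
  set.seed(65)
  K <- 60; L <- 3; B <- 200
  sc <- make_scores(K, seed = 66)
  pathway <- sample(sc$gene_id, L)
  means <- artp_oracle_comparison(sc, pathway, B = B, B2 = 600, m = 5, seed = 67)
  expect_lt(abs(means["impl"] - means["oracle"]), 0.02)
})

test_that("ARTP p-values are super-uniform for random pathways", {
  set.seed(69)
  sc <- make_scores(500)
  # fresh permutation nulls per repeat: observed and null replicates are then
  # exactly exchangeable, so the p-value is exactly super-uniform and the
  # repeats are independent (a single shared null sample would correlate them)
  p <- replicate(2000, {
    null <- artp_null(8, B = 100, source = "permutation", K = 500)
    u <- sort(sc$u[sample.int(500, 8)])
    pathrank:::artp_eval(cumsum(log(u)), null)$pvalue
  })
  for (alpha in c(0.01, 0.05, 0.1)) {
    se <- sqrt(alpha * (1 - alpha) / 2000)
    expect_lte(mean(p <= alpha), alpha + 3 * se)
  }
})

test_that("input contracts: B floor, L vs K, empirical allows L > K", {
  sc <- make_scores(50)
  expect_error(artp_test(sc, sc$gene_id[1:3], B = 50), "at least 100")
  expect_error(artp_null(60, B = 200, source = "permutation", K = 50), "exceed")
  null <- artp_null(60, B = 200, source = "empirical_uniform")
  expect_equal(null$L, 60L)
})

test_that("empirical-uniform results are reproducible for a fixed seed", {
  sc <- make_scores(300, seed = 71)
  set.seed(72)
  pathway <- sample(sc$gene_id, 12)
  a <- artp_test(sc, pathway, B = 300, null_source = "empirical_uniform", seed = 73)
  b <- artp_test(sc, pathway, B = 300, null_source = "empirical_uniform", seed = 73)
  expect_identical(a$pvalue, b$pvalue)
  expect_identical(a$extras[[1]]$phat, b$extras[[1]]$phat)
})
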