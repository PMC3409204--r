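# Cross-cutting invariants of the five tests.

test_that("rank-based tests are invariant to monotone transforms of p-values", {
  set.seed(121)
  K <- 400
  p <- runif(K)
  sc1 <- gene_scores(data.frame(gene_id = sprintf("g%03d", 1:K), pvalue = p))
  sc2 <- gene_scores(data.frame(gene_id = sprintf("g%03d", 1:K), pvalue = p^2))
  pathway <- sample(sc1$gene_id, 12)
  expect_equal(fisher_test(sc1, pathway)$pvalue, fisher_test(sc2, pathway)$pvalue)
  expect_equal(tsm_test(sc1, pathway, mode = "normal")$pvalue,
               tsm_test(sc2, pathway, mode = "normal")$pvalue)
  expect_equal(hypergeometric_test(sc1, pathway, top_n = 40)$pvalue,
               hypergeometric_test(sc2, pathway, top_n = 40)$pvalue)
  null <- artp_null(12, B = 200, source = "empirical_uniform", seed = 122)
  expect_equal(artp_test(sc1, pathway, null = null)$pvalue,
               artp_test(sc2, pathway, null = null)$pvalue)
  # GSEA's ES depends on -log p magnitudes. Power transforms p^c only rescale
  # the -log p weights, and the hit normalization N_R cancels the scale, so
  # the ES is unchanged; a non-power monotone transform changes it.
  expect_equal(gsea_es(sc1, pathway), gsea_es(sc2, pathway))
  sc3 <- gene_scores(data.frame(gene_id = sprintf("g%03d", 1:K),
                                pvalue = pnorm(qnorm(p) - 0.5)))
  expect_false(isTRUE(all.equal(gsea_es(sc1, pathway), gsea_es(sc3, pathway))))
  expect_equal(fisher_test(sc1, pathway)$pvalue, fisher_test(sc3, pathway)$pvalue)
})

test_that("permutation p-values are super-uniform under random pathways", {
  set.seed(123)
  K <- 600
  L <- 12
  sc <- make_scores(K, seed = 124)
  tnull <- tsm_null(L, R = 5000)
  anull <- artp_null(L, B = 300, source = "empirical_uniform")
  reps <- 2000
  pv <- matrix(NA_real_, reps, 3)
  for (r in seq_len(reps)) {
    idx <- sample.int(K, L)
    u_path <- sort(sc$u[idx])
    pv[r, 1] <- pathrank:::tsm_pvalue_empirical(tsm_statistic(u_path), tnull)
    pv[r, 2] <- pathrank:::artp_eval(cumsum(log(u_path)), anull)$pvalue
    pv[r, 3] <- pathrank:::fm_pvalue_asymptotic(u_path)
  }
  for (j in 1:2) {
    for (alpha in c(0.01, 0.05, 0.1)) {
      se <- sqrt(alpha * (1 - alpha) / reps)
      expect_lte(mean(pv[, j] <= alpha), alpha + 3 * se,
                 label = sprintf("column %d at alpha %.2f", j, alpha))
    }
  }
  # FM's chi-square reference is analytic and approximate on discrete ranks:
  # near-nominal (within Monte-Carlo error plus a small discretization term),
  # not exactly super-uniform
  expect_lt(abs(mean(pv[, 3] <= 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / reps) + 0.01)
})

test_that("power rises with the proportion of pathway genes with effects", {
  res <- lapply(c(0.4, 1.0), function(pi) {
    run_scenario(small_alt_scenario(K = 2000, pi = pi), methods = "fm",
                 n_reps = 100, seed = 125)
  })
  lo <- res[[1]]; hi <- res[[2]]
  se_diff <- sqrt(lo$se^2 + hi$se^2)
  expect_gte(hi$rate, lo$rate - 3 * se_diff)
  expect_gt(hi$rate, 0.5) # enrichment is detectable at all
})

test_that("power rises with pathway size at fixed effect count", {
  res <- lapply(c(20L, 100L), function(L) {
    run_scenario(small_alt_scenario(K = 2000, L = L, M = 200, pi = 0.4),
                 methods = "fm", n_reps = 100, seed = 126)
  })
  se_diff <- sqrt(res[[1]]$se^2 + res[[2]]$se^2)
  expect_gte(res[[2]]$rate, res[[1]]$rate - 3 * se_diff)
})
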