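test_that("MAF draws live on (0, 0.5) and are seed-reproducible", {
  m <- sample_maf(20000, seed = 81)
  expect_true(all(m > 0 & m < 0.5))
  expect_lt(abs(mean(m) - 0.25), 3 * sqrt(0.25^2 / 12 / 20000) * 2)
  expect_identical(m, sample_maf(20000, seed = 81))
})

test_that("genotype columns follow Hardy-Weinberg proportions", {
  N <- 10000
  G <- genotype_matrix(N, 3, maf = c(0.5, 0.2, 0.05), seed = 82)
  expect_true(all(G %in% 0:2))
  for (j in 1:3) {
    q <- c(0.5, 0.2, 0.05)[j]
    probs <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    freq <- tabulate(G[, j] + 1, 3) / N
    se <- sqrt(probs * (1 - probs) / N)
    expect_true(all(abs(freq - probs) < 3 * se + 1e-9),
                label = sprintf("HWE frequencies at q=%.2f", q))
    expect_lt(abs(mean(G[, j]) - 2 * q), 3 * sqrt(2 * q * (1 - q) / N))
  }
  expect_error(genotype_matrix(10, 2, c(0.6, 0.2)), "0, 0.5")
})

test_that("HWE goodness-of-fit rarely rejects across many columns", {
  set.seed(83)
  maf <- runif(1000, 0.05, 0.5)
  G <- genotype_matrix(500, 1000, maf)
  rej <- vapply(1:1000, function(j) {
    q <- maf[j]
    probs <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    obs <- tabulate(G[, j] + 1, 3)
    suppressWarnings(stats::chisq.test(obs, p = probs)$p.value) < 0.001
  }, logical(1))
  expect_lt(mean(rej), 0.01)
})

test_that("effect assignment respects the scenario bookkeeping", {
  scn <- small_alt_scenario(K = 500, L = 20, M = 50, pi = 0.4)
  eff <- assign_effects(scn, seed = 84)
  expect_equal(sum(eff$beta != 0), 50)
  expect_equal(sum(eff$beta[eff$pathway_idx] != 0), 8) # round(0.4 * 20)
  expect_equal(sum(eff$beta[-eff$pathway_idx] != 0), 42)

  all_in <- assign_effects(small_alt_scenario(K = 500, L = 20, M = 50, pi = 1),
                           seed = 85)
  expect_equal(sum(all_in$beta[all_in$pathway_idx] != 0), 20)

  nul <- assign_effects(small_null_scenario(K = 500), seed = 86)
  expect_equal(sum(nul$beta != 0), 50)
})

test_that("null scenarios pick pathway and effects independently", {
  scn <- small_null_scenario(K = 200, L = 20, M = 30)
  set.seed(87)
  overlap <- replicate(5000, {
    eff <- assign_effects(scn)
    sum(eff$beta[eff$pathway_idx] != 0)
  })
  expected <- 30 * 20 / 200 # per effect gene, P(in pathway) = L/K
  se <- sqrt(5000)^-1 * stats::sd(overlap)
  expect_lt(abs(mean(overlap) - expected), 3 * se)
})

test_that("phenotype is the additive genetic value plus optional noise", {
  G <- genotype_matrix(50, 5, rep(0.3, 5), seed = 88)
  beta <- c(0, 1, 0, 0, 0)
  expect_equal(phenotype(G, beta), G[, 2])
  set.seed(89)
  y0 <- phenotype(G, rep(0, 5), noise_sd = 1)
  expect_equal(length(y0), 50)
  expect_gt(stats::sd(y0), 0)
  # variance decomposition at large N
  N <- 10000
  maf <- c(0.1, 0.25, 0.4)
  G2 <- genotype_matrix(N, 3, maf, seed = 90)
  b <- c(0.5, -1, 2)
  y <- phenotype(G2, b, noise_sd = 1, seed = 91)
  expected_var <- sum(b^2 * 2 * maf * (1 - maf)) + 1
  expect_equal(stats::var(y), expected_var, tolerance = 0.1)
})

test_that("single-SNP regression p-values behave at the extremes", {
  set.seed(92)
  G <- genotype_matrix(100, 3, c(0.4, 0.3, 0.2))
  G[, 3] <- 0 # monomorphic
  y <- G[, 1] + rnorm(100, 0, 1e-8)
  p <- single_snp_pvalues(G, y)
  expect_lt(p[1], 1e-10)
  expect_equal(p[3], 1)
  expect_error(single_snp_pvalues(G, rep(1, 100)), "constant")
  expect_error(single_snp_pvalues(G[1:2, ], c(1, 2)), "3 individuals")
})

test_that("regression p-values are uniform under independence (KS check)", {
  set.seed(93)
  G <- genotype_matrix(100, 10000, runif(10000, 0.05, 0.5))
  y <- rnorm(100)
  p <- single_snp_pvalues(G, y)
  ks <- max(abs(sort(p) - seq_along(p) / length(p)))
  expect_lt(ks, 0.02)
})

test_that("simulated studies are deterministic given (scenario, seed)", {
  scn <- small_null_scenario(K = 300)
  a <- simulate_gwas(scn, seed = 94)
  b <- simulate_gwas(scn, seed = 94)
  expect_identical(a$pvalues, b$pvalues)
  expect_identical(a$pathway_idx, b$pathway_idx)
  expect_identical(a$beta, b$beta)
  sc <- sim_scores(a)
  expect_s3_class(sc, "pr_scores")
  expect_equal(sc$pvalue, a$pvalues)
})
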