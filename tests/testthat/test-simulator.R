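test_that("Hardy-Weinberg probabilities are correct and normalised", {
  expect_equal(hwe_probs(0.5), c(0.25, 0.5, 0.25))
  expect_equal(hwe_probs(0.2), c(0.64, 0.32, 0.04))
  for (maf in c(0.05, 0.17, 0.4, 0.5)) {
    expect_equal(sum(hwe_probs(maf)), 1)
  }
  expect_error(hwe_probs(0), "0, 0.5")
  expect_error(hwe_probs(0.7), "0, 0.5")
})

test_that("prevalence, heritability and marginals match brute force", {
  # constant table: prevalence = the constant, h2 = 0, flat marginals
  const <- two_locus_model(matrix(0.3, 3, 3), 0.2, 0.4)
  expect_equal(prevalence(const), 0.3)
  expect_equal(heritability(const), 0)
  expect_equal(marginal_penetrances(const)$locus1, rep(0.3, 3))

  # single-cell table at maf 0.5: K is that cell's genotype probability
  f <- matrix(0, 3, 3)
  f[2, 2] <- 1
  m1 <- two_locus_model(f, 0.5, 0.5)
  expect_equal(prevalence(m1), 0.5 * 0.5)

  # parity table with balanced genotype weights: K = 1/2, h2 = 1
  xor <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  mx <- two_locus_model(xor, 0.5, 0.5)
  expect_equal(prevalence(mx), 0.5)
  expect_equal(heritability(mx), 1)
  expect_equal(marginal_penetrances(mx)$locus1, rep(0.5, 3))
  expect_equal(marginal_penetrances(mx)$locus2, rep(0.5, 3))

  # random tables against direct 9-cell summation
  for (seed in 1:8) {
    f <- withr::with_seed(seed, matrix(runif(9), 3, 3))
    maf1 <- withr::with_seed(seed + 50, runif(1, 0.05, 0.5))
    maf2 <- withr::with_seed(seed + 60, runif(1, 0.05, 0.5))
    mod <- two_locus_model(f, maf1, maf2)
    p1 <- hwe_probs(maf1)
    p2 <- hwe_probs(maf2)
    K <- 0
    for (a in 1:3) for (b in 1:3) K <- K + p1[a] * p2[b] * f[a, b]
    expect_equal(prevalence(mod), K, tolerance = 1e-12)
    h2 <- 0
    for (a in 1:3) for (b in 1:3) h2 <- h2 + p1[a] * p2[b] * (f[a, b] - K)^2
    expect_equal(heritability(mod), h2 / (K * (1 - K)), tolerance = 1e-12)
    marg <- marginal_penetrances(mod)
    for (a in 1:3) expect_equal(marg$locus1[a], sum(p2 * f[a, ]), tolerance = 1e-12)
    for (b in 1:3) expect_equal(marg$locus2[b], sum(p1 * f[, b]), tolerance = 1e-12)
  }
})

test_that("constructed pure-epistasis models hit their targets", {
  for (case in list(c(0.01, 0.2), c(0.1, 0.4), c(0.4, 0.2))) {
    mod <- build_pure_epistasis_model(case[1], case[2], seed = 99)
    expect_lt(abs(heritability(mod) - case[1]), 1e-6)
    K <- prevalence(mod)
    marg <- marginal_penetrances(mod)
    expect_lt(max(abs(c(marg$locus1, marg$locus2) - K)), 1e-9)
  }
  # degenerate and infeasible targets
  expect_equal(heritability(build_pure_epistasis_model(0, 0.2, seed = 1)), 0)
  expect_error(build_pure_epistasis_model(1.01, 0.2, seed = 1), "\\[0, 1\\)")
  expect_error(
    build_pure_epistasis_model(0.999, 0.2, seed = 1, max_restarts = 50),
    "infeasible"
  )
})

test_that("sampling is reproducible with exact case-control counts", {
  mod <- build_pure_epistasis_model(0.1, 0.4, seed = 4)
  d1 <- simulate_epistasis(mod, n = 300, n_noise = 5, seed = 10)
  d2 <- simulate_epistasis(mod, n = 300, n_noise = 5, seed = 10)
  expect_identical(d1, d2)
  expect_equal(sum(phenotype(d1) == 1), 150)
  expect_equal(sum(phenotype(d1) == 0), 150)
  expect_equal(ncol(d1), 8) # 2 functional + 5 noise + class
  expect_equal(length(functional_snps(d1)), 2)

  d3 <- simulate_epistasis(mod, n_cases = 30, n_controls = 90, n_noise = 2,
    seed = 3)
  expect_equal(sum(phenotype(d3) == 1), 30)
  expect_equal(sum(phenotype(d3) == 0), 90)

  expect_error(
    simulate_epistasis(two_locus_model(matrix(0, 3, 3), 0.4), n = 10,
      seed = 1),
    "identically 0"
  )
})

test_that("functional genotypes follow the model's conditional law", {
  # constant penetrance: case genotypes are plain Hardy-Weinberg draws
  mod <- two_locus_model(matrix(0.3, 3, 3), 0.2, 0.2)
  d <- simulate_epistasis(mod, n = 1600, n_noise = 0, seed = 6)
  g <- genotype_matrix(d)[phenotype(d) == 1, functional_snps(d)[1]]
  obs <- tabulate(g + 1L, 3L)
  p <- chisq.test(obs, p = hwe_probs(0.2))$p.value
  expect_gt(p, 0.001)
})

test_that("noise SNP allele frequencies match their design value", {
  mod <- build_pure_epistasis_model(0.2, 0.4, seed = 8)
  d <- simulate_epistasis(mod, n = 1600, n_noise = 18, noise_maf = 0.3,
    seed = 12)
  noise_cols <- setdiff(seq_len(20), functional_snps(d))
  g <- genotype_matrix(d)
  se <- sqrt(0.3 * 0.7 / (2 * 1600))
  for (j in noise_cols) {
    maf_hat <- mean(g[, j]) / 2
    expect_lt(abs(maf_hat - 0.3), 4 * se)
  }
})

test_that("pure epistasis hides single-SNP effects but not the pair", {
  mod <- build_pure_epistasis_model(0.4, 0.4, seed = 14)
  d <- simulate_epistasis(mod, n = 1600, n_noise = 0, seed = 15)
  g <- genotype_matrix(d)
  ph <- phenotype(d)
  fx <- functional_snps(d)
  # marginal single-SNP association is null by design
  for (j in fx) {
    p <- chisq.test(table(g[, j], ph))$p.value
    expect_gt(p, 1e-4)
  }
  # the joint 9-cell test is overwhelmingly powered at h2 = 0.4
  joint <- interaction(g[, fx[1]], g[, fx[2]])
  expect_lt(chisq.test(table(joint, ph))$p.value, 1e-10)
})

test_that("the simulation grid covers the heritability-by-MAF design", {
  grid <- velez_grid(1, seed = 20)
  expect_equal(nrow(grid), 14)
  expect_equal(sort(unique(grid$h2)),
    c(0.01, 0.025, 0.05, 0.10, 0.20, 0.30, 0.40))
  expect_equal(sort(unique(grid$maf)), c(0.2, 0.4))
  grid2 <- velez_grid(1, seed = 20)
  expect_identical(
    purrr::map(grid$model, "penetrance"),
    purrr::map(grid2$model, "penetrance")
  )
  for (i in seq_len(nrow(grid))) {
    expect_lt(abs(heritability(grid$model[[i]]) - grid$h2[i]), 1e-6)
  }
})
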