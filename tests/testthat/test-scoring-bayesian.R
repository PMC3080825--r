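test_that("hyperparameter tables follow the K2 and BDeu conventions", {
  expect_equal(k2_hyper(2, 3), matrix(1, 2, 3))
  expect_equal(k2_hyper(1, 1), matrix(1, 1, 1))
  expect_equal(bdeu_hyper(6, 2, 3), matrix(1, 2, 3)) # alpha = r*q coincidence
  expect_equal(bdeu_hyper(15, 2, 9), matrix(15 / 18, 2, 9))
  for (alpha in c(0.5, 1, 15, 162)) {
    expect_equal(sum(bdeu_hyper(alpha, 2, 9)), alpha) # equivalent sample size
  }
  expect_error(bdeu_hyper(0, 2, 3), "positive")
  expect_error(bdeu_hyper(-3, 2, 3), "positive")
})

test_that("the family marginal equals the prequential predictive product", {
  # closed case: binary child, no parents, one case + one control
  d <- tibble::tibble(S1 = c(0L, 1L), Class = c(1L, 0L))
  fc <- family_counts(d)
  expect_equal(log_family_marginal(fc, k2_hyper(2, 1)), log(1 / 6))

  # empty data scores log(1) = 0
  fc0 <- list(r = 2L, q = 3L, s = matrix(0L, 2, 3))
  expect_equal(log_family_marginal(fc0, k2_hyper(2, 3)), 0)

  # random small datasets, random hyperparameters, several data orderings
  for (seed in 1:20) {
    d <- rand_geno(m = withr::with_seed(seed, sample(1:6, 1)), n = 1, seed)
    fc <- family_counts(d, 1)
    a <- withr::with_seed(seed + 100, matrix(runif(6, 0.2, 3), 2, 3))
    val <- log_family_marginal(fc, a)
    state <- genotype_matrix(d)[, 1] + 1L
    for (r in 1:3) {
      ord <- withr::with_seed(seed * 10 + r, sample(nrow(d)))
      oracle <- prequential_log_marginal(phenotype(d)[ord], state[ord], a)
      expect_equal(val, oracle, tolerance = 1e-10)
    }
  }
})

test_that("nonpositive hyperparameters are rejected", {
  fc <- family_counts(rand_geno(5, 1, 1), 1)
  expect_error(log_family_marginal(fc, matrix(0, 2, 3)), "positive")
})

test_that("bayesian DDAG scores reduce to the disease family", {
  d <- tibble::tibble(S1 = c(0L, 1L), Class = c(1L, 0L))
  expect_equal(score_bayesian(d, integer(), "k2")$score, log(1 / 6))
  # k = 0: BDeu with alpha = 2 has unit hyperparameters, same as K2
  d2 <- rand_geno(12, 2, seed = 5)
  expect_equal(
    score_bayesian(d2, integer(), "bdeu", alpha = 2)$score,
    score_bayesian(d2, integer(), "k2")$score
  )
})

test_that("marginal likelihoods sum to one over the space of datasets", {
  # one ternary SNP root family + binary disease with the SNP as parent;
  # score with parent roots included is the log joint marginal of the data,
  # so exp(score) must sum to 1 over all 6^m datasets.
  for (m in 1:2) {
    cells <- all_small_datasets(m)
    for (crit in list(c("k2", NA), c("bdeu", 15))) {
      tot <- 0
      for (i in seq_len(nrow(cells))) {
        snp <- as.integer((cells[i, ] - 1) %% 3)
        dis <- as.integer((cells[i, ] - 1) %/% 3)
        d <- tibble::tibble(S1 = snp, Class = dis)
        sc <- score_bayesian(d, 1, crit[1],
          alpha = suppressWarnings(as.numeric(crit[2])),
          include_parent_roots = TRUE
        )$score
        tot <- tot + exp(sc)
      }
      expect_equal(tot, 1, tolerance = 1e-9)
    }
  }
})

test_that("BDeu, but not K2, is invariant under 2-node edge reversal", {
  d <- rand_geno(15, 1, seed = 8)
  x <- genotype_matrix(d)[, 1]
  ph <- phenotype(d)
  for (alpha in c(1, 6, 15)) {
    fwd <- two_node_score(x, ph, "snp_to_disease", "bdeu", alpha)
    rev <- two_node_score(x, ph, "disease_to_snp", "bdeu", alpha)
    expect_equal(fwd, rev, tolerance = 1e-10)
    # the package's BDeu score (with roots) equals both orientations
    pkg <- score_bayesian(d, 1, "bdeu", alpha, include_parent_roots = TRUE)$score
    expect_equal(pkg, fwd, tolerance = 1e-10)
  }
  # constructed dataset where K2 differs across orientations
  dk <- tibble::tibble(S1 = c(0L, 1L, 2L, 2L), Class = c(0L, 1L, 1L, 1L))
  k2_fwd <- two_node_score(genotype_matrix(dk)[, 1], phenotype(dk),
    "snp_to_disease", "k2")
  k2_rev <- two_node_score(genotype_matrix(dk)[, 1], phenotype(dk),
    "disease_to_snp", "k2")
  expect_gt(abs(k2_fwd - k2_rev), 1e-6)
})

test_that("scores are invariant to row order and column relabeling", {
  d <- rand_geno(40, 5, seed = 13)
  perm <- withr::with_seed(2, sample(nrow(d)))
  for (crit in c("k2", "bdeu:alpha=15", "mdl-epi-v2", "mml-v1")) {
    expect_equal(
      score_ddag(d[perm, ], c(2, 4), crit)$score,
      score_ddag(d, c(2, 4), crit)$score
    )
  }
  # relabel columns: move SNP 2 and 4 to positions 1 and 2
  d2 <- d[c("S2", "S4", "S1", "S3", "S5", "Class")]
  expect_equal(
    score_ddag(d2, c(1, 2), "bdeu:alpha=15")$score,
    score_ddag(d, c(2, 4), "bdeu:alpha=15")$score
  )
})

test_that("criterion ids parse to the right scheme and orientation", {
  cr <- parse_criterion("bdeu:alpha=15")
  expect_equal(cr$alpha, 15)
  expect_equal(cr$orientation, "higher")
  expect_equal(parse_criterion("mdl-epi-v2")$variant, "epi")
  expect_equal(parse_criterion("mdl-none")$orientation, "lower")
  expect_equal(parse_criterion("mml-v2")$version, "v2")
  expect_error(parse_criterion("bdeu:alpha=-3"), "invalid")
  expect_error(parse_criterion("mdl-bogus-v1"), "unknown")
  expect_true(all(c("k2", "mdl-none", "mml-v1") %in% list_criteria()))
})
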