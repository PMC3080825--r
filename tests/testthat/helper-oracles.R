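# Independent oracles used across the test suite.  These deliberately avoid
# the package's own code paths (no lgamma identities, no shared helpers):
# scores are checked against sequential predictive products and brute-force
# tallies.

# Prequential oracle for the Dirichlet-multinomial family marginal: the log
# of the product of sequential predictive probabilities
#   P(x_t = k | history) = (a[k, j_t] + n_seen[k, j_t]) / (A_j + N_j)
# over the data items in the given order.
prequential_log_marginal <- function(child, parent_state, a) {
  stopifnot(length(child) == length(parent_state))
  seen <- matrix(0, nrow = nrow(a), ncol = ncol(a))
  lp <- 0
  for (t in seq_along(child)) {
    k <- child[t] + 1L
    j <- parent_state[t]
    lp <- lp + log((a[k, j] + seen[k, j]) / (sum(a[, j]) + sum(seen[, j])))
    seen[k, j] <- seen[k, j] + 1
  }
  lp
}

# Generic scorer for a saturated 2-node network over one ternary SNP x and
# the binary disease d, built from the prequential oracle only.  direction
# "snp_to_disease" scores S -> D (root family S, child family D | S);
# "disease_to_snp" scores D -> S.
two_node_score <- function(x, d, direction, scheme = "bdeu", alpha = NULL) {
  hyper <- function(r, q) {
    if (scheme == "k2") matrix(1, r, q) else matrix(alpha / (r * q), r, q)
  }
  if (direction == "snp_to_disease") {
    prequential_log_marginal(x, rep(1L, length(x)), hyper(3, 1)) +
      prequential_log_marginal(d, x + 1L, hyper(2, 3))
  } else {
    prequential_log_marginal(d, rep(1L, length(d)), hyper(2, 1)) +
      prequential_log_marginal(x, d + 1L, hyper(3, 2))
  }
}

# Brute-force family counts by explicit row-by-row tallying.
brute_family_counts <- function(data, parents) {
  g <- as.matrix(data[-ncol(data)])
  ph <- data[[ncol(data)]]
  parents <- sort(parents)
  k <- length(parents)
  q <- 3^k
  s <- matrix(0L, nrow = 2, ncol = q)
  for (i in seq_len(nrow(g))) {
    j <- 1L
    for (p in parents) j <- j + g[i, p] * 3^(k - match(p, parents))
    s[ph[i] + 1L, j] <- s[ph[i] + 1L, j] + 1L
  }
  s
}

# Seeded random genotype tibble with m rows and n SNPs.
rand_geno <- function(m, n, seed = 1) {
  withr::with_seed(seed, {
    d <- as.data.frame(matrix(sample(0:2, m * n, replace = TRUE), m, n))
    names(d) <- paste0("S", seq_len(n))
    d$Class <- sample(0:1, m, replace = TRUE)
    tibble::as_tibble(lapply(d, as.integer))
  })
}

# Genotype data where the class is a deterministic parity function of the
# first two SNPs (plus uniform noise SNPs): the classic noise-free
# two-locus signal.
xor_geno <- function(m, n_noise = 3, seed = 1) {
  withr::with_seed(seed, {
    g1 <- sample(0:2, m, replace = TRUE)
    g2 <- sample(0:2, m, replace = TRUE)
    d <- data.frame(S1 = g1, S2 = g2)
    for (j in seq_len(n_noise)) {
      d[[paste0("N", j)]] <- sample(0:2, m, replace = TRUE)
    }
    d$Class <- (g1 + g2) %% 2L
    tibble::as_tibble(lapply(d, as.integer))
  })
}

# All datasets of m items over the joint space (SNP in 0:2) x (disease in
# 0:1), as a (6^m) x m matrix of cell indices 1..6; cell c encodes
# snp = (c - 1) %% 3, disease = (c - 1) %/% 3.
all_small_datasets <- function(m) {
  as.matrix(expand.grid(replicate(m, 1:6, simplify = FALSE)))
}
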