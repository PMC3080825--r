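#' Two-locus penetrance models
#'
#' A two-locus model is a 3 x 3 penetrance table `f[a, b] = P(disease |
#' genotype a at locus 1, genotype b at locus 2)` together with the two
#' minor allele frequencies.  Genotypes follow Hardy-Weinberg proportions at
#' each locus and the loci are unlinked.
#'
#' @param penetrance A 3 x 3 numeric matrix with entries in \[0, 1\]; rows =
#'   locus-1 genotypes 0/1/2, columns = locus-2 genotypes.
#' @param maf1,maf2 Minor allele frequencies in (0, 0.5\].
#' @return An object of class `two_locus_model`.
#' @examples
#' xor <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
#' mod <- two_locus_model(xor, 0.5, 0.5)
#' prevalence(mod)    # 0.5
#' heritability(mod)  # 1
#' @export
two_locus_model <- function(penetrance, maf1, maf2 = maf1) {
  penetrance <- as.matrix(penetrance)
  if (!all(dim(penetrance) == c(3L, 3L))) {
    abort("'penetrance' must be a 3 x 3 matrix")
  }
  if (anyNA(penetrance) || any(penetrance < 0) || any(penetrance > 1)) {
    abort("penetrances must lie in [0, 1]")
  }
  for (maf in c(maf1, maf2)) {
    if (!is.numeric(maf) || maf <= 0 || maf > 0.5) {
      abort("minor allele frequencies must lie in (0, 0.5]")
    }
  }
  dimnames(penetrance) <- list(locus1 = 0:2, locus2 = 0:2)
  structure(list(penetrance = penetrance, maf1 = maf1, maf2 = maf2),
    class = "two_locus_model")
}

#' @export
print.two_locus_model <- function(x, ...) {
  cat(sprintf(
    "<two_locus_model> maf1 = %.3g, maf2 = %.3g, K = %.4g, h2 = %.4g\n",
    x$maf1, x$maf2, prevalence(x), heritability(x)
  ))
  print(round(x$penetrance, 4))
  invisible(x)
}

#' Hardy-Weinberg genotype probabilities
#'
#' @param maf Minor allele frequency in (0, 0.5\].
#' @return `c((1-q)^2, 2q(1-q), q^2)` for `q = maf`; sums to 1.
#' @examples
#' hwe_probs(0.2) # 0.64 0.32 0.04
#' @export
hwe_probs <- function(maf) {
  if (!is.numeric(maf) || length(maf) != 1L || is.na(maf) || maf <= 0 ||
      maf > 0.5) {
    abort("'maf' must be a single number in (0, 0.5]")
  }
  q <- maf
  c((1 - q)^2, 2 * q * (1 - q), q^2)
}

#' Population summaries of a two-locus model
#'
#' `prevalence()` is the population disease probability
#' `K = sum_ab p_a p_b f[a, b]`.  `heritability()` is the broad-sense
#' heritability of the dichotomous trait,
#' `h2 = sum_ab p_a p_b (f[a, b] - K)^2 / (K (1 - K))`: the genotype-level
#' variance in penetrance as a fraction of total phenotypic variance.
#' `marginal_penetrances()` gives the single-locus penetrance triples
#' `P(disease | genotype at one locus)`; a model is *purely epistatic* when
#' both triples are constant (no marginal single-SNP effect).
#'
#' @param model A [two_locus_model()].
#' @return `prevalence()` and `heritability()` return a single number;
#'   `marginal_penetrances()` a list with numeric triples `locus1`,
#'   `locus2`.
#' @export
prevalence <- function(model) {
  w <- outer(hwe_probs(model$maf1), hwe_probs(model$maf2))
  sum(w * model$penetrance)
}

#' @rdname prevalence
#' @export
heritability <- function(model) {
  K <- prevalence(model)
  if (K <= 0 || K >= 1) {
    abort("heritability is undefined when prevalence is 0 or 1")
  }
  w <- outer(hwe_probs(model$maf1), hwe_probs(model$maf2))
  sum(w * (model$penetrance - K)^2) / (K * (1 - K))
}

#' @rdname prevalence
#' @export
marginal_penetrances <- function(model) {
  p1 <- hwe_probs(model$maf1)
  p2 <- hwe_probs(model$maf2)
  list(
    locus1 = as.vector(model$penetrance %*% p2),
    locus2 = as.vector(p1 %*% model$penetrance)
  )
}

# Exact projector onto {e : weighted row means and column means all zero},
# built once per (p1, p2) from the SVD null space of the 6 linear
# constraints.
zero_marginal_projector <- function(p1, p2) {
  A <- matrix(0, 6, 9) # cell (a, b) at column a + 3 (b - 1)
  for (a in 1:3) for (b in 1:3) {
    A[a, a + 3 * (b - 1)] <- p2[b]
    A[3 + b, a + 3 * (b - 1)] <- p1[a]
  }
  sv <- svd(A)
  keep <- sv$d > 1e-12 * sv$d[1]
  V <- sv$v[, keep, drop = FALSE]
  diag(9) - V %*% t(V)
}

#' Construct a pure-epistasis penetrance table
#'
#' Builds a random two-locus model with *exactly zero* marginal single-locus
#' effects and broad-sense heritability equal to `h2_target` (to 1e-6).
#' Construction: a seeded random table is projected onto the
#' zero-marginal-effect constraint set (6 linear constraints on the 9
#' cells), the deviation from the baseline prevalence is rescaled to hit the
#' target heritability, and candidate prevalences are scanned until the
#' rescaled table stays inside \[0, 1\].  Deterministic given `seed`.
#'
#' @param h2_target Target broad-sense heritability in \[0, 1).
#' @param maf Minor allele frequency used for both loci.
#' @param seed Integer seed; the global RNG state is left untouched.
#' @param max_restarts Random restarts before declaring the target
#'   infeasible.
#' @return A [two_locus_model()] whose heritability matches `h2_target`
#'   within 1e-6 and whose marginal penetrance deviation is below 1e-9.
#' @examples
#' mod <- build_pure_epistasis_model(0.1, 0.2, seed = 7)
#' heritability(mod)
#' marginal_penetrances(mod)
#' @export
build_pure_epistasis_model <- function(h2_target, maf, seed,
                                       max_restarts = 2000) {
  if (!is.numeric(h2_target) || h2_target < 0 || h2_target >= 1) {
    abort("'h2_target' must lie in [0, 1)")
  }
  p1 <- hwe_probs(maf)
  if (h2_target == 0) {
    return(two_locus_model(matrix(0.5, 3, 3), maf, maf))
  }
  P <- zero_marginal_projector(p1, p1)
  W <- outer(p1, p1)
  best_h2 <- 0
  res <- withr::with_seed(seed, {
    found <- NULL
    for (i in seq_len(max_restarts)) {
      e <- matrix(P %*% runif(9, -1, 1), 3, 3)
      Ve <- sum(W * e^2)
      if (Ve < 1e-12) next
      lo <- min(e)
      hi <- max(e)
      for (K0 in sample(seq(0.05, 0.95, by = 0.05))) {
        cneed <- sqrt(h2_target * K0 * (1 - K0) / Ve)
        # largest rescaling keeping K0 + c e inside [0, 1]
        cmax <- min(if (lo < 0) -K0 / lo else Inf,
                    if (hi > 0) (1 - K0) / hi else Inf)
        best_h2 <- max(best_h2, cmax^2 * Ve / (K0 * (1 - K0)))
        if (cneed <= cmax) {
          found <- pmin(pmax(K0 + cneed * e, 0), 1)
          break
        }
      }
      if (!is.null(found)) break
    }
    found
  })
  if (is.null(res)) {
    abort(sprintf(
      "pure-epistasis target h2 = %g infeasible at maf = %g (attained at most %.4g)",
      h2_target, maf, best_h2
    ))
  }
  model <- two_locus_model(res, maf, maf)
  stopifnot(abs(heritability(model) - h2_target) < 1e-6)
  model
}

#' Simulate a case-control genotype data set
#'
#' Retrospective (case-control) sampling from a two-locus model: the
#' functional genotype pair of each case is drawn from
#' `P(a, b | case) = p_a p_b f[a, b] / K` and of each control from
#' `P(a, b | control) = p_a p_b (1 - f[a, b]) / (1 - K)` (exact conditional
#' distributions, no rejection).  Noise SNPs are drawn independently from
#' Hardy-Weinberg proportions regardless of status.  The two functional
#' SNPs are placed at seed-randomised column positions, recorded in
#' `attr(, "functional")`; rows are shuffled.  Case and control counts are
#' exact by construction.
#'
#' @param model A [two_locus_model()].
#' @param n Total sample size (split 1:1 unless `n_cases`/`n_controls` are
#'   given).
#' @param n_noise Number of unlinked noise SNPs (default 18, for the classic
#'   20-SNP panel).
#' @param noise_maf Minor allele frequency of the noise SNPs; defaults to
#'   the functional-locus MAF.  May be a vector of length `n_noise`.
#' @param seed Integer seed; fully reproducible, global RNG untouched.
#' @param n_cases,n_controls Optional explicit counts (override `n`).
#' @return A genotype tibble (SNP columns `S1..S<n>`, class column `Class`)
#'   with attributes `functional` (functional SNP column positions),
#'   `model`, and `seed`.
#' @examples
#' mod <- build_pure_epistasis_model(0.4, 0.4, seed = 1)
#' d <- simulate_epistasis(mod, n = 200, seed = 9)
#' functional_snps(d)
#' @export
simulate_epistasis <- function(model, n = NULL, n_noise = 18,
                               noise_maf = NULL, seed,
                               n_cases = NULL, n_controls = NULL) {
  stopifnot(inherits(model, "two_locus_model"))
  if (is.null(n_cases)) {
    if (is.null(n)) abort("give either 'n' or 'n_cases'/'n_controls'")
    if (n %% 2L != 0L) abort("'n' must be even for a 1:1 case-control split")
    n_cases <- n %/% 2L
  }
  if (is.null(n_controls)) n_controls <- n_cases
  m <- n_cases + n_controls
  f <- model$penetrance
  w <- outer(hwe_probs(model$maf1), hwe_probs(model$maf2))
  p_case <- as.vector(w * f)
  p_ctrl <- as.vector(w * (1 - f))
  if (n_cases > 0 && sum(p_case) <= 0) {
    abort("cannot sample cases: penetrance is identically 0")
  }
  if (n_controls > 0 && sum(p_ctrl) <= 0) {
    abort("cannot sample controls: penetrance is identically 1")
  }
  if (is.null(noise_maf)) noise_maf <- model$maf1
  noise_maf <- rep_len(noise_maf, n_noise)
  n_snps <- 2L + n_noise

  dat <- withr::with_seed(seed, {
    cells <- c(
      sample.int(9L, n_cases, replace = TRUE, prob = p_case),
      sample.int(9L, n_controls, replace = TRUE, prob = p_ctrl)
    )
    g1 <- (cells - 1L) %% 3L        # locus 1 genotype (rows of f)
    g2 <- (cells - 1L) %/% 3L       # locus 2 genotype
    g <- matrix(0L, nrow = m, ncol = n_snps)
    pos <- sort(sample.int(n_snps, 2L))
    g[, pos[1]] <- g1
    g[, pos[2]] <- g2
    for (j in seq_len(n_noise)) {
      col <- setdiff(seq_len(n_snps), pos)[j]
      g[, col] <- sample(0:2, m, replace = TRUE, prob = hwe_probs(noise_maf[j]))
    }
    ph <- c(rep(1L, n_cases), rep(0L, n_controls))
    ord <- sample.int(m)
    list(g = g[ord, , drop = FALSE], ph = ph[ord], pos = pos)
  })

  out <- as_tibble(as.data.frame(dat$g))
  names(out) <- paste0("S", seq_len(n_snps))
  out$Class <- dat$ph
  attr(out, "functional") <- dat$pos
  attr(out, "model") <- model
  attr(out, "seed") <- seed
  out
}

#' @rdname simulate_epistasis
#' @param data A simulated genotype tibble.
#' @export
functional_snps <- function(data) {
  attr(data, "functional")
}

#' The heritability-by-MAF simulation grid
#'
#' Reproduces the design of the classic pure-epistasis benchmark: models
#' distributed uniformly over seven broad-sense heritabilities (0.01, 0.025,
#' 0.05, 0.10, 0.20, 0.30, 0.40) crossed with two minor allele frequencies
#' (0.2, 0.4).  With `models_per_cell = 5` this yields the familiar 70
#' models.  The exact penetrance tables of the original benchmark are not
#' redistributed with it; each grid cell here is filled with freshly
#' constructed pure-epistasis tables matching the cell's design parameters.
#'
#' @param models_per_cell Models per (heritability, MAF) cell.
#' @param seed Integer seed; per-model seeds are derived from it.
#' @return A tibble with columns `h2`, `maf`, `rep`, `model` (list column of
#'   [two_locus_model()] objects).
#' @examples
#' g <- velez_grid(1, seed = 3)
#' nrow(g) # 14
#' @export
velez_grid <- function(models_per_cell = 5, seed = 1) {
  stopifnot(models_per_cell >= 1)
  design <- tidyr::expand_grid(
    h2 = c(0.01, 0.025, 0.05, 0.10, 0.20, 0.30, 0.40),
    maf = c(0.2, 0.4),
    rep = seq_len(models_per_cell)
  )
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L,
    nrow(design)))
  design$model <- purrr::pmap(
    list(design$h2, design$maf, seeds),
    function(h2, maf, s) build_pure_epistasis_model(h2, maf, seed = s)
  )
  design
}

#' @rdname simulate_epistasis
#' @inheritParams velez_grid
#' @export
simulation_design <- function(model, n, n_noise = 18, noise_maf = NULL,
                              seed = 1) {
  tibble(
    model = if (inherits(model, "two_locus_model")) list(model) else model,
    n = n, n_noise = n_noise,
    noise_maf = noise_maf %||% NA_real_,
    seed = seed
  )
}
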