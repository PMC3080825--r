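#' Dirichlet hyperparameter tables
#'
#' One table of pseudo-counts `a_jk` for a single node family with `r` child
#' states and `q` joint parent states.  `k2_hyper()` sets every entry to 1
#' (prior ignorance per parameter).  `bdeu_hyper()` spreads a prior
#' equivalent sample size `alpha` uniformly, `a_jk = alpha / (r q)`, so the
#' table always sums to `alpha`; this is the choice that makes Markov
#' equivalent structures score identically.
#'
#' @param r Number of child states.
#' @param q Number of joint parent states.
#' @param alpha Prior equivalent sample size (> 0).
#' @return An `r` x `q` numeric matrix of strictly positive pseudo-counts.
#' @examples
#' k2_hyper(2, 3)
#' sum(bdeu_hyper(15, 2, 9)) # == 15
#' @export
k2_hyper <- function(r, q) {
  stopifnot(r >= 1, q >= 1)
  matrix(1, nrow = r, ncol = q)
}

#' @rdname k2_hyper
#' @export
bdeu_hyper <- function(alpha, r, q) {
  stopifnot(r >= 1, q >= 1)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    abort("'alpha' must be a single positive number")
  }
  matrix(alpha / (r * q), nrow = r, ncol = q)
}

#' Log marginal likelihood of one node family
#'
#' The Dirichlet-multinomial marginal likelihood of the data restricted to
#' one family (a child node and its parents), in natural log space:
#'
#' \deqn{\sum_j \left[\log\Gamma(a_{j\cdot}) - \log\Gamma(a_{j\cdot} + s_{j\cdot})
#'   + \sum_k \{\log\Gamma(a_{jk} + s_{jk}) - \log\Gamma(a_{jk})\}\right]}
#'
#' where \eqn{s_{jk}} counts child state k with joint parent state j and
#' \eqn{a_{jk}} is the Dirichlet pseudo-count.  Equivalently it is the log of
#' the product of sequential predictive probabilities of the data items in
#' any order (the prequential view), which the test suite exploits as an
#' independent oracle.
#'
#' @param counts A [family_counts()] object (or any list with an `r` x `q`
#'   count matrix `s`).
#' @param hyper An `r` x `q` matrix of positive Dirichlet pseudo-counts.
#' @return The log marginal likelihood (a single finite number; 0 when the
#'   family holds no data).
#' @examples
#' d <- tibble::tibble(S1 = c(0L, 1L), Class = c(1L, 0L))
#' fc <- family_counts(d)            # parentless disease family
#' log_family_marginal(fc, k2_hyper(2, 1)) # log(1/6)
#' @export
log_family_marginal <- function(counts, hyper) {
  s <- counts$s
  if (!is.matrix(hyper) || !all(dim(hyper) == dim(s))) {
    abort("'hyper' must be a matrix with the same r x q shape as the counts")
  }
  if (any(hyper <= 0) || anyNA(hyper)) {
    abort("Dirichlet hyperparameters must be strictly positive")
  }
  aj <- colSums(hyper)
  sj <- colSums(s)
  sum(lgamma(aj) - lgamma(aj + sj)) + sum(lgamma(hyper + s) - lgamma(hyper))
}

#' Data-encoding length of one family, in bits
#'
#' The second term of an MDL score: the number of bits needed to encode the
#' child values given the parent values when probabilities are estimated
#' from the data itself,
#' \eqn{-\sum_{j}\sum_k s_{jk} \log_2(s_{jk}/s_{j\cdot})}
#' with \eqn{0 \log 0 = 0}.  Equals m times the empirical conditional entropy
#' of the child given its parents; zero iff the child is a deterministic
#' function of the parents on the observed rows.  Parent states with no data
#' contribute nothing.
#'
#' @param counts A [family_counts()] object.
#' @return Encoding length in bits (nonnegative).
#' @export
encoding_length_bits <- function(counts) {
  s <- counts$s
  sj <- colSums(s)
  sum(xlog2x(sj)) - sum(xlog2x(s))
}

xlog2x <- function(x) {
  out <- x * 0
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos])
  out
}

#' Structure (DAG) penalty of a DDAG, in bits
#'
#' Parameter counts are d = 3^k free parameters for the binary disease node
#' with k ternary parents (one per joint parent state) and d = 2 for each
#' parent SNP (three states, two free parameters).  Variants:
#'
#' * `suzuki`: (d/2) log2(m) bits per node.
#' * `aic`: d bits per node (sample-size independent).
#' * `epi`: the epistasis-tailored penalty.  The expected number of data
#'   items per joint parent state is m/3^k, so each disease parameter is
#'   stored to precision m/3^k: disease term (3^k/2) log2(m/3^k).  Each
#'   parent SNP contributes 2 * (1/2) log2(m) = log2(m) bits.
#' * `none`: 0.
#'
#' Version `"v1"` counts only the disease node (SNP-node penalties are
#' constant across models when every SNP stays in the model and so are
#' dropped); `"v2"` adds the k parent-SNP terms.
#'
#' @param k Number of parent SNPs (>= 0).
#' @param m Number of data items (>= 1).
#' @param variant `"suzuki"`, `"aic"`, `"epi"` or `"none"`.
#' @param version `"v1"` or `"v2"`.
#' @return Penalty in bits.  For the `epi` variant with m < 3^k the disease
#'   term is negative; a warning is issued and the value returned as-is.
#' @examples
#' dag_penalty_bits(1, 8, "suzuki", "v2")  # 7.5
#' dag_penalty_bits(1, 9, "epi", "v2")     # (3/2) log2(3) + log2(9)
#' @export
dag_penalty_bits <- function(k, m, variant = c("suzuki", "aic", "epi", "none"),
                             version = c("v1", "v2")) {
  variant <- match.arg(variant)
  version <- match.arg(version)
  stopifnot(k >= 0, m >= 1)
  d_disease <- 3^k
  if (variant == "none") {
    return(0)
  }
  if (variant == "aic") {
    pen <- d_disease
    if (version == "v2") pen <- pen + 2 * k
    return(pen)
  }
  if (variant == "suzuki") {
    pen <- d_disease / 2 * log2(m)
    if (version == "v2") pen <- pen + k * log2(m) # k SNPs, (2/2) log2 m each
    return(pen)
  }
  # epi
  if (m < d_disease) {
    warn(sprintf(
      "epi penalty with m = %d < 3^k = %d: disease term is negative", m,
      d_disease
    ))
  }
  pen <- d_disease / 2 * log2(m / d_disease)
  if (version == "v2") pen <- pen + k * log2(m)
  pen
}

#' Score a DDAG model
#'
#' Computes one scoring criterion for the DDAG in which `parents` are the
#' parents of the disease node.
#'
#' All criteria are computed under the full-domain convention: every SNP in
#' the panel is part of the network, SNP nodes never have parents in a DDAG,
#' and so every SNP-node *data* term (root-family marginal likelihood,
#' marginal encoding length) is an additive constant identical across
#' models.  Those constants are omitted, which is what makes scores of
#' models with different parent-set sizes comparable.  The version-1 /
#' version-2 distinction for MDL and MML therefore lives entirely in the
#' structure penalty (see [dag_penalty_bits()]).
#'
#' `score_bayesian()` returns the log Dirichlet-multinomial marginal of the
#' disease family (r = 2, q = 3^k), in natural logs.  Orientation: higher
#' is better.  With `include_parent_roots = TRUE` the parent SNPs'
#' root-family marginals (r = 3, q = 1) are added, giving the joint
#' marginal likelihood of the model's own variables; this is the quantity
#' for which BDeu satisfies likelihood equivalence across Markov-equivalent
#' orientations, and it is what the normalization identity (marginal
#' likelihoods summing to one over data space) holds for.  It is not used
#' in model search because the root terms grow with m for every added
#' parent, which would swamp the disease-family comparison.
#'
#' `score_mdl()` returns the DAG penalty plus the disease-family encoding
#' length, in bits.  Orientation: lower is better.
#'
#' `score_mml()` returns the K2 score converted to log2 space minus the
#' Suzuki-style parameter penalty sum(d_i/2) log2(m) over the nodes of the
#' model (v1: disease node only; v2: disease plus parent SNPs).  Orientation:
#' higher is better.
#'
#' `score_ddag()` dispatches on a criterion id string (see
#' [parse_criterion()]).
#'
#' @param data A genotype tibble.
#' @param parents Parent SNPs (positions or names), possibly empty.
#' @param scheme `"k2"` or `"bdeu"`.
#' @param alpha BDeu prior equivalent sample size (required when
#'   `scheme = "bdeu"`).
#' @param variant,version See [dag_penalty_bits()].
#' @param criterion A criterion id string such as `"bdeu:alpha=15"`.
#' @return A one-row tibble with columns `criterion`, `parent_set` (comma
#'   separated SNP names), `k`, `score` and `orientation`.
#' @examples
#' d <- tibble::tibble(S1 = c(0L, 1L, 2L, 0L), S2 = c(1L, 1L, 0L, 2L),
#'                     Class = c(0L, 1L, 1L, 0L))
#' score_ddag(d, "S1", "bdeu:alpha=15")
#' score_mdl(d, c("S1", "S2"), variant = "suzuki", version = "v2")
#' @export
score_ddag <- function(data, parents, criterion) {
  crit <- parse_criterion(criterion)
  switch(crit$type,
    bayesian = score_bayesian(data, parents, crit$scheme, crit$alpha),
    mdl = score_mdl(data, parents, crit$variant, crit$version,
      .id = crit$id),
    mml = score_mml(data, parents, crit$version)
  )
}

#' @rdname score_ddag
#' @param include_parent_roots Also add the parent SNPs' root-family
#'   marginals (see Details).  Default `FALSE`.
#' @export
score_bayesian <- function(data, parents, scheme = c("k2", "bdeu"),
                           alpha = NULL, include_parent_roots = FALSE) {
  scheme <- match.arg(scheme)
  validate_genotypes(data)
  p <- resolve_parents(data, parents)
  fc <- family_counts(data, p)
  if (scheme == "bdeu") {
    if (is.null(alpha)) abort("BDeu needs a prior equivalent sample size 'alpha'")
    hyper_d <- bdeu_hyper(alpha, fc$r, fc$q)
  } else {
    hyper_d <- k2_hyper(fc$r, fc$q)
  }
  val <- log_family_marginal(fc, hyper_d)
  if (include_parent_roots) {
    g <- genotype_matrix(data)
    for (snp in p) {
      cnt <- tabulate(g[, snp] + 1L, nbins = 3L)
      fam <- list(r = 3L, q = 1L, s = matrix(cnt, nrow = 3L))
      h <- if (scheme == "bdeu") bdeu_hyper(alpha, 3L, 1L) else k2_hyper(3L, 1L)
      val <- val + log_family_marginal(fam, h)
    }
  }
  id <- if (scheme == "k2") "k2" else sprintf("bdeu:alpha=%g", alpha)
  score_report(id, data, p, val, "higher")
}

#' @rdname score_ddag
#' @export
score_mdl <- function(data, parents, variant = c("suzuki", "aic", "epi", "none"),
                      version = c("v1", "v2"), .id = NULL) {
  variant <- match.arg(variant)
  version <- match.arg(version)
  validate_genotypes(data)
  p <- resolve_parents(data, parents)
  fc <- family_counts(data, p)
  val <- dag_penalty_bits(fc$k, fc$m, variant, version) +
    encoding_length_bits(fc)
  id <- .id %||% if (variant == "none") "mdl-none" else {
    sprintf("mdl-%s-%s", variant, version)
  }
  score_report(id, data, p, val, "lower")
}

#' @rdname score_ddag
#' @export
score_mml <- function(data, parents, version = c("v1", "v2")) {
  version <- match.arg(version)
  validate_genotypes(data)
  p <- resolve_parents(data, parents)
  m <- nrow(data)
  k <- length(p)
  k2_log2 <- score_bayesian(data, p, "k2")$score / log(2)
  pen <- 3^k / 2 * log2(m)
  if (version == "v2") pen <- pen + k * log2(m)
  score_report(sprintf("mml-%s", version), data, p, k2_log2 - pen, "higher")
}

score_report <- function(id, data, parents, value, orientation) {
  tibble(
    criterion = id,
    parent_set = paste(snp_names(data)[parents], collapse = ","),
    k = length(parents),
    score = value,
    orientation = orientation
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
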