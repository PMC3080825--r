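#' Model-space counting
#'
#' A DDAG is identified by the disease node's parent set, so the model space
#' over n SNPs with parent sets of size kmin..kmax has
#' `sum(choose(n, kmin:kmax))` members (2^n when all sizes are allowed).
#' `count_dags()` counts all labeled DAGs on n nodes by the standard
#' inclusion-exclusion recurrence
#' `a_n = sum_{s=1..n} (-1)^(s+1) C(n,s) 2^(s(n-s)) a_(n-s)`, `a_0 = 1`,
#' for contrast with the DDAG space (e.g. ~4.2e18 DAGs on 10 nodes versus
#' 2^10 = 1024 DDAGs for 10 SNPs).
#'
#' Counts are returned as doubles: they are exact below 2^53 and carry ~15
#' significant digits beyond, which covers any panel size of practical
#' interest here.
#'
#' @param n Number of SNPs (or nodes for `count_dags()`).
#' @param kmin,kmax Parent-set size bounds, `0 <= kmin <= kmax <= n`.
#' @return A single numeric count.
#' @examples
#' count_parent_sets(20, 1, 4)   # 6195
#' count_parent_sets(101, 1, 4)  # 4254726
#' count_dags(10)                # ~4.2e18
#' @export
count_parent_sets <- function(n, kmin, kmax) {
  if (!(n >= 0 && kmin >= 0 && kmin <= kmax && kmax <= n)) {
    abort("need 0 <= kmin <= kmax <= n")
  }
  sum(choose(n, kmin:kmax))
}

#' @rdname count_parent_sets
#' @export
count_dags <- function(n) {
  stopifnot(n >= 0)
  a <- numeric(n + 1)
  a[1] <- 1
  if (n == 0) return(1)
  for (nn in seq_len(n)) {
    s <- seq_len(nn)
    a[nn + 1] <- sum((-1)^(s + 1) * choose(nn, s) * 2^(s * (nn - s)) * a[nn - s + 1])
  }
  a[n + 1]
}

#' Enumerate candidate parent sets
#'
#' All parent sets of sizes `kmin..kmax` over n SNPs, ordered by size
#' ascending and lexicographically within each size.  The whole list is
#' materialised; at the desk scales this package targets (a few thousand to
#' a few million models) this is cheap relative to scoring.
#'
#' @inheritParams count_parent_sets
#' @return A list of sorted integer vectors (1-based SNP column positions);
#'   its length equals `count_parent_sets(n, kmin, kmax)`.
#' @examples
#' enumerate_parent_sets(3, 1, 2)
#' @export
enumerate_parent_sets <- function(n, kmin, kmax) {
  if (!(n >= 0 && kmin >= 0 && kmin <= kmax && kmax <= n)) {
    abort("need 0 <= kmin <= kmax <= n")
  }
  out <- list()
  for (k in kmin:kmax) {
    if (k == 0L) {
      out <- c(out, list(integer()))
    } else {
      out <- c(out, asplit_combn(combn(n, k)))
    }
  }
  out
}

asplit_combn <- function(cm) {
  lapply(seq_len(ncol(cm)), function(j) as.integer(cm[, j]))
}

#' Score every candidate DDAG under one or more criteria
#'
#' The workhorse behind [exhaustive_search()], [two_stage_screen()] and the
#' evaluation harness.  Counts each model's disease-family contingency table
#' once and evaluates all requested criteria on it with vectorised
#' (per-parent-set-size) arithmetic, so adding criteria is much cheaper than
#' re-searching.
#'
#' @param data A genotype tibble.
#' @param criteria Character vector of criterion ids (see
#'   [parse_criterion()]).
#' @param kmin,kmax Parent-set size bounds.
#' @param subsets Optional list of integer parent sets to score instead of
#'   the full enumeration (used by the two-stage screen).
#' @return A tibble with one row per model: `parent_set` (comma-separated
#'   SNP names), `parents` (list column of column positions), `k`, and one
#'   numeric score column per criterion id.
#' @examples
#' d <- simulate_epistasis(build_pure_epistasis_model(0.3, 0.4, seed = 1),
#'                         n = 100, n_noise = 3, seed = 2)
#' score_all_ddags(d, c("k2", "bdeu:alpha=15"), 1, 2)
#' @export
score_all_ddags <- function(data, criteria, kmin = 1, kmax = 4,
                            subsets = NULL) {
  validate_genotypes(data)
  g <- genotype_matrix(data)
  ph <- phenotype(data)
  n <- ncol(g)
  m <- nrow(g)
  crits <- lapply(criteria, parse_criterion)
  if (is.null(subsets)) {
    subsets <- enumerate_parent_sets(n, kmin, kmax)
  } else {
    subsets <- lapply(subsets, function(p) resolve_parents(data, p))
  }
  nmod <- length(subsets)

  need_k2 <- any(vapply(crits, function(cr) {
    cr$type == "mml" || (cr$type == "bayesian" && cr$scheme == "k2")
  }, logical(1)))
  ks <- lengths(subsets)
  scores <- matrix(NA_real_, nrow = nmod, ncol = length(crits))

  for (k in sort(unique(ks))) {
    rows <- which(ks == k)
    q <- 3L^k
    S <- matrix(0, nrow = length(rows), ncol = 2L * q)
    for (i in seq_along(rows)) {
      code <- joint_state_code(g, subsets[[rows[i]]])
      S[i, ] <- tabulate(1L + code + q * ph, nbins = 2L * q)
    }
    Nj <- S[, seq_len(q), drop = FALSE] + S[, q + seq_len(q), drop = FALSE]
    bayes_disease <- function(a0) {
      rowSums(lgamma(a0 + S)) - 2 * q * lgamma(a0) +
        q * lgamma(2 * a0) - rowSums(lgamma(2 * a0 + Nj))
    }
    k2_vec <- if (need_k2) bayes_disease(1) else NULL
    enc_vec <- NULL
    enc_disease <- function() {
      if (is.null(enc_vec)) {
        enc_vec <<- rowSums(xlog2x(Nj)) - rowSums(xlog2x(S))
      }
      enc_vec
    }
    for (ci in seq_along(crits)) {
      cr <- crits[[ci]]
      val <- switch(cr$type,
        bayesian = if (cr$scheme == "k2") k2_vec else {
          bayes_disease(cr$alpha / (2 * q))
        },
        mdl = dag_penalty_bits(k, m, cr$variant, cr$version) + enc_disease(),
        mml = {
          pen <- 3^k / 2 * log2(m)
          if (cr$version == "v2") pen <- pen + k * log2(m)
          k2_vec / log(2) - pen
        }
      )
      scores[rows, ci] <- val
    }
  }

  out <- tibble(
    parent_set = vapply(subsets, function(p) {
      paste(snp_names(data)[p], collapse = ",")
    }, character(1)),
    parents = subsets,
    k = as.integer(ks)
  )
  for (ci in seq_along(crits)) out[[crits[[ci]]$id]] <- scores[, ci]
  out
}

#' Exhaustive DDAG search
#'
#' Scores every parent set of size `kmin..kmax` under one criterion and
#' returns the models ranked best-first.  No preference is given to any
#' model size beyond the score itself; ties are broken deterministically by
#' smaller parent-set size, then lexicographic parent set.
#'
#' @inheritParams score_all_ddags
#' @param criterion A single criterion id.
#' @return A `ddag_ranking` tibble with columns `rank`, `parent_set`,
#'   `parents` (list), `k` and `score`, carrying the criterion id and its
#'   orientation as attributes.
#' @examples
#' d <- simulate_epistasis(build_pure_epistasis_model(0.4, 0.4, seed = 1),
#'                         n = 200, n_noise = 4, seed = 2)
#' head(exhaustive_search(d, "bdeu:alpha=15", 1, 2))
#' @export
exhaustive_search <- function(data, criterion, kmin = 1, kmax = 4,
                              subsets = NULL) {
  crit <- parse_criterion(criterion)
  tab <- score_all_ddags(data, criterion, kmin, kmax, subsets = subsets)
  rank_models(tab, crit$id, crit$orientation)
}

rank_models <- function(tab, id, orientation, extra_keys = NULL) {
  score <- tab[[id]]
  dir_score <- if (orientation == "higher") -score else score
  lex <- vapply(tab$parents, function(p) {
    paste(sprintf("%06d", p), collapse = "")
  }, character(1))
  keys <- c(list(dir_score), extra_keys, list(tab$k, lex))
  ord <- do.call(order, keys)
  out <- tab[ord, ]
  out$score <- out[[id]]
  out[[id]] <- NULL
  out <- dplyr::relocate(out, "parent_set", "k", "score")
  out <- tibble::add_column(out, rank = seq_len(nrow(out)), .before = 1)
  attr(out, "criterion") <- id
  attr(out, "orientation") <- orientation
  class(out) <- c("ddag_ranking", class(out))
  out
}

#' Two-stage anchored screen
#'
#' For panels too large to search exhaustively, a known risk locus can be
#' used as an anchor.  Stage 1 scores every 2-parent model
#' `{anchor, SNP_i}`; the partner SNPs of the `top_m` best pair models are
#' pooled with the anchor.  Stage 2 exhaustively scores all parent sets of
#' size `1..kmax` drawn from that pool of `top_m + 1` loci and returns the
#' stage-2 ranking.  The same criterion is used for both stages.
#'
#' @inheritParams exhaustive_search
#' @param anchor The anchor SNP (name or column position).
#' @param top_m Number of stage-1 pair models whose partner SNPs are kept.
#' @return A `ddag_ranking` tibble (stage 2), with the stage-1 ranking in
#'   `attr(, "stage1")` and the pooled SNP names in `attr(, "pool")`.
#' @examples
#' d <- simulate_epistasis(build_pure_epistasis_model(0.4, 0.4, seed = 1),
#'                         n = 200, n_noise = 8, seed = 2)
#' scr <- two_stage_screen(d, anchor = 1, top_m = 4, kmax = 3,
#'                         criterion = "bdeu:alpha=15")
#' head(scr)
#' @export
two_stage_screen <- function(data, anchor, top_m, kmax = 4,
                             criterion = "bdeu:alpha=15") {
  validate_genotypes(data)
  anchor <- resolve_parents(data, anchor)
  if (length(anchor) != 1L) abort("'anchor' must be a single SNP")
  n <- length(snp_names(data))
  if (top_m < 1L) abort("'top_m' must be at least 1")
  others <- setdiff(seq_len(n), anchor)
  pairs <- lapply(others, function(i) sort(c(anchor, i)))
  stage1 <- exhaustive_search(data, criterion, subsets = pairs)
  partners <- vapply(stage1$parents, function(p) setdiff(p, anchor)[1], 0L)
  keep <- unique(partners[seq_len(min(top_m, length(partners)))])
  pool <- sort(c(anchor, keep))
  pool_sets <- enumerate_parent_sets(length(pool), 1L, min(kmax, length(pool)))
  subsets <- lapply(pool_sets, function(s) pool[s])
  out <- exhaustive_search(data, criterion, subsets = subsets)
  attr(out, "stage1") <- stage1
  attr(out, "pool") <- snp_names(data)[pool]
  attr(out, "anchor") <- snp_names(data)[anchor]
  out
}
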