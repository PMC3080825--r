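#' Multifactor dimensionality reduction (MDR) baseline
#'
#' A minimal, faithful MDR: each multilocus genotype cell of a SNP
#' combination is labeled high-risk when its case:control ratio reaches the
#' threshold (the overall case:control ratio; 1 for balanced data), reducing
#' the combination to one binary attribute, which is then evaluated by
#' stratified k-fold cross-validated balanced accuracy.  Conventions for
#' edge cases: empty cells are low-risk; cells with cases but no controls
#' are high-risk; a cell whose ratio equals the threshold is high-risk.
#'
#' @param counts A 2 x q matrix of per-cell counts (row 1 = controls, row 2
#'   = cases), as in `family_counts()$s`.
#' @param threshold Positive case:control ratio threshold.
#' @return A logical vector of length q: `TRUE` = high-risk.
#' @examples
#' s <- rbind(controls = c(1, 0, 2, 0), cases = c(3, 0, 2, 1))
#' mdr_label_cells(s, 1) # TRUE FALSE TRUE TRUE
#' @export
mdr_label_cells <- function(counts, threshold = 1) {
  if (is.list(counts)) counts <- counts$s
  stopifnot(nrow(counts) == 2L, threshold > 0)
  ctrl <- counts[1, ]
  case <- counts[2, ]
  # case >= threshold * ctrl avoids 0-division; covers the zero-control rule
  high <- case >= threshold * ctrl
  high[ctrl + case == 0] <- FALSE
  unname(high)
}

#' @rdname mdr_label_cells
#' @param data A genotype tibble.
#' @param combo SNP combination (positions or names).
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed for the fold assignment.
#' @return `mdr_cv_score()` returns a one-row tibble with `parent_set`, `k`,
#'   `testing_accuracy` and `cv_consistency` (`NA` outside [mdr_search()],
#'   where it is defined as the number of folds whose within-fold exhaustive
#'   comparison this combination wins).
#' @export
mdr_cv_score <- function(data, combo, folds = 10, seed = 1) {
  validate_genotypes(data)
  p <- resolve_parents(data, combo)
  if (length(p) == 0L) abort("'combo' must contain at least one SNP")
  fid <- mdr_fold_ids(data, folds, seed)
  acc <- mdr_fold_accuracies(genotype_matrix(data), phenotype(data), p, fid,
    folds)
  tibble(
    parent_set = paste(snp_names(data)[p], collapse = ","),
    k = length(p),
    testing_accuracy = mean(acc$test),
    cv_consistency = NA_integer_
  )
}

# Stratified fold assignment keyed to a canonical row order (sorted by row
# content), so permuting data rows cannot change which individuals share a
# fold.
mdr_fold_ids <- function(data, folds, seed) {
  stopifnot(folds >= 2)
  ph <- phenotype(data)
  if (min(tabulate(ph + 1L, 2L)) < folds) {
    abort(sprintf("cannot stratify %d folds: a class has fewer individuals",
      folds))
  }
  key <- do.call(paste, c(as.list(as.data.frame(genotype_matrix(data))),
    list(ph, sep = "\r")))
  fid <- integer(length(ph))
  withr::with_seed(seed, {
    for (cls in 0:1) {
      rows <- which(ph == cls)
      rows <- rows[order(key[rows])]
      fid[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
  })
  fid
}

# Per-fold train/test balanced accuracy for one combination.  One tabulate
# call yields the per-(cell, class, fold) counts.
mdr_fold_accuracies <- function(g, ph, p, fid, folds) {
  k <- length(p)
  q <- 3L^k
  code <- joint_state_code(g, p)
  cnt <- array(
    tabulate(1L + code + q * ph + 2L * q * (fid - 1L), nbins = 2L * q * folds),
    dim = c(q, 2L, folds)
  )
  tot <- rowSums(cnt, dims = 2)
  test_acc <- train_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- tot - cnt[, , f]
    thr <- sum(tr[, 2]) / sum(tr[, 1])
    high <- mdr_label_cells(t(tr), thr)
    train_acc[f] <- balanced_accuracy(tr, high)
    test_acc[f] <- balanced_accuracy(cnt[, , f], high)
  }
  list(test = test_acc, train = train_acc)
}

# counts: q x 2 matrix (col 1 controls, col 2 cases); high: logical q
balanced_accuracy <- function(counts, high) {
  tp <- sum(counts[high, 2])
  fn <- sum(counts[!high, 2])
  tn <- sum(counts[!high, 1])
  fp <- sum(counts[high, 1])
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0.5
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0.5
  (sens + spec) / 2
}

#' Exhaustive MDR search
#'
#' Scores every SNP combination of size `kmin..kmax` by cross-validated
#' testing balanced accuracy and ranks them (ties broken by
#' cross-validation consistency, then smaller size, then lexicographic).
#' The result has the same shape as [exhaustive_search()] output, so the
#' evaluation harness accepts it interchangeably.
#'
#' @inheritParams mdr_cv_score
#' @param kmin,kmax Combination size bounds.
#' @return A `ddag_ranking` tibble with `score` = testing balanced accuracy
#'   and an extra `cv_consistency` column; orientation "higher".
#' @examples
#' mod <- build_pure_epistasis_model(0.4, 0.4, seed = 1)
#' d <- simulate_epistasis(mod, n = 100, n_noise = 3, seed = 2)
#' head(mdr_search(d, 1, 2, folds = 5))
#' @export
mdr_search <- function(data, kmin = 1, kmax = 4, folds = 10, seed = 1) {
  validate_genotypes(data)
  g <- genotype_matrix(data)
  ph <- phenotype(data)
  n <- ncol(g)
  subsets <- enumerate_parent_sets(n, max(kmin, 1L), kmax)
  fid <- mdr_fold_ids(data, folds, seed)
  nmod <- length(subsets)
  test_acc <- matrix(0, nmod, folds)
  train_acc <- matrix(0, nmod, folds)
  for (i in seq_len(nmod)) {
    acc <- mdr_fold_accuracies(g, ph, subsets[[i]], fid, folds)
    test_acc[i, ] <- acc$test
    train_acc[i, ] <- acc$train
  }
  # within-fold winner by training accuracy; deterministic tie-break
  ks <- lengths(subsets)
  lex <- vapply(subsets, function(p) paste(sprintf("%06d", p), collapse = ""),
    character(1))
  cvc <- integer(nmod)
  for (f in seq_len(folds)) {
    best <- which(train_acc[, f] == max(train_acc[, f]))
    best <- best[order(ks[best], lex[best])][1]
    cvc[best] <- cvc[best] + 1L
  }
  tab <- tibble(
    parent_set = vapply(subsets, function(p) {
      paste(snp_names(data)[p], collapse = ",")
    }, character(1)),
    parents = subsets,
    k = as.integer(ks),
    mdr = rowMeans(test_acc),
    cv_consistency = cvc
  )
  rank_models(tab, "mdr", "higher", extra_keys = list(-tab$cv_consistency))
}
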