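#' Top-model accuracy and recall
#'
#' A criterion *correctly learns* the generating model when the rank-1
#' parent set equals the true functional set exactly (supersets do not
#' count).  *Recall* relaxes this to the fraction of true SNPs recovered by
#' the top-ranked model: `|S intersect T| / |S|` with S the generating
#' model's SNPs and T the top model's SNPs; 0 iff disjoint, 1 iff S is a
#' subset of T.
#'
#' @param ranked A `ddag_ranking` tibble (from [exhaustive_search()],
#'   [two_stage_screen()] or [mdr_search()]).
#' @param truth Integer vector of true functional SNP column positions.
#' @return `top_model_correct()` a logical; `recall()` a number in \[0, 1\].
#' @examples
#' recall(c(1, 2), c(1, 3, 4)) # 0.5
#' @export
top_model_correct <- function(ranked, truth) {
  stopifnot(nrow(ranked) >= 1)
  setequal(ranked$parents[[1]], as.integer(truth))
}

#' @rdname top_model_correct
#' @param truth_set,top_set Integer vectors of SNP column positions.
#' @export
recall <- function(truth_set, top_set) {
  if (length(truth_set) == 0L) abort("'truth_set' must be nonempty")
  length(intersect(truth_set, top_set)) / length(unique(truth_set))
}

#' McNemar's test for paired classifier disagreement
#'
#' Compares two methods over the same collection of data sets from the
#' discordant counts alone: `b` = data sets where method A was correct and
#' B wrong, `c` = the reverse.  The statistic is `(|b - c| - 1)^2 / (b + c)`
#' with continuity correction (the default) or `(b - c)^2 / (b + c)`
#' without; the p-value comes from the chi-square distribution with 1 degree
#' of freedom.
#'
#' @param b,c Nonnegative discordant counts, `b + c >= 1`.
#' @param correct Apply the continuity correction?
#' @return A one-row tibble with `statistic`, `p_value`, `b`, `c`,
#'   `corrected`.
#' @examples
#' mcnemar_test(0, 20, correct = FALSE)
#' @export
mcnemar_test <- function(b, c, correct = TRUE) {
  stopifnot(b >= 0, c >= 0)
  if (b + c < 1) abort("McNemar's test is undefined when b = c = 0")
  stat <- if (correct) {
    (max(abs(b - c) - 1, 0))^2 / (b + c)
  } else {
    (b - c)^2 / (b + c)
  }
  tibble(
    statistic = stat,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE),
    b = b, c = c, corrected = correct
  )
}

#' Accuracy/recall experiment over simulated data sets
#'
#' The full simulated-data harness: for every design row a data set is
#' simulated, every criterion runs an exhaustive DDAG search, and top-model
#' correctness plus recall are tallied per (criterion, sample size).  The
#' best criterion (by total correct count) is compared to every other one
#' with McNemar's test on the discordant counts.
#'
#' @param designs A tibble of simulation designs as built by
#'   [simulation_design()] (columns `model`, `n`, `n_noise`, `noise_maf`,
#'   `seed`).
#' @param criteria Character vector of criterion ids.
#' @param kmin,kmax Search bounds.
#' @return An object of class `epi_experiment`: a list with tibbles
#'   `summary` (criterion, n, correct, total, accuracy, mean_recall,
#'   recall_sum), `per_dataset`, and `mcnemar` (each criterion vs the
#'   best).  `tidy()` returns the summary, `glance()` one row for the best
#'   criterion.
#' @examples
#' mod <- build_pure_epistasis_model(0.4, 0.4, seed = 1)
#' des <- simulation_design(rep(list(mod), 3), n = 400, n_noise = 4,
#'                          seed = 11:13)
#' ex <- accuracy_experiment(des, c("k2", "bdeu:alpha=15"), 1, 2)
#' tidy(ex)
#' @export
accuracy_experiment <- function(designs, criteria, kmin = 1, kmax = 4) {
  stopifnot(nrow(designs) >= 1, length(criteria) >= 1)
  crits <- lapply(criteria, parse_criterion)
  per <- vector("list", nrow(designs))
  for (i in seq_len(nrow(designs))) {
    des <- designs[i, ]
    noise_maf <- if (is.na(des$noise_maf)) NULL else des$noise_maf
    d <- simulate_epistasis(des$model[[1]], n = des$n,
      n_noise = des$n_noise, noise_maf = noise_maf, seed = des$seed)
    truth <- functional_snps(d)
    tab <- score_all_ddags(d, criteria, kmin, kmax)
    per[[i]] <- purrr::map_dfr(crits, function(cr) {
      top <- top_parent_set(tab, cr$id, cr$orientation)
      tibble(
        dataset = i, n = des$n, criterion = cr$id,
        correct = setequal(top, truth),
        recall = recall(truth, top),
        top_k = length(top)
      )
    })
  }
  per <- dplyr::bind_rows(per)
  summary <- per |>
    dplyr::group_by(.data$criterion, .data$n) |>
    dplyr::summarise(
      correct = sum(.data$correct), total = dplyr::n(),
      accuracy = mean(.data$correct),
      mean_recall = mean(.data$recall),
      recall_sum = sum(.data$recall),
      .groups = "drop"
    )
  totals <- summary |>
    dplyr::group_by(.data$criterion) |>
    dplyr::summarise(correct = sum(.data$correct), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$correct))
  best <- totals$criterion[1]
  wide <- per |>
    dplyr::select("dataset", "criterion", "correct") |>
    tidyr::pivot_wider(names_from = "criterion", values_from = "correct")
  mcn <- purrr::map_dfr(setdiff(criteria, best), function(id) {
    b <- sum(wide[[best]] & !wide[[id]])
    c <- sum(!wide[[best]] & wide[[id]])
    if (b + c == 0) {
      tibble(best = best, criterion = id, b = b, c = c,
        statistic = NA_real_, p_value = NA_real_)
    } else {
      mt <- mcnemar_test(b, c)
      tibble(best = best, criterion = id, b = b, c = c,
        statistic = mt$statistic, p_value = mt$p_value)
    }
  })
  structure(
    list(summary = summary, per_dataset = per, mcnemar = mcn, best = best),
    class = "epi_experiment"
  )
}

#' Best model of a multi-criterion score table
#'
#' Picks the best-scoring parent set from a [score_all_ddags()] table under
#' one criterion, using the same deterministic tie-break as
#' [exhaustive_search()] (smaller parent set first, then lexicographic).
#'
#' @param tab A [score_all_ddags()] result.
#' @param criterion A criterion id present as a column of `tab`.
#' @return Integer vector of SNP column positions of the top model.
#' @export
top_model <- function(tab, criterion) {
  top_parent_set(tab, criterion, criterion_orientation(criterion))
}

# Best-scoring row of a score_all_ddags() table under one criterion, with
# the deterministic (k, lexicographic) tie-break; returns the parent set.
top_parent_set <- function(tab, id, orientation) {
  s <- tab[[id]]
  best <- if (orientation == "higher") max(s) else min(s)
  cand <- which(s == best)
  if (length(cand) > 1L) {
    lex <- vapply(tab$parents[cand], function(p) {
      paste(sprintf("%06d", p), collapse = "")
    }, character(1))
    cand <- cand[order(tab$k[cand], lex)]
  }
  tab$parents[[cand[1]]]
}

#' @export
print.epi_experiment <- function(x, ...) {
  cat("<epi_experiment>\n")
  print(x$summary)
  cat(sprintf("best criterion: %s\n", x$best))
  invisible(x)
}

#' Marker-hit report for a ranking
#'
#' Inspects the `top_n` best models of a ranking and reports how many of
#' them contain at least one SNP from a marker set of interest (e.g. all
#' SNPs in one candidate gene), and how many distinct marker SNPs appear.
#'
#' @param ranked A `ddag_ranking` tibble.
#' @param marker_set Integer vector of marker SNP column positions.
#' @param top_n Number of top models to inspect.
#' @return A list of class `marker_hits` with `models_with_hit`,
#'   `distinct_markers`, and `flags` (a tibble with one row per inspected
#'   model: rank, parent_set, k, hit, markers_in_model).
#' @export
marker_hit_report <- function(ranked, marker_set, top_n = 25) {
  stopifnot(top_n >= 1)
  marker_set <- as.integer(marker_set)
  top <- head(ranked, top_n)
  in_model <- lapply(top$parents, intersect, marker_set)
  flags <- tibble(
    rank = top$rank, parent_set = top$parent_set, k = top$k,
    hit = lengths(in_model) > 0,
    markers_in_model = vapply(in_model, function(x) {
      paste(x, collapse = ",")
    }, character(1))
  )
  structure(
    list(
      models_with_hit = sum(flags$hit),
      distinct_markers = length(unique(unlist(in_model))),
      flags = flags
    ),
    class = "marker_hits"
  )
}

#' @export
print.marker_hits <- function(x, ...) {
  cat(sprintf(
    "<marker_hits> %d of top %d models contain a marker SNP (%d distinct markers)\n",
    x$models_with_hit, nrow(x$flags), x$distinct_markers
  ))
  invisible(x)
}
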