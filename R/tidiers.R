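#' Tidy and glance methods
#'
#' Broom-style summaries for the package's result objects.
#'
#' @param x A `ddag_ranking`, `two_locus_model`, `epi_experiment` or
#'   `marker_hits` object.
#' @param ... Unused.
#' @return A tibble.
#' @name epiddag-tidiers
NULL

#' @rdname epiddag-tidiers
#' @export
tidy.ddag_ranking <- function(x, ...) {
  tibble(
    rank = x$rank, parent_set = x$parent_set, k = x$k, score = x$score,
    criterion = attr(x, "criterion"), orientation = attr(x, "orientation")
  )
}

#' @rdname epiddag-tidiers
#' @export
glance.ddag_ranking <- function(x, ...) {
  tibble(
    criterion = attr(x, "criterion"),
    orientation = attr(x, "orientation"),
    n_models = nrow(x),
    top_parent_set = x$parent_set[1],
    top_k = x$k[1],
    top_score = x$score[1]
  )
}

#' @rdname epiddag-tidiers
#' @export
tidy.two_locus_model <- function(x, ...) {
  tidyr::expand_grid(g1 = 0:2, g2 = 0:2) |>
    dplyr::mutate(penetrance = as.vector(t(x$penetrance)))
}

#' @rdname epiddag-tidiers
#' @export
glance.two_locus_model <- function(x, ...) {
  marg <- marginal_penetrances(x)
  tibble(
    maf1 = x$maf1, maf2 = x$maf2,
    prevalence = prevalence(x),
    heritability = heritability(x),
    max_marginal_dev = max(
      abs(marg$locus1 - prevalence(x)),
      abs(marg$locus2 - prevalence(x))
    )
  )
}

#' @rdname epiddag-tidiers
#' @export
tidy.epi_experiment <- function(x, ...) {
  x$summary
}

#' @rdname epiddag-tidiers
#' @export
glance.epi_experiment <- function(x, ...) {
  best <- x$summary |>
    dplyr::filter(.data$criterion == x$best) |>
    dplyr::summarise(
      correct = sum(.data$correct), total = sum(.data$total),
      mean_recall = mean(.data$mean_recall)
    )
  tibble(
    best_criterion = x$best,
    correct = best$correct, total = best$total,
    accuracy = best$correct / best$total,
    mean_recall = best$mean_recall,
    n_criteria = length(unique(x$summary$criterion))
  )
}

#' @rdname epiddag-tidiers
#' @export
tidy.marker_hits <- function(x, ...) {
  x$flags
}

#' @rdname epiddag-tidiers
#' @export
glance.marker_hits <- function(x, ...) {
  tibble(
    models_with_hit = x$models_with_hit,
    distinct_markers = x$distinct_markers,
    top_n = nrow(x$flags)
  )
}
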