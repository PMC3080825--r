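#' Plot methods
#'
#' `autoplot.ddag_ranking()` shows the score of the best models against
#' their rank, coloured by parent-set size.  `autoplot.two_locus_model()`
#' draws the penetrance table as a heat map.  `autoplot.epi_experiment()`
#' shows top-model accuracy per criterion across sample sizes.
#'
#' @param object The result object.
#' @param top_n Number of top-ranked models to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @name epiddag-plots
NULL

#' @rdname epiddag-plots
#' @export
autoplot.ddag_ranking <- function(object, top_n = 50, ...) {
  df <- head(tidy(object), top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$score,
    colour = factor(.data$k))) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "rank", y = sprintf("score (%s)", attr(object, "criterion")),
      colour = "parents",
      title = sprintf("Top %d DDAG models (%s is better)", nrow(df),
        attr(object, "orientation"))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname epiddag-plots
#' @export
autoplot.two_locus_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$g1), y = factor(.data$g2),
    fill = .data$penetrance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "white",
      high = "firebrick") +
    ggplot2::labs(
      x = "locus 1 genotype", y = "locus 2 genotype", fill = "P(disease)",
      title = sprintf("Penetrance table (h2 = %.3g, maf = %.2g)",
        heritability(object), object$maf1)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname epiddag-plots
#' @export
autoplot.epi_experiment <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = factor(.data$n),
    y = .data$accuracy, group = .data$criterion,
    colour = .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "sample size", y = "top-model accuracy",
      colour = "criterion") +
    ggplot2::theme_minimal()
}
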