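#' Scoring criterion identifiers
#'
#' Every scoring function in the package is addressed by a string id:
#'
#' * `"k2"` — Bayesian score, all Dirichlet hyperparameters equal to 1.
#' * `"bdeu:alpha=A"` — Bayesian Dirichlet equivalent uniform score with
#'   prior equivalent sample size `A` (e.g. `"bdeu:alpha=15"`); hyperparameters
#'   `alpha / (r * q)` per family.
#' * `"mdl-suzuki-v1"`, `"mdl-suzuki-v2"` — MDL with the (d/2) log2(m) penalty.
#' * `"mdl-aic-v1"`, `"mdl-aic-v2"` — MDL with a one-bit-per-parameter penalty
#'   (independent of m).
#' * `"mdl-epi-v1"`, `"mdl-epi-v2"` — MDL with the epistasis-tailored penalty
#'   in which the disease node's parameter precision is m/3^k.
#' * `"mdl-none"` — MDL with no structure penalty (pure data-encoding length).
#' * `"mml-v1"`, `"mml-v2"` — minimum message length: the K2 score in log2
#'   space minus a (d/2) log2(m) parameter penalty.
#'
#' Version 1 scores include only the disease-node term in the penalty (all n
#' SNPs are regarded as part of every model, so SNP-node contributions cancel
#' across models); version 2 scores include the k parent SNPs as model nodes,
#' adding their penalty and (for MDL) marginal encoding terms.
#'
#' Bayesian and MML scores are "higher is better"; MDL bit totals are "lower
#' is better".
#'
#' @param id A criterion id string.
#' @return `parse_criterion()` returns a list with elements `id`, `type`
#'   (`"bayesian"`, `"mdl"` or `"mml"`), `orientation` (`"higher"` or
#'   `"lower"`), and type-specific fields (`scheme`, `alpha`, `variant`,
#'   `version`).  `list_criteria()` returns the canonical id vector.
#' @examples
#' parse_criterion("bdeu:alpha=15")$alpha
#' list_criteria()
#' @export
parse_criterion <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  if (id == "k2") {
    return(list(id = "k2", type = "bayesian", scheme = "k2", alpha = NA_real_,
      orientation = "higher"))
  }
  if (grepl("^bdeu:alpha=", id)) {
    alpha <- suppressWarnings(as.numeric(sub("^bdeu:alpha=", "", id)))
    if (is.na(alpha) || alpha <= 0) {
      abort(sprintf("invalid BDeu prior equivalent sample size in '%s'", id))
    }
    return(list(id = id, type = "bayesian", scheme = "bdeu", alpha = alpha,
      orientation = "higher"))
  }
  if (id == "mdl-none") {
    return(list(id = id, type = "mdl", variant = "none", version = "v1",
      orientation = "lower"))
  }
  m <- regmatches(id, regexec("^mdl-(suzuki|aic|epi)-(v1|v2)$", id))[[1]]
  if (length(m) == 3L) {
    return(list(id = id, type = "mdl", variant = m[2], version = m[3],
      orientation = "lower"))
  }
  m <- regmatches(id, regexec("^mml-(v1|v2)$", id))[[1]]
  if (length(m) == 2L) {
    return(list(id = id, type = "mml", version = m[2], orientation = "higher"))
  }
  abort(sprintf("unknown scoring criterion '%s'", id))
}

#' @rdname parse_criterion
#' @param alpha_grid Numeric vector of BDeu prior equivalent sample sizes to
#'   include in the listing.
#' @export
list_criteria <- function(alpha_grid = c(1, 3, 6, 9, 12, 15, 18, 21, 24, 30,
                                         36, 42, 54, 162)) {
  c(
    "k2",
    sprintf("bdeu:alpha=%g", alpha_grid),
    sprintf("mdl-%s-%s", rep(c("suzuki", "aic", "epi"), each = 2),
      c("v1", "v2")),
    "mdl-none",
    "mml-v1", "mml-v2"
  )
}

#' @rdname parse_criterion
#' @export
criterion_orientation <- function(id) {
  parse_criterion(id)$orientation
}
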