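#' Case-control genotype tables
#'
#' A genotype table is an ordinary tibble in "MDR format": one integer column
#' per biallelic SNP coded as minor-allele dosage 0/1/2, plus a final binary
#' class column (1 = case, 0 = control).  The class column is recognised by
#' position (last), not by name.  The three genotype states are treated
#' categorically by every scoring function, so the dosage coding is only a
#' file convention.
#'
#' @param data A data frame in MDR format (last column = class).
#' @return `validate_genotypes()` returns `data` (as a tibble) invisibly after
#'   checking it; it throws an informative error naming the offending
#'   row/column otherwise.
#' @examples
#' d <- tibble::tibble(S1 = c(0L, 2L), S2 = c(1L, 1L), Class = c(1L, 0L))
#' validate_genotypes(d)
#' snp_names(d)
#' @export
validate_genotypes <- function(data) {
  data <- as_tibble(data)
  if (ncol(data) < 2L) {
    abort("a genotype table needs at least one SNP column plus the class column")
  }
  if (nrow(data) < 1L) {
    abort("a genotype table needs at least one row")
  }
  g <- data[-ncol(data)]
  for (j in seq_along(g)) {
    v <- g[[j]]
    bad <- which(is.na(v) | !(v %in% c(0L, 1L, 2L)))
    if (length(bad)) {
      abort(sprintf(
        "malformed genotype: value %s at row %d, column '%s' (must be 0, 1 or 2)",
        as.character(v[bad[1]]), bad[1], names(g)[j]
      ))
    }
  }
  ph <- data[[ncol(data)]]
  bad <- which(is.na(ph) | !(ph %in% c(0L, 1L)))
  if (length(bad)) {
    abort(sprintf(
      "malformed class: value %s at row %d (must be 0 or 1)",
      as.character(ph[bad[1]]), bad[1]
    ))
  }
  invisible(data)
}

#' @rdname validate_genotypes
#' @export
snp_names <- function(data) {
  names(data)[-ncol(data)]
}

#' @rdname validate_genotypes
#' @export
phenotype <- function(data) {
  as.integer(data[[ncol(data)]])
}

#' @rdname validate_genotypes
#' @export
genotype_matrix <- function(data) {
  g <- as.matrix(data[-ncol(data)])
  storage.mode(g) <- "integer"
  g
}

#' Read and write MDR-format genotype tables
#'
#' Tab-delimited (default) or CSV text files with a header row, one 0/1/2
#' column per SNP and the 0/1 class column last.  The round trip through
#' either dialect is lossless.  Missing genotypes are not supported: any
#' non-integer, out-of-range or missing cell is rejected with an error that
#' names the row and column.
#'
#' @param path Path to the file.
#' @param dialect `"tab"` or `"csv"`.
#' @return `read_genotype_table()` returns a validated genotype tibble.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' d <- tibble::tibble(S1 = c(0L, 1L), S2 = c(2L, 1L), Class = c(1L, 0L))
#' write_genotype_table(d, f)
#' identical(read_genotype_table(f), d)
#' @export
read_genotype_table <- function(path, dialect = c("tab", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- if (dialect == "tab") "\t" else ","
  data <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_integer()),
    progress = FALSE, show_col_types = FALSE, lazy = FALSE
  )
  prob <- readr::problems(data)
  if (nrow(prob) > 0L) {
    abort(sprintf(
      "parse error in %s: row %d, column %d (%s)",
      path, prob$row[1], prob$col[1], prob$expected[1]
    ))
  }
  validate_genotypes(data)
  data
}

#' @rdname read_genotype_table
#' @param data A genotype tibble (see [validate_genotypes()]).
#' @export
write_genotype_table <- function(data, path, dialect = c("tab", "csv")) {
  dialect <- match.arg(dialect)
  validate_genotypes(data)
  if (dialect == "tab") {
    readr::write_tsv(data, path, progress = FALSE)
  } else {
    readr::write_csv(data, path, progress = FALSE)
  }
  invisible(path)
}

#' Sufficient statistics for one DDAG family
#'
#' Tallies the 2 x 3^k contingency table of the disease node against the
#' joint genotype states of its parent SNPs.  Joint parent states are indexed
#' in a fixed mixed-radix order: parents are taken in ascending column order
#' and the lowest column index is the most significant digit, so state
#' `j = 1 + sum_i g[parent_i] * 3^(k-i)`.  This indexing is part of the
#' package contract: it makes every score reproducible.
#'
#' @param data A genotype tibble.
#' @param parents Integer vector of SNP column positions (1-based, among the
#'   SNP columns only) or a character vector of SNP names.  May be empty
#'   (the parentless disease model).
#' @return An object of class `family_counts`: a list with elements `r` (2),
#'   `q` (3^k), `k`, `m`, `s` (an `r` x `q` integer matrix, rows = disease
#'   states 0/1, columns = joint parent states) and `parent_states` (a tibble
#'   mapping each column of `s` to its genotype tuple).
#' @examples
#' d <- tibble::tibble(S1 = c(0L, 0L, 1L, 2L), S2 = c(1L, 1L, 0L, 2L),
#'                     Class = c(0L, 1L, 1L, 0L))
#' family_counts(d, "S1")$s
#' @export
family_counts <- function(data, parents = integer()) {
  validate_genotypes(data)
  p <- resolve_parents(data, parents)
  g <- genotype_matrix(data)
  ph <- phenotype(data)
  k <- length(p)
  q <- 3L^k
  code <- joint_state_code(g, p)
  s <- matrix(tabulate(1L + code + q * ph, nbins = 2L * q),
    nrow = 2L, ncol = q, byrow = TRUE
  )
  rownames(s) <- c("0", "1")
  states <- parent_state_table(snp_names(data)[p], k)
  structure(
    list(r = 2L, q = q, k = k, m = nrow(data), s = s, parent_states = states),
    class = "family_counts"
  )
}

#' @export
print.family_counts <- function(x, ...) {
  cat(sprintf(
    "<family_counts> disease node with %d parent(s): r = %d, q = %d, m = %d\n",
    x$k, x$r, x$q, x$m
  ))
  print(x$s)
  invisible(x)
}

# 0-based mixed-radix joint state code per row; parents sorted ascending,
# lowest column index most significant.
joint_state_code <- function(g, parents) {
  parents <- sort(parents)
  if (length(parents) == 0L) {
    return(integer(nrow(g)))
  }
  code <- g[, parents[1]]
  for (p in parents[-1]) code <- code * 3L + g[, p]
  code
}

parent_state_table <- function(parent_names, k) {
  if (k == 0L) {
    return(tibble(state = 1L))
  }
  grid <- expand.grid(rev(replicate(k, 0:2, simplify = FALSE)))[, k:1, drop = FALSE]
  names(grid) <- parent_names
  out <- as_tibble(grid)
  out$state <- seq_len(3L^k)
  out
}

# Accepts SNP names or 1-based positions among the SNP columns; returns
# sorted integer positions.
resolve_parents <- function(data, parents) {
  nms <- snp_names(data)
  n <- length(nms)
  if (is.character(parents)) {
    idx <- match(parents, nms)
    if (anyNA(idx)) {
      abort(sprintf("unknown SNP name(s): %s",
        paste(parents[is.na(idx)], collapse = ", ")))
    }
  } else {
    idx <- as.integer(parents)
    if (length(idx) && (anyNA(idx) || any(idx < 1L) || any(idx > n))) {
      abort(sprintf("parent index out of range [1, %d]", n))
    }
  }
  if (anyDuplicated(idx)) abort("duplicate parent indices")
  sort(idx)
}
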