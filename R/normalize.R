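#' Two-pass standardization of an expression matrix
#'
#' Standardizes a gene x sample expression matrix in exactly two passes:
#' first every gene row is centred (median by default) and scaled to unit
#' standard deviation, then every sample column is centred and scaled the
#' same way.  The passes are applied once each, in that order; the transform
#' is not iterated to a joint fixed point.  After the second pass the row
#' constraints are in general no longer satisfied exactly, which is
#' intentional: downstream score thresholds are calibrated against data
#' prepared this way.
#'
#' The standard deviation uses the population convention (divide by `n`,
#' not `n - 1`).  The choice only rescales scores uniformly, but it is kept
#' fixed so that thresholds are comparable across runs.
#'
#' @param x Numeric matrix, genes in rows and samples in columns.  Row and
#'   column names, when present, must be unique.
#' @param center Either `"median"` (default) or `"mean"`; the location
#'   statistic subtracted in both passes.
#' @return A numeric matrix of the same dimensions and dimnames.
#' @examples
#' x <- matrix(rnorm(40), 8, 5,
#'             dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
#' xn <- normalize_matrix(x)
#' apply(xn, 2, median)  # all ~0
#' @export
normalize_matrix <- function(x, center = c("median", "mean")) {
  center <- match.arg(center)
  x <- as_expression_matrix(x)
  if (anyNA(x)) {
    stop("expression matrix contains missing values; imputation is not supported")
  }
  x <- standardize_rows(x, center, margin = "gene")
  x <- t(standardize_rows(t(x), center, margin = "sample"))
  x
}

## population sd: sqrt(mean((x - mean(x))^2))
sd_pop <- function(v) {
  sqrt(sum((v - mean(v))^2) / length(v))
}

standardize_rows <- function(x, center, margin) {
  ctr <- if (center == "median") {
    apply(x, 1L, stats::median)
  } else {
    rowMeans(x)
  }
  s <- apply(x, 1L, sd_pop)
  bad <- which(s == 0)
  if (length(bad) > 0L) {
    ids <- rownames(x)[bad]
    if (is.null(ids)) ids <- as.character(bad)
    stop(sprintf(
      "zero-variance %s%s: %s (pre-filter with drop_zero_variance())",
      margin, if (length(bad) > 1L) "s" else "",
      paste(utils::head(ids, 5L), collapse = ", ")
    ))
  }
  (x - ctr) / s
}

#' Validate a gene x sample expression matrix
#'
#' Coerces to a base numeric matrix and checks the invariants expected
#' throughout the package: at least one row and column, numeric entries,
#' and unique gene/sample identifiers when dimnames are present.
#'
#' @param x A numeric matrix or an object coercible to one.
#' @return The validated matrix.
#' @export
as_expression_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression matrix must be numeric")
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("expression matrix must have at least one gene and one sample")
  }
  if (!is.null(rownames(x)) && anyDuplicated(rownames(x))) {
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    stop("duplicate gene identifiers: ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (!is.null(colnames(x)) && anyDuplicated(colnames(x))) {
    dup <- unique(colnames(x)[duplicated(colnames(x))])
    stop("duplicate sample identifiers: ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  x
}

#' Drop zero-variance genes and samples before normalization
#'
#' Rows (then columns) with zero standard deviation cannot be standardized;
#' [normalize_matrix()] treats them as an error.  This pre-filter removes
#' them and reports how many were dropped.
#'
#' @param x Numeric expression matrix.
#' @param quiet Suppress the message about dropped rows/columns.
#' @return The filtered matrix.
#' @export
drop_zero_variance <- function(x, quiet = FALSE) {
  x <- as_expression_matrix(x)
  rs <- apply(x, 1L, sd_pop)
  if (any(rs == 0)) {
    if (!quiet) message("dropping ", sum(rs == 0), " zero-variance gene(s)")
    x <- x[rs > 0, , drop = FALSE]
  }
  cs <- apply(x, 2L, sd_pop)
  if (any(cs == 0)) {
    if (!quiet) message("dropping ", sum(cs == 0), " zero-variance sample(s)")
    x <- x[, cs > 0, drop = FALSE]
  }
  if (nrow(x) < 1L || ncol(x) < 1L) stop("no rows/columns left after variance filter")
  x
}
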