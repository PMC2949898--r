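#' Upper tail of the hypergeometric distribution
#'
#' Probability of observing `k` or more marked samples when drawing
#' `s_size` samples without replacement from a population of `N` samples of
#' which `m` are marked.  Computed as the exact tail sum with log-space
#' binomial coefficients, so extreme enrichments (p-values far below
#' machine epsilon on the linear scale of a single term) are accumulated
#' without underflow.
#'
#' @param k Observed count of marked samples in the draw.
#' @param m Number of marked samples in the population.
#' @param s_size Draw size.
#' @param N Population size.
#' @return P\[X >= k\], in (0, 1\].
#' @export
hypergeometric_tail <- function(k, m, s_size, N) {
  stopifnot(length(k) == 1, length(m) == 1, length(s_size) == 1, length(N) == 1)
  if (m > N || s_size > N) stop("m and s_size must not exceed N")
  if (k < 0 || k > min(m, s_size)) {
    stop(sprintf("k = %d outside [0, min(m, s_size) = %d]", k, min(m, s_size)))
  }
  x <- seq.int(k, min(m, s_size))
  logterms <- lchoose(m, x) + lchoose(N - m, s_size - x) - lchoose(N, s_size)
  logterms <- logterms[is.finite(logterms)]
  if (length(logterms) == 0L) return(0)
  top <- max(logterms)
  min(exp(top + log(sum(exp(logterms - top)))), 1)
}

#' Sample class annotations
#'
#' Validates a per-sample annotation table: one row per sample, a
#' categorical class label (may be `NA` for unannotated samples, which are
#' excluded from all tests), and an optional ordinal score such as a
#' malignancy grade.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param class Character/factor class labels; `NA` marks unannotated
#'   samples.
#' @param score Optional numeric ordinal score per sample.
#' @return A data frame of class `"sample_annotation"`.
#' @export
sample_annotation <- function(sample_id, class, score = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample identifiers in annotation: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  ann <- data.frame(sample_id = sample_id, class = as.character(class),
                    stringsAsFactors = FALSE)
  if (!is.null(score)) ann$score <- as.numeric(score)
  class(ann) <- c("sample_annotation", "data.frame")
  ann
}

## Resolve a bicluster's annotated sample ids and the annotated universe.
saturation_counts <- function(b, ann) {
  ids <- if (inherits(b, "bicluster")) bicluster_members(b)$samples else as.character(b)
  unknown <- setdiff(ids, ann$sample_id)
  if (length(unknown) > 0L) {
    stop("bicluster samples missing from annotation: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  annotated <- ann[!is.na(ann$class), , drop = FALSE]
  in_b <- annotated$sample_id %in% ids
  list(classes = sort(unique(annotated$class)),
       class_all = annotated$class,
       class_b = annotated$class[in_b],
       N = nrow(annotated),
       s_size = sum(in_b))
}

#' Multiple-class saturation (MCS) p-value of a bicluster
#'
#' Scans every nonempty subset of the sample classes and scores, for each
#' subset, the hypergeometric tail probability of seeing that many or more
#' of the subset's samples inside the bicluster.  Returns the subset with
#' the smallest p-value, i.e. the group of phenotypes the bicluster is most
#' saturated with.  The raw minimum is reported (no multiplicity
#' correction), together with the number of subsets scanned so the caller
#' can Bonferroni-adjust if desired.  Unannotated samples are excluded from
#' both the bicluster and the population.
#'
#' @param b A `"bicluster"`, or a character vector of sample identifiers.
#' @param ann A [sample_annotation()] table covering the matrix samples.
#' @param max_q Guard on the number of classes; the scan is exhaustive over
#'   `2^q - 1` subsets.
#' @return A `"saturation"` object: `class_subset`, the Eq.-style counts
#'   `k`, `m`, `s_size`, `N`, `p_value`, and `n_subsets_tested`.
#' @export
mcs_pvalue <- function(b, ann, max_q = 10L) {
  cnt <- saturation_counts(b, ann)
  q <- length(cnt$classes)
  if (q < 1L) stop("no annotated classes")
  if (q > max_q) {
    stop(sprintf("%d classes: exhaustive subset scan over 2^q - 1 is infeasible; restrict the classes", q))
  }
  subsets <- class_subsets(cnt$classes)
  best <- NULL
  for (sub in subsets) {
    m <- sum(cnt$class_all %in% sub)
    k <- sum(cnt$class_b %in% sub)
    p <- hypergeometric_tail(k, m, cnt$s_size, cnt$N)
    if (is.null(best) || p < best$p_value) {
      best <- saturation_result(sub, k, m, cnt$s_size, cnt$N, p, length(subsets))
    }
  }
  best
}

#' Single-class saturation (SCS) p-value of a bicluster
#'
#' The restriction of [mcs_pvalue()] to single classes: the most enriched
#' individual class and its hypergeometric tail p-value.  Always at least
#' the MCS p-value, since the MCS scan minimizes over a superset of class
#' subsets.
#'
#' @inheritParams mcs_pvalue
#' @return A `"saturation"` object (see [mcs_pvalue()]).
#' @export
scs_pvalue <- function(b, ann) {
  cnt <- saturation_counts(b, ann)
  if (length(cnt$classes) < 1L) stop("no annotated classes")
  best <- NULL
  for (cl in cnt$classes) {
    m <- sum(cnt$class_all == cl)
    k <- sum(cnt$class_b == cl)
    p <- hypergeometric_tail(k, m, cnt$s_size, cnt$N)
    if (is.null(best) || p < best$p_value) {
      best <- saturation_result(cl, k, m, cnt$s_size, cnt$N, p, length(cnt$classes))
    }
  }
  best
}

## all nonempty subsets, smallest first so the min-p tie-break is the
## smallest, lexicographically earliest subset
class_subsets <- function(classes) {
  q <- length(classes)
  out <- list()
  for (r in seq_len(q)) {
    combs <- utils::combn(classes, r, simplify = FALSE)
    out <- c(out, combs)
  }
  out
}

saturation_result <- function(class_subset, k, m, s_size, N, p, n_tested) {
  structure(list(
    class_subset = class_subset, k = as.integer(k), m = as.integer(m),
    s_size = as.integer(s_size), N = as.integer(N),
    p_value = p, n_subsets_tested = as.integer(n_tested)
  ), class = "saturation")
}

#' @export
print.saturation <- function(x, ...) {
  cat(sprintf("Saturation: {%s}  k = %d of m = %d (|S| = %d, N = %d)  p = %.3g\n",
              paste(x$class_subset, collapse = ", "),
              x$k, x$m, x$s_size, x$N, x$p_value))
  invisible(x)
}

#' Jonckheere concordance statistic
#'
#' Counts sample pairs on which a continuous ordering `h` agrees strictly
#' with an ordinal annotation `y`: pairs with `h(s) < h(s')` and
#' `y(s) < y(s')`.  Ties in either vector contribute nothing.
#'
#' @param h Numeric score vector (e.g. BOA sample scores).
#' @param y Ordinal annotation vector of the same length.
#' @return Integer pair count.
#' @export
jonckheere_U <- function(h, y) {
  stopifnot(length(h) == length(y), length(h) >= 2)
  sum(outer(h, h, "<") & outer(y, y, "<"))
}

#' Jonckheere trend test for a monotone trend across ordered classes
#'
#' Tests whether a sample ordering `h` increases (or decreases) along an
#' ordinal grouping `y`, e.g. whether expression-based sample scores track a
#' malignancy grade.  Under the null of a random ordering the concordance
#' count U is approximately normal with mean `sum_(i<j) N_i N_j / 2` and
#' variance `[N^2 (2N + 3) - sum_i N_i^2 (2 N_i + 3)] / 72`, where `N_i`
#' are the class sizes; the test reports the one-sided normal p-value in
#' the observed direction, with the direction attached as a sign (so a
#' decreasing trend prints as a negative signed p).
#'
#' The variance formula assumes no ties in `h`.  With ties present the
#' result is flagged and, if `n_perm > 0`, a seeded permutation p-value in
#' the observed direction is computed as well.
#'
#' @inheritParams jonckheere_U
#' @param n_perm Number of permutations for the optional exact-style
#'   p-value (0 = skip).
#' @param seed Optional seed for the permutation draw.
#' @return A `"trend"` object: `U`, `mu0`, `var0`, `z`, `direction` (+1 or
#'   -1), `p_value` (one-sided, observed direction), `signed_p`,
#'   `ties` flag, and `p_perm` when requested.
#' @export
jonckheere_test <- function(h, y, n_perm = 0L, seed = NULL) {
  keep <- !is.na(h) & !is.na(y)
  h <- h[keep]
  y <- y[keep]
  stopifnot(length(h) >= 2)
  n_i <- as.numeric(table(y))
  if (length(n_i) < 2L) stop("need at least two classes with samples")
  n <- sum(n_i)
  mu0 <- (n^2 - sum(n_i^2)) / 4  # = sum_(i<j) N_i N_j / 2
  var0 <- (n^2 * (2 * n + 3) - sum(n_i^2 * (2 * n_i + 3))) / 72
  if (var0 <= 0) stop("degenerate class partition: null variance is zero")
  u <- jonckheere_U(h, y)
  z <- (u - mu0) / sqrt(var0)
  direction <- if (u >= mu0) 1L else -1L
  p <- if (direction > 0) {
    stats::pnorm(z, lower.tail = FALSE)
  } else {
    stats::pnorm(z)
  }
  ties <- anyDuplicated(h) > 0L
  p_perm <- NULL
  if (n_perm > 0L) {
    p_perm <- with_seed(seed, {
      hits <- 0L
      for (i in seq_len(n_perm)) {
        u_star <- jonckheere_U(sample(h), y)
        extreme <- if (direction > 0) u_star >= u else u_star <= u
        hits <- hits + extreme
      }
      (1 + hits) / (n_perm + 1)
    })
  }
  structure(list(
    U = u, mu0 = mu0, var0 = var0, z = z,
    direction = direction, p_value = p, signed_p = direction * p,
    ties = ties, p_perm = p_perm, n = n, class_sizes = n_i
  ), class = "trend")
}

#' @export
print.trend <- function(x, ...) {
  cat(sprintf("Jonckheere trend test: U = %d (null mean %.1f, var %.1f)\n",
              x$U, x$mu0, x$var0))
  cat(sprintf("  z = %.3f, %s trend, one-sided p = %.3g%s\n",
              x$z, if (x$direction > 0) "increasing" else "decreasing",
              x$p_value,
              if (x$ties) " [ties in h: normal approximation flagged]" else ""))
  if (!is.null(x$p_perm)) cat(sprintf("  permutation p = %.3g\n", x$p_perm))
  invisible(x)
}
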