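#' Jaccard similarity between two biclusters' gene sets
#'
#' Similarity is measured on gene sets only: genes are the dominant and far
#' more complex dimension of an expression matrix, and two runs that find
#' the same gene module with slightly different sample cuts should count as
#' the same discovery.
#'
#' @param b1,b2 `"bicluster"` objects (or plain integer vectors of gene
#'   indices).
#' @return `|G1 n G2| / |G1 u G2|`, in \[0, 1\].
#' @export
jaccard_similarity <- function(b1, b2) {
  g1 <- if (inherits(b1, "bicluster")) b1$genes else as.integer(b1)
  g2 <- if (inherits(b2, "bicluster")) b2$genes else as.integer(b2)
  if (length(g1) == 0L && length(g2) == 0L) {
    stop("Jaccard similarity is undefined for two empty gene sets")
  }
  length(intersect(g1, g2)) / length(union(g1, g2))
}

#' Collapse identical biclusters
#'
#' Two biclusters are identical when their (gene set, sample set) pairs
#' match exactly.  Empty or non-converged runs are excluded from the unique
#' list and counted separately, so the multi-start accounting
#' (converged + non-converged + empty = number of initializations) stays
#' intact.
#'
#' @param biclusters List of `"bicluster"` objects.
#' @return List with `unique` (list of biclusters, first occurrence kept),
#'   `multiplicity` (integer vector, same length), and `n_excluded` (runs
#'   that were empty or failed to converge).
#' @export
deduplicate <- function(biclusters) {
  ok <- vapply(biclusters, function(b) b$converged && length(b$genes) > 0L, logical(1))
  excluded <- sum(!ok)
  kept <- biclusters[ok]
  keys <- vapply(kept, function(b) {
    paste(paste(b$genes, collapse = ","), paste(b$samples, collapse = ","), sep = "|")
  }, character(1))
  first <- !duplicated(keys)
  uniq <- kept[first]
  mult <- as.integer(table(factor(keys, levels = keys[first])))
  list(unique = uniq, multiplicity = mult, n_excluded = excluded)
}

#' Group unique biclusters into super-biclusters
#'
#' Builds the 1 - Jaccard dissimilarity matrix over the unique biclusters,
#' runs agglomerative hierarchical clustering, and cuts the tree at
#' dissimilarity `1 - sim_threshold`.  Each resulting group becomes a
#' super-bicluster whose `convergence_count` sums the multiplicities of its
#' members (how many of the random initializations converged into the
#' group); singleton groups are kept.  The prototype of each group is its
#' member covering the most genes (ties: more samples, then higher
#' multiplicity, then smaller `init_id`).
#'
#' @param unique_biclusters List of unique `"bicluster"` objects, e.g.
#'   `deduplicate(...)$unique`.
#' @param multiplicity Integer vector of per-member convergence counts;
#'   defaults to all 1.
#' @param sim_threshold Similarity level at which biclusters are considered
#'   the same discovery; groups are merged while pairwise linkage
#'   dissimilarity is at most `1 - sim_threshold`.
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (`"average"`, `"single"` or `"complete"`).
#' @return List of `"superbicluster"` objects ordered by decreasing
#'   `convergence_count`; each has `members`, `multiplicity`, `prototype`
#'   (a bicluster), `prototype_index`, `convergence_count` and
#'   `prototype_count`.
#' @export
build_superbiclusters <- function(unique_biclusters, multiplicity = NULL,
                                  sim_threshold = 0.5,
                                  linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  n <- length(unique_biclusters)
  if (n < 1L) stop("need at least one unique bicluster")
  if (is.null(multiplicity)) multiplicity <- rep(1L, n)
  stopifnot(length(multiplicity) == n)

  if (n == 1L) {
    groups <- 1L
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        d[i, j] <- d[j, i] <- 1 - jaccard_similarity(unique_biclusters[[i]],
                                                     unique_biclusters[[j]])
      }
    }
    tree <- stats::hclust(stats::as.dist(d), method = linkage)
    groups <- stats::cutree(tree, h = 1 - sim_threshold)
  }

  sbcs <- lapply(sort(unique(groups)), function(gid) {
    idx <- which(groups == gid)
    members <- unique_biclusters[idx]
    mult <- as.integer(multiplicity[idx])
    p <- prototype_index(members, mult)
    structure(list(
      members = members,
      multiplicity = mult,
      prototype = members[[p]],
      prototype_index = p,
      convergence_count = sum(mult),
      prototype_count = mult[p],
      sim_threshold = sim_threshold,
      linkage = linkage
    ), class = "superbicluster")
  })
  ord <- order(vapply(sbcs, `[[`, integer(1), "convergence_count"), decreasing = TRUE)
  sbcs[ord]
}

#' Prototype of a super-bicluster
#'
#' The representative member: the one covering the most genes.  Ties fall
#' through a deterministic ladder: larger sample set, then larger
#' multiplicity, then smaller initialization id.
#'
#' @param sbc A `"superbicluster"` object.
#' @return The prototype `"bicluster"`.
#' @export
select_prototype <- function(sbc) {
  stopifnot(inherits(sbc, "superbicluster"))
  sbc$members[[prototype_index(sbc$members, sbc$multiplicity)]]
}

prototype_index <- function(members, multiplicity) {
  stopifnot(length(members) >= 1L)
  n_g <- vapply(members, function(b) length(b$genes), integer(1))
  n_s <- vapply(members, function(b) length(b$samples), integer(1))
  iid <- vapply(members, function(b) {
    if (is.na(b$init_id)) .Machine$integer.max else b$init_id
  }, integer(1))
  order(-n_g, -n_s, -multiplicity, iid)[1L]
}

#' @export
print.superbicluster <- function(x, ...) {
  cat(sprintf("Super-bicluster: %d member(s), convergence count %d\n",
              length(x$members), x$convergence_count))
  cat(sprintf("  prototype: %d genes x %d samples (reached %d time(s))\n",
              length(x$prototype$genes), length(x$prototype$samples),
              x$prototype_count))
  invisible(x)
}
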