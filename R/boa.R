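#' @title Bi-ordering analysis: score updates and selection rules
#' @description Internal building blocks of the BOA fixed-point iteration.
#'   All four are exported because they define the algorithm's contract and
#'   are useful for inspecting a fit one step at a time.
#' @name boa-steps
NULL

#' @describeIn boa-steps Mean expression of every gene over a sample subset.
#'   Scores all genes, not only current members: this is what induces the
#'   full gene ordering.
#' @param x Normalized expression matrix (genes x samples).
#' @param samples Nonempty integer vector of sample (column) indices.
#' @export
gene_scores <- function(x, samples) {
  if (length(samples) == 0L) stop("empty sample set: iteration collapsed")
  rowMeans(x[, samples, drop = FALSE])
}

#' @describeIn boa-steps Mean expression of every sample over a gene subset.
#' @param genes Nonempty integer vector of gene (row) indices.
#' @export
sample_scores <- function(x, genes) {
  if (length(genes) == 0L) stop("empty gene set: iteration collapsed")
  colMeans(x[genes, , drop = FALSE])
}

## Threshold denominator d(n).  The selection rule compares centred scores
## against theta / d(n).  "sqrt" (default) scales the cut-off like the
## standard error of a mean of n unit-variance values; "linear" divides by
## n itself.  Both are offered because either convention appears in the
## iterative-signature literature; the choice is recorded in every fit.
denom_fun <- function(denominator = c("sqrt", "linear")) {
  denominator <- match.arg(denominator)
  if (denominator == "sqrt") sqrt else identity
}

#' @describeIn boa-steps Genes whose centred score strictly exceeds
#'   `theta_g / d(s_size)` (for `mode = "over"`; the mirrored rule, score
#'   below `-theta_g / d(s_size)`, for `mode = "under"`).
#' @param f Numeric gene score vector (all genes).
#' @param theta_g,theta_s Positive cut-off thresholds.
#' @param s_size,g_size Size of the sample (gene) set the scores were
#'   computed over; enters the threshold denominator.
#' @param denominator `"sqrt"` (default) or `"linear"`; the function `d`
#'   applied to the set size in the threshold `theta / d(n)`.
#' @param mode `"over"` selects high scores, `"under"` low scores.
#' @export
select_genes <- function(f, theta_g, s_size,
                         denominator = c("sqrt", "linear"),
                         mode = c("over", "under")) {
  mode <- match.arg(mode)
  stopifnot(s_size >= 1, theta_g > 0)
  d <- denom_fun(denominator)
  ctr <- f - mean(f)
  cut <- theta_g / d(s_size)
  unname(which(if (mode == "over") ctr > cut else ctr < -cut))
}

#' @describeIn boa-steps Sample counterpart of [select_genes()].
#' @param h Numeric sample score vector (all samples).
#' @export
select_samples <- function(h, theta_s, g_size,
                           denominator = c("sqrt", "linear"),
                           mode = c("over", "under")) {
  mode <- match.arg(mode)
  stopifnot(g_size >= 1, theta_s > 0)
  d <- denom_fun(denominator)
  ctr <- h - mean(h)
  cut <- theta_s / d(g_size)
  unname(which(if (mode == "over") ctr > cut else ctr < -cut))
}

#' Fit a single bicluster by the BOA fixed-point iteration
#'
#' Starting from an initial sample subset, alternately (a) scores every gene
#' by its mean expression over the current samples, (b) keeps the genes whose
#' centred score exceeds `theta_g / d(|S|)`, (c) scores every sample over the
#' kept genes, and (d) keeps the samples whose centred score exceeds
#' `theta_s / d(|G|)`, until both sets are identical to the previous
#' iteration.  `mode = "under"` mirrors both selection rules to find
#' down-regulated blocks.  The iteration is fully deterministic given the
#' matrix, the initial subset and the thresholds.
#'
#' If either set becomes empty the run is abandoned and an empty,
#' non-converged bicluster is returned (the protocol runner logs these and
#' moves on to the next initialization).
#'
#' @param x Normalized expression matrix (see [normalize_matrix()]).
#' @param init Initial sample subset: integer column indices or sample names.
#' @param theta_g,theta_s Positive thresholds for gene/sample selection.
#' @param mode `"over"` (default) or `"under"`.
#' @param denominator `"sqrt"` (default) or `"linear"` threshold scaling;
#'   see [select_genes()].
#' @param max_iter Iteration cap; in practice convergence takes well under
#'   ten iterations.
#' @param check One of `"warn"`, `"error"`, `"none"`: what to do when the
#'   input does not look normalized (column centres far from 0 or column
#'   scale far from 1).
#' @param init_id Optional integer tag recording which initialization
#'   produced this fit.
#' @return An object of class `"bicluster"`: a list with the member index
#'   vectors `genes` and `samples`, full score vectors `gene_scores` and
#'   `sample_scores` (the bi-ordering), the thresholds, `iterations`,
#'   `converged`, a `status` string, and the gene/sample identifiers.
#' @seealso [boa_fixed()] for the fixed-size variant, [bea()] for the
#'   multi-start protocol.
#' @examples
#' x <- matrix(rnorm(2000), 100, 20)
#' x[1:10, 1:5] <- x[1:10, 1:5] + 4
#' xn <- normalize_matrix(x)
#' boa(xn, init = 1:5, theta_g = 3, theta_s = 2)
#' @export
boa <- function(x, init, theta_g, theta_s,
                mode = c("over", "under"),
                denominator = c("sqrt", "linear"),
                max_iter = 100L, check = c("warn", "error", "none"),
                init_id = NA_integer_) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  check <- match.arg(check)
  x <- as_expression_matrix(x)
  check_normalized(x, action = check)
  s <- resolve_samples(x, init)
  if (length(s) == 0L) stop("initial sample subset must be nonempty")

  g_prev <- NULL
  s_prev <- s
  f <- h <- NULL
  converged <- FALSE
  status <- "max_iter"
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    f <- gene_scores(x, s)
    g <- select_genes(f, theta_g, length(s), denominator, mode)
    if (length(g) == 0L) {
      return(empty_bicluster(x, theta_g, theta_s, mode, denominator, iter, init_id, s0 = resolve_samples(x, init)))
    }
    h <- sample_scores(x, g)
    s_new <- select_samples(h, theta_s, length(g), denominator, mode)
    if (length(s_new) == 0L) {
      return(empty_bicluster(x, theta_g, theta_s, mode, denominator, iter, init_id, s0 = resolve_samples(x, init)))
    }
    if (!is.null(g_prev) && identical(g, g_prev) && identical(s_new, s_prev)) {
      converged <- TRUE
      status <- "converged"
      s <- s_new
      g_prev <- g
      break
    }
    g_prev <- g
    s_prev <- s_new
    s <- s_new
  }

  new_bicluster(
    genes = g_prev, samples = s, gene_scores = f, sample_scores = h,
    theta_g = theta_g, theta_s = theta_s, mode = mode,
    denominator = denominator, variant = "threshold",
    iterations = iter, converged = converged, status = status,
    init = resolve_samples(x, init), init_id = init_id,
    gene_ids = rownames(x), sample_ids = colnames(x)
  )
}

#' Fixed-size variant of the BOA iteration
#'
#' Replaces the threshold selections by rank selections: keep the `k_g`
#' genes with the largest scores and the `k_s` samples with the largest
#' scores (smallest, for `mode = "under"`).  The mean of the selected
#' submatrix is non-decreasing over iterations (non-increasing for
#' `"under"`), so the iteration always terminates in a fixed point or, under
#' exact score ties, a 2-cycle; a detected 2-cycle stops the run and returns
#' the state with the better submatrix mean.  Rank ties are broken towards
#' the lower index so the fit is deterministic.
#'
#' @inheritParams boa
#' @param k_g,k_s Number of genes / samples to keep each iteration
#'   (`1 <= k_g <= nrow(x)`, `1 <= k_s <= ncol(x)`).
#' @return A `"bicluster"` object (see [boa()]); additionally carries
#'   `objective`, the per-iteration submatrix means.
#' @export
boa_fixed <- function(x, init, k_g, k_s,
                      mode = c("over", "under"),
                      max_iter = 100L, check = c("warn", "error", "none"),
                      init_id = NA_integer_) {
  mode <- match.arg(mode)
  check <- match.arg(check)
  x <- as_expression_matrix(x)
  check_normalized(x, action = check)
  stopifnot(k_g >= 1, k_g <= nrow(x), k_s >= 1, k_s <= ncol(x))
  s <- resolve_samples(x, init)
  if (length(s) == 0L) stop("initial sample subset must be nonempty")

  take_top <- function(v, k) {
    ord <- if (mode == "over") order(-v, seq_along(v)) else order(v, seq_along(v))
    sort(ord[seq_len(k)])
  }

  states <- list()  # last two (G, S) states for cycle detection
  means <- numeric(0)
  f <- h <- NULL
  g <- integer(0)
  converged <- FALSE
  status <- "max_iter"
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    f <- gene_scores(x, s)
    g <- take_top(f, k_g)
    h <- sample_scores(x, g)
    s <- take_top(h, k_s)
    means <- c(means, mean(x[g, s]))
    state <- list(g = g, s = s)
    n <- length(states)
    if (n >= 1L && identical(state, states[[n]])) {
      converged <- TRUE
      status <- "converged"
      break
    }
    if (n >= 2L && identical(state, states[[n - 1L]])) {
      ## 2-cycle under exact ties: keep the better of the two states
      status <- "cycle"
      prev <- states[[n]]
      m_prev <- mean(x[prev$g, prev$s])
      m_cur <- means[length(means)]
      better <- if (mode == "over") m_prev > m_cur else m_prev < m_cur
      if (better) {
        g <- prev$g
        s <- prev$s
        f <- gene_scores(x, s)   # rescore so the stored ordering matches
        h <- sample_scores(x, g)
      }
      break
    }
    states <- c(if (n >= 1L) states[n] else list(), list(state))
  }

  out <- new_bicluster(
    genes = g, samples = s, gene_scores = f, sample_scores = h,
    theta_g = NA_real_, theta_s = NA_real_, mode = mode,
    denominator = NA_character_, variant = "fixed",
    iterations = iter, converged = converged, status = status,
    init = resolve_samples(x, init), init_id = init_id,
    gene_ids = rownames(x), sample_ids = colnames(x)
  )
  out$k_g <- k_g
  out$k_s <- k_s
  out$objective <- means
  out
}

#' Random initial sample subsets for the multi-start protocol
#'
#' Draws `n_init` independent subsets of `1:n_s`; each sample enters a
#' subset with probability `p_include`.  Empty draws are redrawn.  The whole
#' list is generated up-front under one seed, so downstream runs do not
#' depend on execution order; the caller's RNG state is left untouched.
#'
#' @param n_s Number of samples.
#' @param n_init Number of subsets to draw.
#' @param p_include Per-sample inclusion probability, in (0, 1).
#' @param seed Optional integer seed for reproducibility.
#' @return List of `n_init` sorted nonempty integer vectors.
#' @export
random_initializations <- function(n_s, n_init = 1000L, p_include = 0.2, seed = NULL) {
  stopifnot(n_s >= 1, n_init >= 1, p_include > 0, p_include < 1)
  with_seed(seed, {
    lapply(seq_len(n_init), function(i) {
      repeat {
        keep <- which(stats::runif(n_s) < p_include)
        if (length(keep) > 0L) return(keep)
      }
    })
  })
}

## Evaluate code under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

resolve_samples <- function(x, init) {
  if (is.character(init)) {
    idx <- match(init, colnames(x))
    if (anyNA(idx)) stop("unknown sample identifiers: ",
                         paste(init[is.na(idx)], collapse = ", "))
    sort(idx)
  } else {
    init <- as.integer(init)
    if (any(init < 1L | init > ncol(x))) stop("sample indices out of range")
    sort(unique(init))
  }
}

## Cheap sanity check that x went through normalize_matrix(): the second
## pass leaves every column centred at 0 with unit scale, so far-off column
## summaries indicate raw data.
check_normalized <- function(x, action = "warn", tol = 0.5) {
  if (action == "none") return(invisible(TRUE))
  cols <- seq_len(min(ncol(x), 50L))
  med <- apply(x[, cols, drop = FALSE], 2L, stats::median)
  mu <- colMeans(x[, cols, drop = FALSE])
  s <- apply(x[, cols, drop = FALSE], 2L, sd_pop)
  centred <- min(max(abs(med)), max(abs(mu))) < tol
  scaled <- all(s > tol & s < 1 / tol + 1.5)
  if (!centred || !scaled) {
    msg <- "input does not look normalized; run normalize_matrix() first"
    if (action == "error") stop(msg) else warning(msg)
  }
  invisible(TRUE)
}

new_bicluster <- function(genes, samples, gene_scores, sample_scores,
                          theta_g, theta_s, mode, denominator, variant,
                          iterations, converged, status, init, init_id,
                          gene_ids = NULL, sample_ids = NULL) {
  structure(list(
    genes = as.integer(genes),
    samples = as.integer(samples),
    gene_scores = gene_scores,
    sample_scores = sample_scores,
    theta_g = theta_g, theta_s = theta_s,
    mode = mode, denominator = denominator, variant = variant,
    iterations = as.integer(iterations),
    converged = isTRUE(converged),
    status = status,
    init = as.integer(init),
    init_id = as.integer(init_id),
    gene_ids = gene_ids,
    sample_ids = sample_ids
  ), class = "bicluster")
}

empty_bicluster <- function(x, theta_g, theta_s, mode, denominator,
                            iterations, init_id, s0) {
  new_bicluster(
    genes = integer(0), samples = integer(0),
    gene_scores = NULL, sample_scores = NULL,
    theta_g = theta_g, theta_s = theta_s, mode = mode,
    denominator = denominator, variant = "threshold",
    iterations = iterations, converged = FALSE, status = "empty",
    init = s0, init_id = init_id,
    gene_ids = rownames(x), sample_ids = colnames(x)
  )
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("BOA bicluster (%s variant, mode = %s)\n", x$variant, x$mode))
  if (x$variant == "threshold") {
    cat(sprintf("  thresholds: theta_g = %.3g, theta_s = %.3g (denominator: %s)\n",
                x$theta_g, x$theta_s, x$denominator))
  } else {
    cat(sprintf("  fixed sizes: k_g = %d, k_s = %d\n", x$k_g, x$k_s))
  }
  cat(sprintf("  %d genes x %d samples; %d iteration(s); status: %s\n",
              length(x$genes), length(x$samples), x$iterations, x$status))
  invisible(x)
}

#' Member identifiers of a bicluster
#'
#' @param b A `"bicluster"` object.
#' @return List with character (or integer, if the matrix had no dimnames)
#'   vectors `genes` and `samples`.
#' @export
bicluster_members <- function(b) {
  stopifnot(inherits(b, "bicluster"))
  list(
    genes = if (is.null(b$gene_ids)) b$genes else b$gene_ids[b$genes],
    samples = if (is.null(b$sample_ids)) b$samples else b$sample_ids[b$samples]
  )
}
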