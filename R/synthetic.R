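#' Design of a synthetic expression matrix with planted biclusters
#'
#' Describes a gene x sample matrix of i.i.d. Gaussian noise with
#' constant-shift blocks planted on chosen gene/sample subsets, plus a
#' categorical class structure over the samples with an ordinal score per
#' class.  The default emulates the shape of a gastric-tissue microarray
#' study: 124 samples in six phenotype classes of sizes 10 (normal),
#' 26 (CG), 22 (IM), 35 (DGC), 22 (IGC) and 7 (MGC) plus two unannotated
#' singletons, with an ordinal malignancy score of 1 for normal, 2 for CG,
#' 3 for IM and 4 for any cancer class; the gene dimension defaults to
#' 1500 rows (the study's ~7400 genes scaled down five-fold so the whole
#' protocol runs at desk scale).
#'
#' Classes are laid out contiguously over the sample indices (unannotated
#' samples last), and each planted block's sample set is, by construction,
#' taken from inside a chosen class group: `purity` controls the fraction
#' of block samples drawn from the target classes, the remainder coming
#' from the complement.  This plants exactly the class-saturation structure
#' the analysis is meant to detect.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param class_sizes Named integer vector of class sizes; must sum to at
#'   most `n_samples` (the remainder is left unannotated).
#' @param ordinal Named numeric vector mapping each class to an ordinal
#'   score; defaults to the malignancy-style 1/2/3/4 map when the default
#'   classes are used.
#' @param blocks List of blocks, each a list with `genes` (integer vector),
#'   `n_samples` or `samples`, `classes` (target class names, used when
#'   `samples` is not given), `shift` (positive effect size, in noise SD
#'   units) and `sign` (+1 over-expressed, -1 under-expressed).  `NULL`
#'   gives a three-block default covering over- and under-expression.
#' @param noise_sd Standard deviation of the Gaussian background.
#' @param purity Fraction (0-1] of each block's samples taken from its
#'   target classes.
#' @param df If finite, background noise is drawn from a scaled Student t
#'   with this many degrees of freedom instead of a Gaussian (heavier
#'   tails, for robustness experiments).
#' @return A `"planted_design"` list; pass to [generate_matrix()].
#' @export
planted_design <- function(n_genes = 1500L, n_samples = 124L,
                           class_sizes = c(normal = 10L, CG = 26L, IM = 22L,
                                           DGC = 35L, IGC = 22L, MGC = 7L),
                           ordinal = NULL,
                           blocks = NULL,
                           noise_sd = 1, purity = 1, df = Inf) {
  stopifnot(n_genes >= 1, n_samples >= 1, noise_sd > 0,
            purity > 0, purity <= 1)
  if (sum(class_sizes) > n_samples) stop("class sizes exceed the number of samples")
  if (is.null(names(class_sizes))) {
    names(class_sizes) <- paste0("C", seq_along(class_sizes))
  }
  if (is.null(ordinal)) {
    ordinal <- if (identical(names(class_sizes),
                             c("normal", "CG", "IM", "DGC", "IGC", "MGC"))) {
      c(normal = 1, CG = 2, IM = 3, DGC = 4, IGC = 4, MGC = 4)
    } else {
      stats::setNames(seq_along(class_sizes), names(class_sizes))
    }
  }
  ## contiguous class layout; unannotated samples take the trailing indices
  labels <- rep(NA_character_, n_samples)
  labels[seq_len(sum(class_sizes))] <- rep(names(class_sizes), class_sizes)

  if (is.null(blocks)) {
    ## block gene coordinates scale with the gene dimension
    ## (1:50, 301:400, 701:760 at the default 1500 genes)
    seg <- function(frac, len) {
      start <- round(n_genes * frac)
      seq.int(start + 1L, min(start + len, n_genes))
    }
    blocks <- list(
      list(genes = seg(0, max(10L, round(n_genes / 30))),
           n_samples = 20L, classes = c("normal", "CG"), shift = 2, sign = 1L),
      list(genes = seg(0.2, max(20L, round(n_genes / 15))),
           n_samples = 25L, classes = "DGC", shift = 1.5, sign = 1L),
      list(genes = seg(0.467, max(12L, round(n_genes / 25))),
           n_samples = 18L, classes = "IM", shift = 2.5, sign = -1L)
    )
  }
  blocks <- lapply(blocks, function(b) {
    b$sign <- if (is.null(b$sign)) 1L else as.integer(sign(b$sign))
    stopifnot(b$shift > 0, b$sign %in% c(-1L, 1L),
              all(b$genes >= 1), all(b$genes <= n_genes))
    if (is.null(b$samples)) {
      stopifnot(!is.null(b$n_samples), !is.null(b$classes))
      pool <- which(labels %in% b$classes)
      other <- setdiff(which(!is.na(labels)), pool)
      n_in <- min(round(purity * b$n_samples), length(pool))
      n_out <- b$n_samples - n_in
      if (n_out > length(other)) stop("block larger than the available samples")
      b$samples <- sort(c(pool[seq_len(n_in)], other[seq_len(n_out)]))
    }
    stopifnot(all(b$samples >= 1), all(b$samples <= n_samples))
    b$samples <- sort(unique(as.integer(b$samples)))
    b$genes <- sort(unique(as.integer(b$genes)))
    b
  })

  structure(list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    class_sizes = class_sizes, ordinal = ordinal, labels = labels,
    blocks = blocks, noise_sd = noise_sd, purity = purity, df = df
  ), class = "planted_design")
}

#' Generate a synthetic expression matrix from a planted design
#'
#' Draws the i.i.d. noise background, adds `sign * shift` on every planted
#' block (overlapping blocks add their shifts), and assembles the sample
#' annotation table.  Identical design and seed give a bitwise-identical
#' matrix; the caller's RNG state is untouched.
#'
#' @param design A [planted_design()].
#' @param seed Integer seed.
#' @return List with `x` (the matrix, dimnames `g1..`/`s1..`), `truth`
#'   (the design's block list), and `annotation` (a [sample_annotation()]
#'   with the ordinal score).
#' @export
generate_matrix <- function(design, seed = 1L) {
  stopifnot(inherits(design, "planted_design"))
  x <- with_seed(seed, {
    n <- design$n_genes * design$n_samples
    noise <- if (is.finite(design$df)) {
      stats::rt(n, df = design$df) * sqrt((design$df - 2) / design$df)
    } else {
      stats::rnorm(n)
    }
    matrix(noise * design$noise_sd, design$n_genes, design$n_samples)
  })
  for (b in design$blocks) {
    x[b$genes, b$samples] <- x[b$genes, b$samples] + b$sign * b$shift
  }
  dimnames(x) <- list(paste0("g", seq_len(design$n_genes)),
                      paste0("s", seq_len(design$n_samples)))
  ann <- sample_annotation(
    sample_id = colnames(x),
    class = design$labels,
    score = unname(design$ordinal[design$labels])
  )
  list(x = x, truth = design$blocks, annotation = ann)
}

#' Recovery of a planted block by a fitted bicluster
#'
#' @param found A `"bicluster"`.
#' @param truth_block One element of a design's `blocks` list (or any list
#'   with integer `genes` and `samples`).
#' @return Named numeric vector: Jaccard overlap on genes and on samples.
#' @export
recovery_score <- function(found, truth_block) {
  stopifnot(inherits(found, "bicluster"))
  jac <- function(a, b) {
    if (length(a) == 0L && length(b) == 0L) return(NA_real_)
    length(intersect(a, b)) / length(union(a, b))
  }
  c(gene_jaccard = jac(found$genes, truth_block$genes),
    sample_jaccard = jac(found$samples, truth_block$samples))
}
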