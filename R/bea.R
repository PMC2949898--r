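#' Bi-ordering exploratory analysis of an expression matrix
#'
#' The end-to-end multi-start protocol: normalize the matrix (two-pass
#' median/std standardization), run the BOA fixed-point iteration from
#' `n_init` random initial sample subsets, collapse identical results,
#' group the unique biclusters into super-biclusters by gene-set Jaccard
#' similarity, pick a prototype per group, and — when sample annotations
#' are supplied — attach the statistical figures of merit to every
#' prototype: the single- and multiple-class saturation p-values and the
#' Jonckheere trend test of the prototype's sample ordering against the
#' ordinal score.
#'
#' @param x Gene x sample expression matrix (raw; see `normalize`).
#' @param annotation Optional [sample_annotation()] covering the samples.
#' @param theta_g,theta_s Positive selection thresholds of the BOA
#'   iteration.
#' @param mode `"over"` (default) or `"under"` expression.
#' @param denominator `"sqrt"` (default) or `"linear"` threshold scaling.
#' @param n_init Number of random initializations.
#' @param p_include Per-sample inclusion probability of an initialization.
#' @param seed Seed for the initialization draw.
#' @param sim_threshold Gene-set Jaccard level at which two biclusters are
#'   grouped into the same super-bicluster.
#' @param linkage Agglomeration method for the grouping.
#' @param max_iter Iteration cap per BOA run.
#' @param normalize Set to `FALSE` when `x` is already normalized.
#' @param center Location statistic of the normalization passes.
#' @param keep_runs Keep the full list of per-initialization fits (memory
#'   permitting) instead of only the deduplicated ones.
#' @return An object of class `"bea"` with the normalized matrix (`x`),
#'   the unique biclusters and multiplicities, the super-bicluster list,
#'   a per-SBC `report` data frame (ordered by convergence count), the
#'   run accounting and a reproducibility `manifest`.
#' @examples
#' des <- planted_design(n_genes = 300, n_samples = 60,
#'                       class_sizes = c(A = 20, B = 20, C = 20),
#'                       blocks = list(list(genes = 1:30, n_samples = 15,
#'                                          classes = "A", shift = 3)))
#' sim <- generate_matrix(des, seed = 7)
#' fit <- bea(sim$x, sim$annotation, theta_g = 3, theta_s = 2.5,
#'            n_init = 50, seed = 7)
#' fit
#' @export
bea <- function(x, annotation = NULL,
                theta_g = 5, theta_s = 4.5,
                mode = c("over", "under"),
                denominator = c("sqrt", "linear"),
                n_init = 1000L, p_include = 0.2, seed = 1L,
                sim_threshold = 0.5,
                linkage = c("average", "single", "complete"),
                max_iter = 100L,
                normalize = TRUE, center = c("median", "mean"),
                keep_runs = FALSE) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  linkage <- match.arg(linkage)
  center <- match.arg(center)
  x <- as_expression_matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  raw_fp <- fingerprint(x)
  if (!is.null(annotation)) {
    stopifnot(inherits(annotation, "sample_annotation"))
    unknown <- setdiff(annotation$sample_id, colnames(x))
    if (length(unknown) > 0L) {
      stop("annotation references samples absent from the matrix: ",
           paste(utils::head(unknown, 10L), collapse = ", "))
    }
  }
  xn <- if (normalize) normalize_matrix(x, center) else x

  inits <- random_initializations(ncol(xn), n_init, p_include, seed)
  runs <- lapply(seq_len(n_init), function(i) {
    boa(xn, inits[[i]], theta_g, theta_s, mode = mode,
        denominator = denominator, max_iter = max_iter,
        check = "none", init_id = i)
  })
  iter_counts <- vapply(runs, `[[`, integer(1), "iterations")
  dd <- deduplicate(runs)

  sbcs <- if (length(dd$unique) > 0L) {
    build_superbiclusters(dd$unique, dd$multiplicity,
                          sim_threshold = sim_threshold, linkage = linkage)
  } else {
    list()
  }

  parameters <- list(
    theta_g = theta_g, theta_s = theta_s, mode = mode,
    denominator = denominator, n_init = as.integer(n_init),
    p_include = p_include, seed = as.integer(seed),
    sim_threshold = sim_threshold, linkage = linkage,
    max_iter = as.integer(max_iter), normalize = normalize, center = center
  )
  manifest <- list(
    package = "biorder",
    version = as.character(utils::packageVersion("biorder")),
    parameters = parameters,
    input = list(n_genes = nrow(x), n_samples = ncol(x), digest = raw_fp),
    accounting = list(
      n_init = as.integer(n_init),
      n_converged = sum(dd$multiplicity),
      n_excluded = dd$n_excluded,
      n_unique = length(dd$unique),
      n_superbiclusters = length(sbcs),
      iterations = as.vector(table(factor(iter_counts,
                                          levels = seq_len(max(iter_counts)))))
    )
  )

  fit <- structure(list(
    x = xn,
    annotation = annotation,
    parameters = parameters,
    initializations = inits,
    runs = if (keep_runs) runs else NULL,
    unique = dd$unique,
    multiplicity = dd$multiplicity,
    n_excluded = dd$n_excluded,
    superbiclusters = sbcs,
    manifest = manifest,
    call = match.call()
  ), class = "bea")
  fit$report <- sbc_report(fit)
  fit
}

#' Table-style report over super-bicluster prototypes
#'
#' One row per super-bicluster, ordered by convergence count: member and
#' prototype counts, prototype dimensions, and — when annotations are
#' available — the SCS and MCS saturation p-values with their winning
#' class subsets and the signed one-sided Jonckheere trend p-value of the
#' prototype's sample ordering against the ordinal score.
#'
#' @param fit A `"bea"` object.
#' @return A data frame.
#' @export
sbc_report <- function(fit) {
  stopifnot(inherits(fit, "bea"))
  sbcs <- fit$superbiclusters
  if (length(sbcs) == 0L) return(data.frame())
  ann <- fit$annotation
  rows <- lapply(seq_along(sbcs), function(i) {
    sb <- sbcs[[i]]
    p <- sb$prototype
    row <- data.frame(
      sbc = paste0("SBC", i),
      n_members = length(sb$members),
      convergence_count = sb$convergence_count,
      prototype_count = sb$prototype_count,
      n_genes = length(p$genes),
      n_samples = length(p$samples),
      stringsAsFactors = FALSE
    )
    if (!is.null(ann)) {
      scs <- scs_pvalue(p, ann)
      mcs <- mcs_pvalue(p, ann)
      row$scs_class <- paste(scs$class_subset, collapse = "+")
      row$scs_p <- scs$p_value
      row$mcs_classes <- paste(mcs$class_subset, collapse = "+")
      row$mcs_p <- mcs$p_value
      if (!is.null(ann$score)) {
        idx <- match(ann$sample_id, p$sample_ids)
        tr <- jonckheere_test(p$sample_scores[idx], ann$score)
        row$trend_signed_p <- tr$signed_p
        row$trend_z <- tr$z
      }
    }
    row
  })
  do.call(rbind, rows)
}

#' @export
print.bea <- function(x, ...) {
  acc <- x$manifest$accounting
  cat("Bi-ordering exploratory analysis\n")
  cat(sprintf("  matrix: %d genes x %d samples (normalized: %s, center = %s)\n",
              nrow(x$x), ncol(x$x), x$parameters$normalize, x$parameters$center))
  cat(sprintf("  BOA: theta_g = %.3g, theta_s = %.3g, mode = %s, denominator = %s\n",
              x$parameters$theta_g, x$parameters$theta_s,
              x$parameters$mode, x$parameters$denominator))
  cat(sprintf("  %d initializations (p = %.2g, seed = %d): %d converged, %d empty/non-converged\n",
              acc$n_init, x$parameters$p_include, x$parameters$seed,
              acc$n_converged, acc$n_excluded))
  cat(sprintf("  %d unique bicluster(s) -> %d super-bicluster(s) at Jaccard >= %.2g (%s linkage)\n",
              acc$n_unique, acc$n_superbiclusters,
              x$parameters$sim_threshold, x$parameters$linkage))
  invisible(x)
}

#' @export
summary.bea <- function(object, ...) {
  structure(list(report = object$report,
                 accounting = object$manifest$accounting),
            class = "summary.bea")
}

#' @export
print.summary.bea <- function(x, ...) {
  cat("Super-bicluster report (ordered by convergence count)\n")
  if (nrow(x$report) == 0L) {
    cat("  no converged biclusters\n")
  } else {
    df <- x$report
    for (col in intersect(c("scs_p", "mcs_p", "trend_signed_p", "trend_z"),
                          colnames(df))) {
      df[[col]] <- signif(df[[col]], 3)
    }
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Heat map of a super-bicluster prototype
#'
#' Draws the prototype's genes (ordered by gene score) against all samples
#' (ordered by sample score), with a line marking the bicluster boundary
#' on the sample axis — the standard way to display a bi-ordering: the
#' member block sits in the top-left corner and the score ordering shows
#' how sharply it separates from the rest of the matrix.
#'
#' @param x A `"bea"` object.
#' @param which Index of the super-bicluster to draw (default 1, the most
#'   stable one).
#' @param col Color palette for [graphics::image()].
#' @param ... Unused.
#' @export
plot.bea <- function(x, which = 1L, col = grDevices::hcl.colors(31, "RdBu", rev = TRUE), ...) {
  stopifnot(which >= 1L, which <= length(x$superbiclusters))
  p <- x$superbiclusters[[which]]$prototype
  g_ord <- p$genes[order(p$gene_scores[p$genes], decreasing = TRUE)]
  s_ord <- order(p$sample_scores, decreasing = TRUE)
  m <- x$x[g_ord, s_ord, drop = FALSE]
  lim <- max(abs(m))
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)),
                  t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  zlim = c(-lim, lim), col = col,
                  xlab = "samples (ordered by h)", ylab = "genes (ordered by f)",
                  main = sprintf("SBC%d prototype: %d genes x %d samples",
                                 which, length(p$genes), length(p$samples)),
                  axes = FALSE)
  graphics::abline(v = length(p$samples) + 0.5, lwd = 2, col = "yellow")
  graphics::box()
  invisible(x)
}

#' Run the full protocol and serialize every stage
#'
#' Convenience wrapper around [bea()] that writes the stage outputs to a
#' directory: `biclusters.json` (unique biclusters with multiplicities),
#' `sbcs.json` (super-bicluster groups with prototypes), `report.tsv`
#' (the per-SBC table) and `manifest.json` (all parameters, input digest
#' and run accounting — enough to reproduce every output bitwise).
#'
#' @param x Expression matrix (or path to a matrix TSV).
#' @param annotation Optional [sample_annotation()] (or path to a TSV).
#' @param out_dir Output directory, created if needed.
#' @param ... Passed to [bea()].
#' @return The `"bea"` fit, invisibly.
#' @export
run_protocol <- function(x, annotation = NULL, out_dir, ...) {
  if (is.character(x) && length(x) == 1L) x <- read_matrix(x)
  if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- read_annotations(annotation, x)
  }
  fit <- bea(x, annotation, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_biclusters(fit, file.path(out_dir, "biclusters.json"))
  write_sbcs(fit, file.path(out_dir, "sbcs.json"))
  utils::write.table(fit$report, file.path(out_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fit$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fit)
}

#' Write the super-bicluster groups of a fit to JSON
#'
#' @param fit A `"bea"` object.
#' @param path Output path.
#' @export
write_sbcs <- function(fit, path) {
  stopifnot(inherits(fit, "bea"))
  payload <- list(
    sim_threshold = fit$parameters$sim_threshold,
    linkage = fit$parameters$linkage,
    superbiclusters = lapply(seq_along(fit$superbiclusters), function(i) {
      sb <- fit$superbiclusters[[i]]
      list(
        id = paste0("SBC", i),
        convergence_count = sb$convergence_count,
        prototype_count = sb$prototype_count,
        prototype = bicluster_to_json(sb$prototype),
        members = mapply(bicluster_to_json, sb$members, sb$multiplicity,
                         SIMPLIFY = FALSE)
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
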