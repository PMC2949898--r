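#' Read a gene x sample expression matrix from TSV
#'
#' Expects gene identifiers in the first column and sample identifiers as
#' the header; all remaining cells numeric.  Duplicate identifiers and
#' non-numeric cells are reported by name.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix with gene row names and sample column names.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix file needs a gene-id column plus at least one sample")
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers in ", path, ": ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 5L), collapse = ", "))
  }
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers in ", path, ": ",
         paste(utils::head(unique(sample_ids[duplicated(sample_ids)]), 5L), collapse = ", "))
  }
  vals <- df[-1L]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric expression values in column(s): ",
         paste(utils::head(sample_ids[bad], 5L), collapse = ", "))
  }
  x <- as.matrix(vals)
  dimnames(x) <- list(gene_ids, sample_ids)
  as_expression_matrix(x)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_matrix()]: gene ids in the first column (`gene_id`),
#' samples as header columns.
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix <- function(x, path) {
  x <- as_expression_matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table from TSV
#'
#' Columns: `sample_id`, `class`, and optionally `score` (an ordinal
#' annotation such as a malignancy grade).  Empty class fields become `NA`
#' (unannotated samples, excluded from the statistics).
#'
#' @param path Path to a tab-separated file.
#' @param x Optional expression matrix; when given, every annotated sample
#'   must exist among its columns, and offenders are listed otherwise.
#' @return A [sample_annotation()] data frame.
#' @export
read_annotations <- function(path, x = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("sample_id", "class")
  if (!all(need %in% colnames(df))) {
    stop("annotation file must have columns 'sample_id' and 'class'")
  }
  ann <- sample_annotation(df$sample_id, df$class,
                           score = if ("score" %in% colnames(df)) df$score)
  if (!is.null(x)) {
    unknown <- setdiff(ann$sample_id, colnames(x))
    if (length(unknown) > 0L) {
      stop("annotation references samples absent from the matrix: ",
           paste(utils::head(unknown, 10L), collapse = ", "))
    }
  }
  ann
}

#' Write a sample annotation table to TSV
#'
#' @param ann A [sample_annotation()] data frame.
#' @param path Output path.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

## Deterministic content fingerprint for the run manifest (no wall-clock
## state, so reruns of the same inputs are byte-identical).
fingerprint <- function(x) {
  sprintf("%dx%d:%.10e:%.10e:%.10e", nrow(x), ncol(x),
          sum(x), min(x), max(x))
}

bicluster_to_json <- function(b, multiplicity = NULL) {
  ids <- bicluster_members(b)
  out <- list(
    genes = as.vector(ids$genes),
    samples = as.vector(ids$samples),
    gene_scores = unname(b$gene_scores),
    sample_scores = unname(b$sample_scores),
    mode = b$mode, variant = b$variant,
    iterations = b$iterations, converged = b$converged, status = b$status,
    init_id = b$init_id
  )
  if (b$variant == "threshold") {
    out$theta_g <- b$theta_g
    out$theta_s <- b$theta_s
    out$denominator <- b$denominator
  } else {
    out$k_g <- b$k_g
    out$k_s <- b$k_s
  }
  if (!is.null(multiplicity)) out$multiplicity <- multiplicity
  out
}

#' Write the unique biclusters of a fit to JSON
#'
#' The file carries the gene/sample identifier universes plus one record
#' per unique bicluster (member ids, full score vectors, thresholds,
#' provenance, multiplicity), so it can be read back with
#' [read_biclusters()].
#'
#' @param fit A `"bea"` object.
#' @param path Output path.
#' @export
write_biclusters <- function(fit, path) {
  stopifnot(inherits(fit, "bea"))
  payload <- list(
    gene_ids = rownames(fit$x),
    sample_ids = colnames(fit$x),
    parameters = fit$parameters,
    n_excluded = fit$n_excluded,
    biclusters = mapply(bicluster_to_json, fit$unique, fit$multiplicity,
                        SIMPLIFY = FALSE)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read biclusters back from the JSON written by [write_biclusters()]
#'
#' @param path Path to a biclusters JSON file.
#' @return List with `biclusters` (list of `"bicluster"` objects),
#'   `multiplicity`, `n_excluded`, `gene_ids`, `sample_ids`,
#'   and `parameters`.
#' @export
read_biclusters <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  gene_ids <- payload$gene_ids
  sample_ids <- payload$sample_ids
  bcs <- lapply(payload$biclusters, function(rec) {
    b <- new_bicluster(
      genes = match(rec$genes, gene_ids),
      samples = match(rec$samples, sample_ids),
      gene_scores = rec$gene_scores,
      sample_scores = rec$sample_scores,
      theta_g = if (is.null(rec$theta_g)) NA_real_ else rec$theta_g,
      theta_s = if (is.null(rec$theta_s)) NA_real_ else rec$theta_s,
      mode = rec$mode,
      denominator = if (is.null(rec$denominator)) NA_character_ else rec$denominator,
      variant = rec$variant,
      iterations = rec$iterations, converged = rec$converged,
      status = rec$status, init = integer(0), init_id = rec$init_id,
      gene_ids = gene_ids, sample_ids = sample_ids
    )
    if (rec$variant == "fixed") {
      b$k_g <- rec$k_g
      b$k_s <- rec$k_s
    }
    b
  })
  mult <- vapply(payload$biclusters, function(rec) {
    if (is.null(rec$multiplicity)) 1L else as.integer(rec$multiplicity)
  }, integer(1))
  list(biclusters = bcs, multiplicity = mult,
       n_excluded = payload$n_excluded,
       gene_ids = gene_ids, sample_ids = sample_ids,
       parameters = payload$parameters)
}
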