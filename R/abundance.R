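# Marker-set scoring of cell subpopulation abundance from bulk expression.
#
# The estimator is MCP-counter-style: the abundance score of a cell population
# in a sample is the arithmetic mean of log2-transformed expression over that
# population's marker genes.  Scores are in "mean log2 expression" units and
# are comparable across samples of the same matrix.

#' Filter genes with pervasive zero/missing expression
#'
#' Removes genes whose fraction of samples with zero or missing expression is
#' at least `max_bad_frac` (default 0.8, i.e. genes that are zero or missing
#' in 80% or more of the samples). The sample set is unchanged.
#'
#' @param expr Numeric matrix, genes x samples, linear scale, rownames = gene
#'   ids, colnames = sample ids. Missing values allowed.
#' @param max_bad_frac Fraction threshold in (0, 1].
#' @return The filtered matrix.
#' @examples
#' m <- matrix(c(0, 0, 0, 1, 2, 3), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("dead", "ok"), c("s1", "s2", "s3")))
#' rownames(filter_genes(m))
#' @export
filter_genes <- function(expr, max_bad_frac = 0.8) {
  check_expression(expr)
  if (max_bad_frac <= 0 || max_bad_frac > 1)
    stopf("max_bad_frac must be in (0, 1]")
  bad <- is.na(expr) | expr == 0
  frac_bad <- rowMeans(bad)
  keep <- frac_bad < max_bad_frac
  if (!any(keep))
    stopf("no genes remain after filtering (all are zero/missing in >= %.0f%% of samples)",
          100 * max_bad_frac)
  expr[keep, , drop = FALSE]
}

check_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stopf("expression must be a numeric matrix (genes x samples)")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stopf("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr))) stopf("duplicate gene ids")
  if (anyDuplicated(colnames(expr))) stopf("duplicate sample ids")
  if (any(expr < 0, na.rm = TRUE)) stopf("expression values must be >= 0")
  invisible(expr)
}

#' Estimate cell subpopulation abundance scores
#'
#' For each cell population the score of a sample is the mean of
#' `log2(expression + 1)` over the population's marker genes present in the
#' matrix. Markers absent from the matrix are skipped; missing values are
#' excluded from the mean rather than imputed. A cell population with no
#' marker present in the matrix is an error, never a silent value.
#'
#' @param expr Genes x samples matrix (linear scale), typically after
#'   [filter_genes()].
#' @param markers A `marker_sets` collection (named list of 10 marker vectors).
#' @param region Region tag attached to the result ("tumor" or "stroma").
#' @return An `abundance_profile`: data.frame with column `patient`, `region`,
#'   and one numeric score column per cell type.
#' @export
estimate_abundance <- function(expr, markers, region = c("tumor", "stroma")) {
  region <- match.arg(region)
  check_expression(expr)
  validate_markers(markers)
  lg <- log2(expr + 1)
  scores <- vapply(names(markers), function(cell) {
    present <- intersect(markers[[cell]], rownames(expr))
    if (length(present) == 0L)
      stopf("cell type '%s' has no marker genes present in the matrix", cell)
    colMeans(lg[present, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(expr)))
  scores <- matrix(scores, nrow = ncol(expr),
                   dimnames = list(colnames(expr), names(markers)))
  if (any(!is.finite(scores)))
    stopf("non-finite abundance score (a marker gene is missing in every sample?)")
  out <- data.frame(patient = colnames(expr), region = region,
                    scores, check.names = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("abundance_profile", "data.frame")
  out
}

#' Extract the score matrix from an abundance profile
#'
#' @param profile An `abundance_profile`.
#' @return Numeric matrix samples x cell types.
#' @export
abundance_matrix <- function(profile) {
  cols <- setdiff(names(profile), c("patient", "region", "group"))
  m <- as.matrix(profile[, cols, drop = FALSE])
  rownames(m) <- profile$patient
  m
}
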