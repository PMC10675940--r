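# Plain-text readers/writers for the formats the pipeline exchanges:
# expression TSV (genes in rows), GMT marker sets, abundance/survival CSV,
# NIfTI volumes and masks (via RNifti).

#' Read a genes-x-samples expression matrix from TSV
#'
#' First column = gene id, remaining columns = samples, linear-scale values.
#'
#' @param path TSV file path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  check_expression(m)
  m
}

#' Write a genes-x-samples expression matrix to TSV
#' @param expr Matrix with gene rownames, sample colnames.
#' @param path Output path.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read marker gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids.
#'
#' @param path GMT file path.
#' @return A `marker_sets` list (validated: 10 disjoint non-empty sets).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)][nzchar(p[-(1:2)])])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets <- structure(sets, class = "marker_sets")
  validate_markers(sets)
  sets
}

#' Write marker gene sets to a GMT file
#' @param markers `marker_sets` list.
#' @param path Output path.
#' @export
write_gmt <- function(markers, path) {
  lines <- vapply(names(markers), function(nm)
    paste(c(nm, "synthetic", markers[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an abundance profile to CSV
#' @param profile `abundance_profile` data.frame.
#' @param path Output path.
#' @export
write_abundance_csv <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}

#' Read an abundance profile from CSV
#' @param path CSV path written by [write_abundance_csv()].
#' @return `abundance_profile` data.frame.
#' @export
read_abundance_csv <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("abundance_profile", "data.frame")
  out
}

#' Write a volume (or mask) to NIfTI
#'
#' @param vol 3D numeric/logical array.
#' @param spacing Voxel spacing in mm, length 3.
#' @param path Output `.nii` / `.nii.gz` path.
#' @export
write_volume_nifti <- function(vol, spacing, path) {
  img <- RNifti::asNifti(vol * 1)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI path.
#' @return List with `data` (3D array) and `spacing` (mm, length 3).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       spacing = RNifti::pixdim(img)[1:3])
}
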