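# Gray-level discretization of a masked ROI, the common precursor to all
# texture matrices.

#' Discretize ROI intensities to integer gray levels
#'
#' Equal-width binning of `[min, max]` into `n_bins` levels (fixed bin
#' count, so normalized texture features are comparable across phases).
#' A constant ROI cannot be binned; it is assigned the single level 1 and
#' flagged degenerate, and downstream texture features take their analytic
#' limits.
#'
#' @param volume 3D intensity array.
#' @param mask Logical mask of the ROI (non-empty).
#' @param spacing Voxel spacing (mm).
#' @param n_bins Number of gray levels, >= 2.
#' @return List of class `droi`: `levels` (3D integer array, NA outside the
#'   mask), `intensities` (raw in-mask values), `mask`, `spacing`, `ng`
#'   (number of levels), `n_bins`, `degenerate`.
#' @export
discretize <- function(volume, mask, spacing = c(1, 1, 1), n_bins = 32L) {
  mask <- check_mask(mask, dim(volume), "ROI mask")
  if (!any(mask)) stopf("ROI mask is empty")
  if (n_bins < 2) stopf("n_bins must be >= 2")
  x <- volume[mask]
  lv <- array(NA_integer_, dim(volume))
  degenerate <- max(x) == min(x)
  if (degenerate) {
    warnf("constant ROI: all voxels assigned gray level 1; texture features take analytic limits")
    lv[mask] <- 1L
  } else {
    w <- (max(x) - min(x)) / n_bins
    lv[mask] <- pmin(as.integer(floor((x - min(x)) / w)) + 1L, as.integer(n_bins))
  }
  structure(list(levels = lv, intensities = x, mask = mask, spacing = spacing,
                 ng = as.integer(n_bins), n_bins = as.integer(n_bins),
                 degenerate = degenerate),
            class = "droi")
}
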