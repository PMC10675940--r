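# Orchestration of the full radiomic vector: 18 first-order + 75 texture
# features per (region, phase) over {tumor, stroma} x {S0, SI, SL}, plus 14
# shape features from the tumor mask once = 572 named values.

FEATURE_FAMILIES <- c(firstorder = 18L, shape = 14L, glcm = 24L, glrlm = 16L,
                      glszm = 16L, gldm = 14L, ngtdm = 5L)

#' Per-family feature counts of the radiomic engine
#' @return Named integer vector (firstorder, shape, glcm, glrlm, glszm,
#'   gldm, ngtdm); totals 107 per full single-image set, 572 over the
#'   region/phase layout.
#' @export
feature_family_counts <- function() FEATURE_FAMILIES

## 93 intensity/texture features for one ROI on one phase
roi_features <- function(volume, mask, spacing, n_bins) {
  droi <- discretize(volume, mask, spacing, n_bins)
  c(setNames2("firstorder", first_order(droi)),
    setNames2("glcm", glcm_features(droi)),
    setNames2("glrlm", glrlm_features(droi)),
    setNames2("glszm", glszm_features(droi)),
    setNames2("gldm", gldm_features(droi)),
    setNames2("ngtdm", ngtdm_features(droi)))
}

setNames2 <- function(family, x) {
  names(x) <- paste(family, names(x), sep = "_")
  x
}

#' Extract the full 572-feature radiomic vector
#'
#' Intensity and texture features (93 each) are computed for the tumor and
#' stroma-band ROIs on the three phases S0/SI/SL; the 14 shape features are
#' computed once from the tumor mask. Names follow
#' `<region>_<phase>_<family>_<feature>` and `tumor_shape_<feature>`; the
#' ordering is fixed (naming schema version 1) so downstream models are
#' reproducible.
#'
#' @param phases A `phase_set` from [derive_phases()] (elements S0, SI, SL,
#'   spacing).
#' @param tumor_mask,stroma_mask Logical masks on the phase grid.
#' @param n_bins Discretization bins for texture features (default 32).
#' @return Named numeric vector of exactly 572 finite values, with
#'   attribute `degenerate` listing any constant (region, phase) ROIs whose
#'   texture features took analytic limits.
#' @export
extract_all <- function(phases, tumor_mask, stroma_mask, n_bins = 32L) {
  spacing <- phases$spacing
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  masks <- list(tumor = tumor_mask != 0, stroma = stroma_mask != 0)
  out <- setNames2("tumor_shape", shape3d(masks$tumor, spacing))
  degenerate <- character(0)
  for (region in c("tumor", "stroma")) {
    for (phase in c("S0", "SI", "SL")) {
      vals <- withCallingHandlers(
        roi_features(phases[[phase]], masks[[region]], spacing, n_bins),
        warning = function(w) {
          if (grepl("constant ROI", conditionMessage(w))) {
            degenerate <<- c(degenerate, paste(region, phase, sep = "/"))
            invokeRestart("muffleWarning")
          }
        })
      names(vals) <- paste(region, phase, names(vals), sep = "_")
      out <- c(out, vals)
    }
  }
  if (length(degenerate))
    warnf("constant ROI(s) %s: texture features took analytic limits; consider excluding them from modelling",
          paste(degenerate, collapse = ", "))
  if (any(!is.finite(out)))
    stopf("non-finite feature value(s): %s",
          paste(utils::head(names(out)[!is.finite(out)], 5), collapse = ", "))
  attr(out, "degenerate") <- degenerate
  out
}

#' Radiomic feature table for a cohort of phantoms/series
#'
#' Runs [prep_patient()] + [extract_all()] per series and binds one row per
#' patient.
#'
#' @param series_list Named list of `volume_series`.
#' @param n_bins Discretization bins.
#' @param ... Passed to [prep_patient()].
#' @return data.frame: patient id column plus 572 feature columns.
#' @export
extract_cohort <- function(series_list, n_bins = 32L, ...) {
  rows <- lapply(series_list, function(s) {
    pr <- prep_patient(s, ...)
    extract_all(pr$phases, pr$tumor_mask, pr$stroma_mask, n_bins = n_bins)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  cbind(patient = names(series_list), tab, row.names = NULL)
}
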