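# The tumor-stroma heterogeneity (TSH) ratio statistic and patient
# stratification.
#
# TSH compares a cell population's abundance inside the tumor with the
# surrounding stroma:  (A_tumor - A_stroma) / A_stroma.  Positive values mean
# tumor enrichment; -1 < TSH < 0 means stromal enrichment; the statistic is
# invariant to rescaling both abundances by the same positive factor.

#' TSH ratio statistic
#'
#' `(a_tumor - a_stroma) / a_stroma`, vectorized. A stromal abundance with
#' magnitude below `eps` makes the ratio undefined and is an error that names
#' the offending entries.
#'
#' @param a_tumor,a_stroma Abundance scores (same length, optionally named by
#'   patient/cell type).
#' @param eps Smallest allowed `|a_stroma|`.
#' @return Numeric vector of TSH ratios.
#' @examples
#' tsh_score(2, 1)   # 1: tumor twice the stroma
#' tsh_score(1, 1)   # 0: homogeneous
#' @export
tsh_score <- function(a_tumor, a_stroma, eps = 1e-8) {
  if (length(a_tumor) != length(a_stroma))
    stopf("a_tumor and a_stroma must have the same length")
  bad <- !is.finite(a_stroma) | abs(a_stroma) < eps
  if (any(bad)) {
    who <- names(a_stroma)[bad]
    if (is.null(who)) who <- which(bad)
    stopf("undefined TSH ratio: |a_stroma| < %g for %s",
          eps, paste(utils::head(who, 5), collapse = ", "))
  }
  (a_tumor - a_stroma) / a_stroma
}

#' Build a per-patient TSH table from paired abundance profiles
#'
#' @param tumor,stroma `abundance_profile` objects for the same patients.
#' @param cell_type Cell type(s) to score; default all ten.
#' @return data.frame: patient, cell_type, a_tumor, a_stroma, tsh.
#' @export
tsh_table <- function(tumor, stroma, cell_type = cell_types()) {
  if (!setequal(tumor$patient, stroma$patient))
    stopf("tumor and stroma profiles cover different patients")
  stroma <- stroma[match(tumor$patient, stroma$patient), ]
  out <- lapply(cell_type, function(ct) {
    a_t <- tumor[[ct]]; a_s <- stroma[[ct]]
    if (is.null(a_t) || is.null(a_s)) stopf("cell type '%s' not in profiles", ct)
    names(a_s) <- tumor$patient
    data.frame(patient = tumor$patient, cell_type = ct,
               a_tumor = a_t, a_stroma = a_s,
               tsh = tsh_score(a_t, a_s), row.names = NULL)
  })
  do.call(rbind, out)
}

#' Stratify patients into good/poor survival groups by TSH value
#'
#' Values strictly above the threshold are labelled "good"; values at or
#' below it (including exact ties) are "poor". The published operating
#' threshold for the cytotoxic-lymphocyte TSH biomarker is available as
#' [tsh_threshold_default()].
#'
#' @param tsh Numeric TSH values (finite).
#' @param threshold Cut point.
#' @return Factor with levels `good`, `poor`, same names as `tsh`.
#' @export
stratify <- function(tsh, threshold = tsh_threshold_default()) {
  if (any(!is.finite(tsh))) stopf("tsh values must be finite")
  labels <- ifelse(tsh > threshold, "good", "poor")
  factor(labels, levels = c("good", "poor"))
}

#' Published TSH stratification threshold
#'
#' The operating cut point (0.3512) reported for separating good- from
#' poor-survival patients on the cytotoxic-lymphocyte TSH biomarker. Treated
#' as a user-supplied constant; its derivation is cohort-specific.
#'
#' @return Numeric scalar 0.3512.
#' @export
tsh_threshold_default <- function() 0.3512

#' Administrative censoring at a follow-up horizon
#'
#' Records with follow-up beyond the horizon are truncated to the horizon and
#' marked event-free; all other records are unchanged.
#'
#' @param records data.frame with `time` (years) and `event` (0/1) columns.
#' @param horizon_years Censoring horizon, default 10.
#' @return The censored records.
#' @export
censor_at <- function(records, horizon_years = 10) {
  stopifnot(all(c("time", "event") %in% names(records)))
  over <- records$time > horizon_years
  records$event[over] <- 0L
  records$time[over] <- horizon_years
  records
}
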