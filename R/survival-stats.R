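# Survival and association statistics for the genomic arm: Kaplan-Meier
# curves, two-group log-rank, multivariate Cox (Breslow ties), nested-model
# likelihood-ratio tests, Benjamini-Hochberg correction, and the paired
# Wilcoxon signed-rank test.  Model fitting is delegated to the survival
# package; this layer enforces the pipeline's contracts (two-group designs,
# degenerate-input errors, reporting layout).

check_records <- function(records) {
  stopifnot(is.data.frame(records), all(c("time", "event") %in% names(records)))
  if (any(records$time <= 0)) stopf("survival times must be > 0")
  if (!all(records$event %in% c(0, 1))) stopf("event must be 0/1")
  invisible(records)
}

as_two_groups <- function(groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L)
    stopf("degenerate grouping: all patients fall in a single group ('%s')",
          levels(g)[1])
  if (nlevels(g) > 2L) stopf("only two-group comparisons are supported")
  g
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator with right-continuous steps at event times.
#'
#' @param records data.frame with `time`, `event`.
#' @param groups Group label per record (optional; single curve if omitted).
#' @return data.frame: group, time, n_risk, n_event, n_censor, surv.
#' @export
km_curve <- function(records, groups = NULL) {
  check_records(records)
  if (is.null(groups)) groups <- rep("all", nrow(records))
  g <- factor(groups)
  fit <- survival::survfit(
    survival::Surv(records$time, records$event) ~ g, conf.type = "none")
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(g)[1], length(sm$time))
         else sub("^g=", "", as.character(sm$strata))
  data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
             n_event = sm$n.event, n_censor = sm$n.censor,
             surv = sm$surv, row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' @param records data.frame with `time`, `event`.
#' @param groups Two-level group labels.
#' @return List: `statistic` (1-df chi-square), `p`, `observed`, `expected`
#'   (per-group event counts).
#' @export
logrank_test <- function(records, groups) {
  check_records(records)
  g <- as_two_groups(groups)
  fit <- survival::survdiff(
    survival::Surv(records$time, records$event) ~ g)
  stat <- unname(fit$chisq)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = unname(fit$obs), expected = unname(fit$exp))
}

#' Multivariate Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Breslow tie handling. Reports, per
#' covariate, the coefficient, hazard ratio with Wald 95% CI
#' (`exp(beta +/- 1.96 se)`), the Wald chi-square statistic, and p value.
#'
#' @param records data.frame with `time`, `event`, and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @return List of class `cox_fit`: `table` (data.frame feature, beta, hr,
#'   ci_low, ci_high, wald, p), `loglik` (model), `loglik_null`, `n_params`,
#'   `fit` (the underlying `coxph` object).
#' @export
cox_fit <- function(records, covariates) {
  check_records(records)
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov))
    stopf("covariates not in records: %s", paste(missing_cov, collapse = ", "))
  if (sum(records$event) > 0 &&
      length(unique(records$time[records$event == 1])) < 2L)
    stopf("need at least 2 distinct event times")
  for (cv in covariates) {
    v <- records[[cv]]
    if (length(unique(v[!is.na(v)])) < 2L)
      stopf("constant covariate '%s'", cv)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~", paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations",
                conditionMessage(w)))
        stopf("Cox fit failed (separation or non-convergence): %s",
              conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- beta / se
  tab <- data.frame(
    feature = names(beta), beta = unname(beta), hr = unname(exp(beta)),
    ci_low = unname(exp(beta - 1.96 * se)), ci_high = unname(exp(beta + 1.96 * se)),
    wald = unname(z^2),
    p = unname(stats::pchisq(z^2, df = 1, lower.tail = FALSE)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(table = tab, loglik = fit$loglik[2],
                 loglik_null = fit$loglik[1], n_params = length(beta),
                 fit = fit),
            class = "cox_fit")
}

#' Likelihood-ratio test between nested Cox models
#'
#' `2 * (logL_full - logL_null)` referred to a chi-square with df equal to
#' the difference in parameter count. Identical models (df 0, statistic ~0)
#' return p = 1.
#'
#' @param fit_null,fit_full `cox_fit` objects, null nested in full.
#' @return List: `statistic`, `df`, `p`.
#' @export
lr_test <- function(fit_null, fit_full) {
  stat <- 2 * (fit_full$loglik - fit_null$loglik)
  df <- fit_full$n_params - fit_null$n_params
  if (df < 0 || stat < -1e-6)
    stopf("models are not nested (null must be the smaller model)")
  stat <- max(stat, 0)
  p <- if (df == 0) {
    if (stat > 1e-6) stopf("df = 0 but the log-likelihoods differ")
    1
  } else stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment: monotone in the p-value ranks, never below
#' the raw p, capped at 1.
#'
#' @param p Numeric vector of p values.
#' @return Adjusted p values, same order as input.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Paired Wilcoxon signed-rank test
#'
#' Tests for a location shift between paired measurements. Zero differences
#' are discarded before ranking (with a warning); if all differences are zero
#' the test is degenerate and returns p = 1 with a warning. The exact null
#' distribution is used for n <= 25 untied differences; larger or tied
#' samples use the normal approximation with continuity correction.
#'
#' @param a,b Paired numeric vectors.
#' @return List: `statistic` (V, sum of positive ranks), `p`, `n_used`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stopf("paired vectors must have equal length")
  d <- a - b
  n_zero <- sum(d == 0)
  if (n_zero > 0) {
    warnf("%d zero difference(s) discarded before ranking", n_zero)
    d <- d[d != 0]
  }
  if (length(d) == 0L)
    return(list(statistic = 0, p = 1, n_used = 0L))
  exact <- length(d) <= 25 && !anyDuplicated(abs(d))
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value, n_used = length(d))
}

#' Univariate prognostic sweep over cell-type TSH biomarkers
#'
#' For each cell type, fits a Cox model of survival on that cell type's TSH
#' value and reports the standard layout (feature, beta, HR, CI, Wald, p)
#' plus BH-corrected p over the full sweep.
#'
#' @param tsh_tbl Long table from [tsh_table()] (patient, cell_type, tsh).
#' @param records Survival records joinable on `patient`.
#' @return data.frame, one row per cell type, ordered as in `tsh_tbl`.
#' @export
univariate_tsh_sweep <- function(tsh_tbl, records) {
  check_records(records)
  cells <- unique(tsh_tbl$cell_type)
  rows <- lapply(cells, function(ct) {
    sub <- tsh_tbl[tsh_tbl$cell_type == ct, ]
    dat <- merge(records, sub[, c("patient", "tsh")], by = "patient")
    fit <- cox_fit(dat, "tsh")
    cbind(feature = ct, fit$table[, -1])
  })
  out <- do.call(rbind, rows)
  out$corrected_p <- bh_adjust(out$p)
  out
}
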