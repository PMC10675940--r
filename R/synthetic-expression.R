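# Synthetic marker-structured expression cohorts with known planted truth.
#
# These generators emulate paired tumor/stroma bulk expression in which each
# of the ten cell populations has a planted mean abundance per (cell type,
# region, survival group).  Marker genes carry the planted signal on the log2
# scale; all remaining genes are uninformative log-normal background.  The
# planted per-sample abundance is returned so estimators can be validated by
# round trip.

#' Generate synthetic marker gene sets for the ten cell populations
#'
#' Produces `n_per_type` synthetic marker gene identifiers for each of the ten
#' scored cell populations. Marker sets are pairwise disjoint and the
#' identifiers are deterministic given the seed.
#'
#' @param n_per_type Number of marker genes per cell type (>= 1).
#' @param seed Integer seed.
#' @return Named list of 10 character vectors (class `marker_sets`), one per
#'   cell type in [cell_types()].
#' @examples
#' m <- generate_markers(5, seed = 1)
#' lengths(m)
#' @export
generate_markers <- function(n_per_type, seed = 1L) {
  if (n_per_type < 1) stopf("n_per_type must be >= 1")
  set.seed(seed)
  types <- cell_types()
  ## deterministic but shuffled gene ids so marker order carries no structure
  ids <- sprintf("GENE%05d", sample.int(99999L, n_per_type * length(types)))
  sets <- split(ids, rep(seq_along(types), each = n_per_type))
  names(sets) <- types
  structure(sets, class = "marker_sets")
}

validate_markers <- function(markers) {
  if (!is.list(markers) || length(markers) != 10L)
    stopf("markers must be a list of exactly 10 cell-type marker sets, got %d",
          length(markers))
  if (any(lengths(markers) == 0L)) stopf("marker sets must be non-empty")
  all_ids <- unlist(markers, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stopf("marker sets must be pairwise disjoint (duplicated: %s)",
          paste(unique(all_ids[duplicated(all_ids)])[1:3], collapse = ", "))
  if (is.null(names(markers)) || anyDuplicated(names(markers)))
    stopf("marker sets must have unique cell-type names")
  invisible(markers)
}

#' Default planted abundance table for synthetic cohorts
#'
#' Mean log2 abundance for each (cell type, region, group) combination. The
#' good-survival group plants higher abundance in the tumor than in the stroma
#' (tumor = 2 x stroma for cytotoxic lymphocytes, so the TSH ratio is
#' positive), while the poor-survival group plants the reverse gradient,
#' mirroring the qualitative tumor-vs-stroma contrast the TSH statistic is
#' designed to detect.
#'
#' @return data.frame with columns cell_type, region, group, mean_log2.
#' @export
default_planted_abundance <- function() {
  grid <- expand.grid(
    cell_type = cell_types(), region = c("tumor", "stroma"),
    group = c("good", "poor"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  base <- seq(3, 5.25, length.out = 10)[match(grid$cell_type, cell_types())]
  ## good: tumor enriched (x2 on the abundance scale); poor: stroma enriched
  mult <- ifelse(grid$group == "good",
                 ifelse(grid$region == "tumor", 2, 1),
                 ifelse(grid$region == "tumor", 0.5, 1))
  grid$mean_log2 <- base * mult / 2
  grid
}

#' Configuration for a synthetic expression + survival cohort
#'
#' @param n_patients Number of patients (> 0).
#' @param n_genes Total genes per expression matrix (>= total marker count).
#' @param planted_abundance data.frame(cell_type, region, group, mean_log2)
#'   giving the planted mean log2 abundance; defaults to
#'   [default_planted_abundance()].
#' @param noise_sd SD of the per-gene log2 noise (>= 0).
#' @param latent_sd Named numeric `c(good =, poor =)`: SD of a per-patient
#'   latent factor added to every cell type's abundance, controlling
#'   inter-cell-type correlation within each group. The default makes the
#'   good group's cell populations more strongly co-varying than the poor
#'   group's, emulating the denser cell-cell coupling reported for
#'   good-survival tumors.
#' @param hazard_ratio Poor-vs-good hazard multiplier (> 0).
#' @param baseline_hazard Good-group event rate, events/year (> 0).
#' @param censor_rate Fraction of patients independently censored in `[0,1]`.
#' @param prop_poor Fraction of patients assigned to the poor group.
#' @param seed Integer seed.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100L, n_genes = 500L,
                          planted_abundance = default_planted_abundance(),
                          noise_sd = 0.3,
                          latent_sd = c(good = 0.4, poor = 0.1),
                          hazard_ratio = 3, baseline_hazard = 0.08,
                          censor_rate = 0.2, prop_poor = 0.5, seed = 1L) {
  if (n_patients <= 0 || n_genes <= 0) stopf("counts must be > 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (hazard_ratio <= 0 || baseline_hazard <= 0)
    stopf("hazard_ratio and baseline_hazard must be > 0")
  if (censor_rate < 0 || censor_rate > 1) stopf("censor_rate must be in [0,1]")
  stopifnot(all(c("cell_type", "region", "group", "mean_log2") %in%
                  names(planted_abundance)))
  structure(list(
    n_patients = as.integer(n_patients), n_genes = as.integer(n_genes),
    planted_abundance = planted_abundance, noise_sd = noise_sd,
    latent_sd = latent_sd, hazard_ratio = hazard_ratio,
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    prop_poor = prop_poor, seed = as.integer(seed)
  ), class = "cohort_config")
}

planted_mean <- function(tbl, cell, region, group) {
  v <- tbl$mean_log2[tbl$cell_type == cell & tbl$region == region &
                       tbl$group == group]
  if (length(v) != 1L)
    stopf("planted_abundance has no unique entry for (%s, %s, %s)",
          cell, region, group)
  v
}

#' Generate a paired tumor/stroma expression cohort with planted abundances
#'
#' Marker genes of cell type `c` in region `r` for a patient in group `g` are
#' drawn with log2 expression `planted(c, r, g) + latent + N(0, noise_sd)`,
#' where the latent term is a per-patient factor shared across cell types
#' (inducing within-group inter-cell-type correlation). Linear-scale values
#' are `2^x - 1`, so the estimator's `log2(x + 1)` transform recovers the
#' planted log2 level exactly at zero noise. Non-marker genes are log-normal
#' background independent of group and region.
#'
#' @param config A [cohort_config()].
#' @param markers A `marker_sets` collection from [generate_markers()].
#' @return List with elements `tumor`, `stroma` (genes x samples matrices,
#'   linear scale), `truth` (long data.frame: patient, cell_type, region,
#'   group, true_log2), and `groups` (named character vector patient -> group).
#' @export
generate_expression_cohort <- function(config, markers) {
  validate_markers(markers)
  n_marker <- sum(lengths(markers))
  if (config$n_genes < n_marker)
    stopf("n_genes (%d) < total marker count (%d)", config$n_genes, n_marker)
  set.seed(config$seed)
  n <- config$n_patients
  patients <- sprintf("P%03d", seq_len(n))
  n_poor <- round(config$prop_poor * n)
  groups <- sample(rep(c("poor", "good"), c(n_poor, n - n_poor)))
  names(groups) <- patients

  gene_ids <- unlist(markers, use.names = FALSE)
  n_bg <- config$n_genes - n_marker
  if (n_bg > 0) gene_ids <- c(gene_ids, sprintf("BG%05d", seq_len(n_bg)))

  lat_sd <- config$latent_sd[groups]
  latent <- stats::rnorm(n, 0, lat_sd)  # shared across cell types and regions

  make_region <- function(region) {
    m <- matrix(NA_real_, nrow = length(gene_ids), ncol = n,
                dimnames = list(gene_ids, patients))
    truth <- vector("list", length(markers))
    for (ci in seq_along(markers)) {
      cell <- names(markers)[ci]
      mu <- vapply(groups, function(g)
        planted_mean(config$planted_abundance, cell, region, g), numeric(1))
      true_log2 <- mu + latent
      genes <- markers[[ci]]
      noise <- matrix(stats::rnorm(length(genes) * n, 0, config$noise_sd),
                      length(genes), n)
      log2val <- sweep(noise, 2L, true_log2, `+`)
      m[genes, ] <- pmax(2^log2val - 1, 0)
      truth[[ci]] <- data.frame(patient = patients, cell_type = cell,
                                region = region, group = unname(groups),
                                true_log2 = unname(true_log2))
    }
    if (n_bg > 0) {
      bg <- 2^matrix(stats::rnorm(n_bg * n, mean = 2, sd = 1), n_bg, n) - 1
      m[n_marker + seq_len(n_bg), ] <- pmax(bg, 0)
    }
    list(mat = m, truth = do.call(rbind, truth))
  }

  tum <- make_region("tumor")
  str <- make_region("stroma")
  list(tumor = tum$mat, stroma = str$mat,
       truth = rbind(tum$truth, str$truth), groups = groups)
}

#' Generate survival records with group-dependent exponential hazard
#'
#' Event times are exponential with rate `baseline_hazard` for the good group
#' and `baseline_hazard * hazard_ratio` for the poor group (proportional
#' hazards). Censoring is independent of the event time: censoring times are
#' uniform on `(0, c_max)` with `c_max` solved per hazard rate so that the
#' expected censored fraction equals `censor_rate` (non-informative
#' censoring, so Cox estimation stays unbiased).
#'
#' @param groups Named character vector (patient -> "good"/"poor").
#' @param config A [cohort_config()] supplying hazard parameters.
#' @param seed Optional seed overriding `config$seed`.
#' @return data.frame: patient, group, time (years), event (0/1), plus
#'   synthetic clinical covariates age (years), er, pr, her2
#'   ("positive"/"negative"), size (mm) drawn independently of outcome.
#' @export
generate_survival <- function(groups, config, seed = config$seed) {
  if (config$hazard_ratio <= 0 || config$baseline_hazard <= 0)
    stopf("hazard_ratio and baseline_hazard must be > 0")
  set.seed(seed)
  n <- length(groups)
  rate <- config$baseline_hazard *
    ifelse(groups == "poor", config$hazard_ratio, 1)
  t_event <- stats::rexp(n, rate)
  if (config$censor_rate > 0) {
    ## P(C < T) for C ~ U(0, c_max), T ~ Exp(rate) equals
    ## (1 - exp(-rate c_max)) / (rate c_max); solve c_max per rate so the
    ## expected censored fraction is censor_rate
    c_max_for <- vapply(unique(rate), function(lam) {
      stats::uniroot(function(cm)
        (1 - exp(-lam * cm)) / (lam * cm) - config$censor_rate,
        lower = 1e-9, upper = 1e9, tol = 1e-10)$root
    }, numeric(1))
    c_time <- stats::runif(n) * c_max_for[match(rate, unique(rate))]
  } else {
    c_time <- rep(Inf, n)
  }
  time <- pmin(t_event, c_time)
  event <- as.integer(t_event <= c_time)
  data.frame(
    patient = names(groups), group = unname(groups),
    time = pmax(time, 1e-6), event = event,
    age = round(stats::rnorm(n, 57, 13), 1),
    er = sample(c("positive", "negative"), n, TRUE, c(0.7, 0.3)),
    pr = sample(c("positive", "negative"), n, TRUE, c(0.62, 0.38)),
    her2 = sample(c("positive", "negative"), n, TRUE, c(0.2, 0.8)),
    size = round(stats::rlnorm(n, log(22), 0.4), 1),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
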