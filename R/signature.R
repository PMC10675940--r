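# Radiogenomic signature modelling: collinearity pruning, genetic-algorithm
# feature selection under k-fold cross-validated AUC, a random-forest
# classifier whose poor-class probability serves as the imaging TSH score,
# ROC/AUC, the tumor-only abundance model, and prognostic validation.

## ---- collinearity pruning -------------------------------------------------

#' Greedy removal of collinear feature pairs
#'
#' While any feature pair has `|r| > r_max`, the pair with the largest `|r|`
#' is considered and the member with the larger mean absolute correlation to
#' all other features is dropped (ties broken lexicographically by name,
#' keeping the earlier name). The result contains no pair with `|r| > r_max`.
#'
#' @param table data.frame or matrix of numeric features (>= 2 columns).
#' @param r_max Absolute Pearson threshold, default 0.8.
#' @return The pruned table (same type as the input).
#' @export
prune_collinear <- function(table, r_max = 0.8) {
  m <- as.matrix(table)
  if (ncol(m) < 2) stopf("need at least 2 features")
  keep <- colnames(m)
  repeat {
    r <- abs(suppressWarnings(stats::cor(m[, keep, drop = FALSE])))
    diag(r) <- 0
    r[is.na(r)] <- 0
    if (max(r) <= r_max) break
    idx <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- keep[idx]
    mean_abs <- rowMeans(r[pair, , drop = FALSE])
    drop_ft <- if (abs(diff(mean_abs)) > 1e-12) pair[which.max(mean_abs)]
               else sort(pair)[2]
    keep <- setdiff(keep, drop_ft)
    if (length(keep) < 2) break
  }
  table[, keep, drop = FALSE]
}

## ---- ROC / AUC ------------------------------------------------------------

#' ROC curve and AUC
#'
#' AUC by the trapezoidal rule over all score thresholds, equal to the
#' normalized Mann-Whitney U statistic (ties counted 1/2). Higher scores are
#' expected for the positive class.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels: logical, 0/1, or a factor whose *second*
#'   level is the positive class.
#' @param threshold Optional score threshold at which to report sensitivity
#'   and specificity (`score > threshold` calls positive).
#' @return List: `auc`, `curve` (data.frame fpr, tpr ordered by threshold),
#'   and when `threshold` is given, `sensitivity`, `specificity`.
#' @export
roc_auc <- function(scores, labels, threshold = NULL) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stopf("labels must contain both classes")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores)  # midranks handle ties = trapezoid over tied blocks
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  tpr <- c(0, cumsum(y[ord] == 1) / n1)
  fpr <- c(0, cumsum(y[ord] == 0) / n0)
  out <- list(auc = auc, curve = data.frame(fpr = fpr, tpr = tpr))
  if (!is.null(threshold)) {
    out$sensitivity <- mean(scores[y == 1] > threshold)
    out$specificity <- mean(scores[y == 0] <= threshold)
  }
  out
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) as.integer(labels == levels(labels)[2])
  else if (is.logical(labels)) as.integer(labels)
  else if (all(labels %in% c(0, 1))) as.integer(labels)
  else stopf("labels must be logical, 0/1, or a two-level factor")
}

#' Youden-optimal operating point of a ROC
#'
#' @param scores,labels As in [roc_auc()].
#' @return List: `threshold`, `sensitivity`, `specificity`.
#' @export
youden_point <- function(scores, labels) {
  y <- as_binary_labels(labels)
  cand <- sort(unique(scores))
  thr <- c(-Inf, (cand[-1] + cand[-length(cand)]) / 2, Inf)
  j <- vapply(thr, function(t)
    mean(scores[y == 1] > t) + mean(scores[y == 0] <= t) - 1, numeric(1))
  best <- which.max(j)
  list(threshold = thr[best],
       sensitivity = mean(scores[y == 1] > thr[best]),
       specificity = mean(scores[y == 0] <= thr[best]))
}

## ---- cross-validated fitness ----------------------------------------------

make_folds <- function(y, k) {
  idx <- seq_along(y)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    members <- sample(idx[y == cl])
    folds[members] <- rep_len(seq_len(k), length(members))
  }
  folds
}

cv_auc <- function(x, y, folds, ntree) {
  scores <- numeric(length(y))
  for (k in sort(unique(folds))) {
    test <- folds == k
    fit <- randomForest::randomForest(
      x = x[!test, , drop = FALSE], y = y[!test], ntree = ntree)
    scores[test] <- stats::predict(fit, x[test, , drop = FALSE],
                                   type = "prob")[, 2]
  }
  roc_auc(scores, y)$auc
}

## ---- genetic algorithm ----------------------------------------------------

#' Genetic-algorithm configuration
#'
#' The published search used a population of 100 over 100 iterations under
#' tenfold cross-validation; the remaining operator settings (uniform
#' crossover at rate 0.8, bit-flip mutation at rate 1/n features, tournament
#' size 3, elitism 1) are standard defaults.
#'
#' @param population_size,generations,cv_folds Core GA sizes (> 0).
#' @param crossover_rate,mutation_rate GA operator rates; `mutation_rate =
#'   NULL` means 1/n_features.
#' @param tournament_size Selection tournament size.
#' @param ntree Random-forest size used inside the fitness function.
#' @param seed Integer seed.
#' @return List of class `ga_config`.
#' @export
ga_config <- function(population_size = 100L, generations = 100L,
                      cv_folds = 10L, crossover_rate = 0.8,
                      mutation_rate = NULL, tournament_size = 3L,
                      ntree = 100L, seed = 1L) {
  if (population_size <= 0 || generations <= 0 || cv_folds <= 0)
    stopf("population_size, generations and cv_folds must be > 0")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 cv_folds = as.integer(cv_folds),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 tournament_size = as.integer(tournament_size),
                 ntree = as.integer(ntree), seed = as.integer(seed)),
            class = "ga_config")
}

#' Genetic-algorithm feature selection
#'
#' Binary-mask chromosomes over the feature columns; fitness is the mean
#' out-of-fold AUC of a random-forest classifier restricted to the masked
#' features (folds fixed once per run). Tournament selection, uniform
#' crossover, bit-flip mutation, elitism of one. Deterministic given
#' `config$seed`; fitness values are memoized per mask.
#'
#' @param table Numeric feature data.frame/matrix.
#' @param labels Two-level factor (or coercible) class labels.
#' @param config A [ga_config()].
#' @return List: `features` (selected names), `mask` (logical), `fitness`
#'   (best search CV AUC; optimistically biased, being a maximum over many
#'   candidate masks), `cv_auc` (the selected subset's CV AUC re-estimated
#'   on fresh folds after the search — the honest performance estimate),
#'   `trajectory` (best fitness per generation), `config`.
#' @export
ga_select <- function(table, labels, config = ga_config()) {
  x <- as.matrix(table)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2) stopf("labels must have exactly two classes")
  set.seed(config$seed)
  n_feat <- ncol(x)
  mut_rate <- if (is.null(config$mutation_rate)) 1 / n_feat
              else config$mutation_rate
  folds <- make_folds(y, config$cv_folds)
  if (min(table(y[folds == 1])) < 1 || min(table(y)) < config$cv_folds)
    stopf("degenerate labels: need >= 1 sample per class per fold")
  cache <- new.env(parent = emptyenv())
  fitness <- function(mask) {
    if (!any(mask)) return(0)
    key <- paste(which(mask), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- cv_auc(x[, mask, drop = FALSE], y, folds, config$ntree)
    cache[[key]] <- val
    val
  }
  pop <- lapply(seq_len(config$population_size), function(i) {
    m <- stats::runif(n_feat) < 0.5
    if (!any(m)) m[sample.int(n_feat, 1)] <- TRUE
    m
  })
  fit <- vapply(pop, fitness, numeric(1))
  trajectory <- numeric(config$generations)
  for (gen in seq_len(config$generations)) {
    elite <- pop[[which.max(fit)]]
    tournament <- function() {
      cand <- sample.int(length(pop), config$tournament_size)
      pop[[cand[which.max(fit[cand])]]]
    }
    nxt <- vector("list", config$population_size)
    nxt[[1]] <- elite
    for (i in 2:config$population_size) {
      p1 <- tournament(); p2 <- tournament()
      child <- if (stats::runif(1) < config$crossover_rate)
        ifelse(stats::runif(n_feat) < 0.5, p1, p2) else p1
      flip <- stats::runif(n_feat) < mut_rate
      child <- xor(child, flip)
      if (!any(child)) child[sample.int(n_feat, 1)] <- TRUE
      nxt[[i]] <- child
    }
    pop <- nxt
    fit <- vapply(pop, fitness, numeric(1))
    trajectory[gen] <- max(fit)
  }
  best <- pop[[which.max(fit)]]
  ## honest re-evaluation on folds not used during the search
  fresh_folds <- make_folds(y, config$cv_folds)
  cv_honest <- cv_auc(x[, best, drop = FALSE], y, fresh_folds, config$ntree)
  list(features = colnames(x)[best], mask = best, fitness = max(fit),
       cv_auc = cv_honest, trajectory = trajectory, config = config)
}

## ---- classifier and signature models --------------------------------------

#' Train the random-forest signature classifier
#'
#' The model's score for a sample is the predicted probability of the
#' poor-survival class (the imaging TSH score surrogate; higher = poor),
#' thresholded at `threshold` for group calls.
#'
#' @param table Numeric feature table (already reduced to the selected
#'   features).
#' @param labels Two-level factor; the "poor" level (or the second level) is
#'   the positive class.
#' @param seed Integer seed.
#' @param ntree Forest size.
#' @param threshold Score threshold for group calls, default 0.5.
#' @return List of class `signature_model`: `features`, `forest`,
#'   `positive_class`, `threshold`, `seed`.
#' @export
train_classifier <- function(table, labels, seed = 1L, ntree = 500L,
                             threshold = 0.5) {
  x <- as.matrix(table)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2) stopf("labels must have exactly two classes")
  positive <- if ("poor" %in% levels(y)) "poor" else levels(y)[2]
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = ntree)
  structure(list(features = colnames(x), forest = fit,
                 positive_class = positive, threshold = threshold,
                 seed = as.integer(seed)),
            class = "signature_model")
}

#' Score new samples with a signature model
#'
#' @param model A `signature_model`.
#' @param table Feature table containing the model's features.
#' @return Numeric vector of poor-class probabilities.
#' @export
predict_score <- function(model, table) {
  missing_ft <- setdiff(model$features, colnames(table))
  if (length(missing_ft))
    stopf("feature(s) absent from table: %s",
          paste(utils::head(missing_ft, 5), collapse = ", "))
  x <- as.matrix(table[, model$features, drop = FALSE])
  stats::predict(model$forest, x, type = "prob")[, model$positive_class]
}

#' Tumor-only cell-abundance model predicting the TSH group
#'
#' Greedy forward selection over the ten abundance scores maximizing the
#' mean out-of-fold AUC of a random forest (stopping when no candidate
#' improves it), then a final classifier on the selected populations.
#' Reports the CV AUC and the sensitivity/specificity at the Youden-optimal
#' threshold of the out-of-fold scores.
#'
#' @param abundances `abundance_profile` (tumor region) or sample x feature
#'   table of the 10 abundance scores.
#' @param tsh_groups Factor of TSH groups ("good"/"poor") per sample.
#' @param seed Integer seed.
#' @param cv_folds Folds for selection and reporting, default 10.
#' @param ntree Forest size, default 200.
#' @return List: `model` (`signature_model`), `features`, `auc` (CV),
#'   `sensitivity`, `specificity`, `roc` (out-of-fold ROC), `scores`
#'   (out-of-fold poor-class probabilities).
#' @export
tumor_only_tsh_model <- function(abundances, tsh_groups, seed = 1L,
                                 cv_folds = 10L, ntree = 200L) {
  x <- if (inherits(abundances, "abundance_profile"))
    abundance_matrix(abundances) else as.matrix(abundances)
  y <- droplevels(as.factor(tsh_groups))
  if (nlevels(y) != 2) stopf("tsh_groups must have exactly two classes")
  set.seed(seed)
  folds <- make_folds(y, cv_folds)
  selected <- character(0)
  best_auc <- 0
  repeat {
    cand <- setdiff(colnames(x), selected)
    if (!length(cand)) break
    aucs <- vapply(cand, function(ft)
      cv_auc(x[, c(selected, ft), drop = FALSE], y, folds, ntree), numeric(1))
    if (max(aucs) <= best_auc + 1e-6) break
    best_auc <- max(aucs)
    selected <- c(selected, cand[which.max(aucs)])
  }
  if (!length(selected)) selected <- colnames(x)[1]
  ## out-of-fold scores of the final feature set
  scores <- numeric(length(y))
  for (k in sort(unique(folds))) {
    test <- folds == k
    fit <- randomForest::randomForest(
      x = x[!test, selected, drop = FALSE], y = y[!test], ntree = ntree)
    scores[test] <- stats::predict(
      fit, x[test, selected, drop = FALSE], type = "prob")[, "poor"]
  }
  roc <- roc_auc(scores, y == "poor")
  yp <- youden_point(scores, y == "poor")
  model <- train_classifier(x[, selected, drop = FALSE], y, seed = seed,
                            ntree = ntree)
  list(model = model, features = selected, auc = roc$auc,
       sensitivity = yp$sensitivity, specificity = yp$specificity,
       roc = roc, scores = scores)
}

## ---- prognostic validation -------------------------------------------------

#' Prognostic validation of a signature model
#'
#' Scores the feature table, splits patients at `threshold` (score above the
#' threshold = predicted poor), censors follow-up at `horizon_years`, and
#' reports Kaplan-Meier curves, the two-group log-rank test, the
#' group-adjusted multivariate Cox model (clinical covariates + predicted
#' group), and the likelihood-ratio test of that model against the
#' clinical-covariates-only model.
#'
#' @param model A `signature_model`.
#' @param features Feature table with a `patient` column (or rownames).
#' @param survival data.frame: patient, time, event, plus clinical columns.
#' @param threshold Score threshold, default `model$threshold` (0.5).
#' @param clinical Clinical covariate columns for adjustment; defaults to
#'   the available subset of age, ER, PR, HER2 and tumor size.
#' @param horizon_years Administrative censoring horizon, default 10.
#' @return List: `scores`, `groups`, `km`, `logrank`, `cox`, `lr` and
#'   `group_hr` (adjusted hazard ratio of the predicted-poor group).
#' @export
validate_prognosis <- function(model, features, survival,
                               threshold = model$threshold,
                               clinical = intersect(
                                 c("age", "er", "pr", "her2", "size"),
                                 names(survival)),
                               horizon_years = 10) {
  ids <- if ("patient" %in% names(features)) features$patient
         else rownames(features)
  if (is.null(ids)) stopf("features need a patient column or rownames")
  ftab <- features[, setdiff(colnames(features), "patient"), drop = FALSE]
  scores <- predict_score(model, ftab)
  pred_group <- factor(ifelse(scores > threshold, "poor", "good"),
                       levels = c("good", "poor"))
  dat <- merge(data.frame(patient = ids, score = scores,
                          pred_group = pred_group),
               survival, by = "patient")
  if (nrow(dat) == 0) stopf("no patients shared between features and survival")
  dat <- censor_at(dat, horizon_years)
  if (nlevels(droplevels(dat$pred_group)) < 2)
    stopf("degenerate grouping: all predicted scores fall on one side of the threshold")
  km <- km_curve(dat, dat$pred_group)
  lrk <- logrank_test(dat, dat$pred_group)
  fit_clin <- cox_fit(dat, clinical)
  fit_full <- cox_fit(dat, c(clinical, "pred_group"))
  lrt <- lr_test(fit_clin, fit_full)
  grp_row <- grep("pred_group", fit_full$table$feature)
  list(scores = scores, groups = pred_group, km = km, logrank = lrk,
       cox = fit_full, lr = lrt,
       group_hr = fit_full$table$hr[grp_row])
}

#' Published six-feature radiogenomic signature preset
#'
#' The reported predictive model retained six features: tumor flatness,
#' tumor sphericity, long-run high gray-level emphasis from the tumor on the
#' precontrast image, IDMN from the tumor on the postcontrast subtraction,
#' and IDMN and GLSZM gray-level non-uniformity from the stroma. Shipped as
#' a named preset so new data can be scored on these columns without
#' re-running the GA; it is a published outcome on cohort data, not an
#' expected GA result on synthetic data.
#'
#' @return Character vector of six feature names in this package's schema.
#' @export
paper_signature <- function() {
  c("tumor_shape_flatness",
    "tumor_shape_sphericity",
    "tumor_S0_glrlm_long_run_high_gray_level_emphasis",
    "tumor_SL_glcm_idmn",
    "stroma_S0_glcm_idmn",
    "stroma_S0_glszm_gray_level_nonuniformity")
}
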