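# Collinearity pruning, ROC/AUC, GA feature selection, the random-forest
# signature, the tumor-only abundance model, and prognostic validation.

test_that("prune_collinear removes exactly the offending features", {
  set.seed(1)
  x <- data.frame(a = rnorm(80))
  x$b <- x$a                      # duplicate
  x$c <- rnorm(80)
  out <- prune_collinear(x)
  expect_equal(ncol(out), 2)
  expect_true("c" %in% names(out))
  expect_equal(sum(c("a", "b") %in% names(out)), 1)

  ## orthogonal features are untouched
  set.seed(2)
  o <- as.data.frame(matrix(rnorm(400), 100, 4))
  expect_identical(names(prune_collinear(o)), names(o))

  ## r(1,2) = 0.9, feature 3 independent -> one of {f1, f2} dropped, f3 kept
  set.seed(3)
  f1 <- rnorm(200); f2 <- 0.9 * f1 + sqrt(1 - 0.81) * rnorm(200)
  tab <- data.frame(f1 = f1, f2 = f2, f3 = rnorm(200))
  out2 <- prune_collinear(tab, r_max = 0.8)
  expect_true("f3" %in% names(out2))
  expect_equal(ncol(out2), 2)

  ## post-condition: no remaining pair above the threshold
  set.seed(4)
  big <- as.data.frame(matrix(rnorm(50 * 12), 50, 12))
  big[, 2] <- big[, 1] + rnorm(50, 0, 0.1)
  big[, 5] <- -big[, 4] + rnorm(50, 0, 0.05)  # strong negative pair
  pruned <- prune_collinear(big, r_max = 0.8)
  r <- abs(cor(pruned)); diag(r) <- 0
  expect_lte(max(r), 0.8)
})

test_that("AUC equals exhaustive pair counting, including ties", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(1:10, c(rep(0, 5), rep(1, 5)))$auc, 1)
  expect_equal(roc_auc(10:1, c(rep(0, 5), rep(1, 5)))$auc, 0)

  set.seed(6)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }

  at <- roc_auc(c(0.2, 0.6, 0.7, 0.9), c(0, 0, 1, 1), threshold = 0.65)
  expect_equal(at$sensitivity, 1)
  expect_equal(at$specificity, 1)
})

test_that("GA recovers a planted informative feature and keeps elitism monotone", {
  set.seed(10)
  n <- 200
  x <- matrix(rnorm(n * 21), n, 21,
              dimnames = list(NULL, c("signal", paste0("noise", 1:20))))
  y <- factor(ifelse(x[, "signal"] + rnorm(n, 0, 0.55) > 0, "poor", "good"))
  sel <- ga_select(as.data.frame(x), y,
                   ga_config(population_size = 16, generations = 8,
                             cv_folds = 5, ntree = 30, seed = 5))
  expect_true("signal" %in% sel$features)
  expect_true(all(diff(sel$trajectory) >= -1e-12))
  expect_gt(sel$fitness, 0.8)

  ## determinism under the seed
  sel2 <- ga_select(as.data.frame(x), y,
                    ga_config(population_size = 16, generations = 8,
                              cv_folds = 5, ntree = 30, seed = 5))
  expect_identical(sel$features, sel2$features)
  expect_equal(sel$fitness, sel2$fitness)
})

test_that("all-noise features give chance-level GA performance", {
  set.seed(20)
  n <- 200
  x <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  y <- factor(rep(c("good", "poor"), each = n / 2))
  sel <- ga_select(x, y, ga_config(population_size = 10, generations = 4,
                                   cv_folds = 5, ntree = 30, seed = 2))
  ## the search maximum is optimistically biased; the selected model scored
  ## on independently generated null data is chance level
  m <- train_classifier(x[, sel$features, drop = FALSE], y, seed = 2,
                        ntree = 50)
  x_new <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  names(x_new) <- names(x)
  auc_indep <- roc_auc(predict_score(m, x_new), y == "poor")$auc
  expect_gt(auc_indep, 0.38)
  expect_lt(auc_indep, 0.62)
  expect_gte(sel$fitness, sel$cv_auc - 0.1)
})

test_that("the classifier is deterministic and separates separable data", {
  set.seed(30)
  n <- 100
  x <- data.frame(u = c(rnorm(n / 2, -2), rnorm(n / 2, 2)), v = rnorm(n))
  y <- factor(rep(c("good", "poor"), each = n / 2))
  m1 <- train_classifier(x, y, seed = 4, ntree = 100)
  m2 <- train_classifier(x, y, seed = 4, ntree = 100)
  s1 <- predict_score(m1, x); s2 <- predict_score(m2, x)
  expect_identical(s1, s2)
  expect_equal(roc_auc(s1, y == "poor")$auc, 1)
  expect_error(predict_score(m1, x["u"]), "absent")
})

test_that("the tumor-only model recovers planted predictor pairs", {
  set.seed(40)
  n <- 160
  ab <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  names(ab) <- cell_types()
  ## group determined by two populations only
  lin <- ab[["Cytotoxic lymphocytes"]] - ab[["Fibroblasts"]]
  groups <- factor(ifelse(lin > 0, "good", "poor"), levels = c("good", "poor"))
  fit <- tumor_only_tsh_model(ab, groups, seed = 3, cv_folds = 5, ntree = 150)
  expect_true(all(c("Cytotoxic lymphocytes", "Fibroblasts") %in% fit$features))
  expect_gt(fit$auc, 0.95)

  ## null labels: chance AUC
  null_groups <- factor(sample(rep(c("good", "poor"), each = n / 2)))
  null_fit <- tumor_only_tsh_model(ab, null_groups, seed = 3, cv_folds = 5,
                                   ntree = 100)
  expect_gt(null_fit$auc, 0.35)
  expect_lt(null_fit$auc, 0.65)

  ## perfectly separating single feature: sens = spec = 1 at the Youden point
  sep <- ab
  sep[["Cytotoxic lymphocytes"]] <- ifelse(groups == "poor", 5, -5)
  pf <- tumor_only_tsh_model(sep, groups, seed = 3, cv_folds = 5, ntree = 100)
  expect_equal(pf$sensitivity, 1)
  expect_equal(pf$specificity, 1)
})

test_that("prognostic validation wires scores into survival statistics", {
  set.seed(50)
  n <- 200
  groups <- setNames(rep(c("good", "poor"), each = n / 2), sprintf("P%d", 1:n))
  cfg <- cohort_config(n_patients = n, hazard_ratio = 3,
                       baseline_hazard = 0.12, censor_rate = 0.15, seed = 50)
  sv <- generate_survival(groups, cfg)
  ## features that encode the group cleanly
  ft <- data.frame(patient = names(groups),
                   marker = ifelse(groups == "poor", 1, 0) + rnorm(n, 0, 0.1),
                   junk = rnorm(n))
  model <- train_classifier(ft[, c("marker", "junk")],
                            factor(unname(groups), levels = c("good", "poor")),
                            seed = 6, ntree = 100)
  vp <- validate_prognosis(model, ft, sv)
  expect_lt(vp$logrank$p, 0.01)
  expect_gt(vp$group_hr, 1.5)
  expect_lt(vp$lr$p, 0.01)
  expect_named(vp$km, c("group", "time", "n_risk", "n_event", "n_censor",
                        "surv"))

  ## LR test of a model against itself is p = 1
  dat <- censor_at(merge(sv, data.frame(patient = ft$patient)))
  f <- cox_fit(dat, c("age", "size"))
  expect_equal(lr_test(f, f)$p, 1)
})

test_that("the published six-feature preset names resolve in the layout", {
  ph <- small_phantom(seed = 12)
  pr <- prep_patient(ph)
  fv <- extract_all(pr$phases, pr$tumor_mask, pr$stroma_mask)
  expect_true(all(paper_signature() %in% names(fv)))
  expect_length(paper_signature(), 6)
})
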