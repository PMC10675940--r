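# TSH ratio, stratification, censoring, and the survival statistics layer.

test_that("tsh_score matches the ratio definition and its invariances", {
  expect_equal(tsh_score(1, 1), 0)
  expect_equal(tsh_score(2, 1), 1)
  ## ratio of the published poor-group tumor/stroma means
  expect_equal(tsh_score(0.3531, 0.9631), -0.6334, tolerance = 1e-4)
  ## scale invariance
  for (k in c(0.5, 2, 17)) {
    expect_equal(tsh_score(k * 1.3, k * 0.7), tsh_score(1.3, 0.7))
  }
  expect_error(tsh_score(1, 0), "undefined")
  expect_error(tsh_score(c(a = 1, b = 2), c(a = 1, b = 1e-12)), "b")
})

test_that("stratify labels good above the threshold with ties to poor", {
  thr <- tsh_threshold_default()
  expect_equal(thr, 0.3512)
  g <- stratify(c(0.3512, 0.36, -0.2), thr)
  expect_equal(as.character(g), c("poor", "good", "poor"))
  expect_error(stratify(c(1, NA)), "finite")
  ## all-equal input collapses to one group and log-rank refuses it
  same <- stratify(rep(0.2, 6), thr)
  rec <- data.frame(time = 1:6, event = rep(1, 6))
  expect_error(logrank_test(rec, same), "degenerate")
})

test_that("censor_at truncates beyond the horizon only", {
  rec <- data.frame(time = c(12, 10, 3.45), event = c(1, 1, 0))
  out <- censor_at(rec, 10)
  expect_equal(out$time, c(10, 10, 3.45))
  expect_equal(out$event, c(0, 1, 0))
})

test_that("km_curve reproduces the product-limit estimator", {
  rec <- data.frame(time = c(1, 2, 3), event = c(1, 1, 1))
  km <- km_curve(rec)
  expect_equal(km$surv, c(2/3, 1/3, 0))

  none <- data.frame(time = c(2, 4, 6), event = c(0, 0, 0))
  expect_true(all(km_curve(none)$surv == 1))

  ## uncensored data: KM equals the empirical survival function
  set.seed(31)
  t_ <- round(rexp(40, 0.3), 3)
  kmu <- km_curve(data.frame(time = t_, event = 1))
  expect_equal(kmu$surv, vapply(kmu$time, function(x) mean(t_ > x), 1))
})

test_that("log-rank matches the hand-built expected/observed oracle", {
  time <- c(1, 2, 3, 4, 2.5, 5)
  event <- c(1, 1, 0, 1, 1, 1)
  group <- c("a", "a", "a", "b", "b", "b")
  ours <- logrank_test(data.frame(time = time, event = event), group)
  want <- oracle_logrank(time, event, group)
  expect_equal(ours$statistic, want$statistic, tolerance = 1e-10)
  expect_equal(ours$p, want$p, tolerance = 1e-10)

  ## identical groups: statistic 0
  rec <- data.frame(time = rep(c(1, 3, 7), 2), event = rep(c(1, 0, 1), 2))
  same <- logrank_test(rec, rep(c("x", "y"), each = 3))
  expect_lt(same$statistic, 1e-10)
  expect_equal(same$p, 1, tolerance = 1e-6)
})

test_that("log-rank p is uniform under label permutation", {
  set.seed(17)
  rec <- data.frame(time = rexp(60, 0.2), event = rbinom(60, 1, 0.8))
  ps <- replicate(400, {
    logrank_test(rec, sample(rep(c("a", "b"), 30)))$p
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cox_fit recovers planted effects and rejects degenerate input", {
  groups <- setNames(rep(c("good", "poor"), each = 250), sprintf("P%d", 1:500))
  cfg <- cohort_config(n_patients = 500, hazard_ratio = 0.38,
                       baseline_hazard = 0.15, censor_rate = 0.1, seed = 3)
  ## hazard_ratio below 1: poor group protective in this parameterization
  sv <- generate_survival(groups, cfg)
  fit <- cox_fit(sv, "group")
  expect_gt(fit$table$hr[1], 0.2)
  expect_lt(fit$table$hr[1], 0.7)
  expect_equal(fit$table$p[1],
               pchisq(fit$table$wald[1], 1, lower.tail = FALSE))

  sv$flat <- 1
  expect_error(cox_fit(sv, "flat"), "constant covariate")
  expect_error(cox_fit(sv, "nope"), "not in records")
})

test_that("null covariates stay within 2 SE of zero most of the time", {
  hits <- 0L
  for (s in 1:40) {
    set.seed(100 + s)
    n <- 120
    rec <- data.frame(time = rexp(n, 0.2), event = rbinom(n, 1, 0.85),
                      x = rnorm(n))
    fit <- cox_fit(rec, "x")
    se <- fit$table$beta[1] / sign(fit$table$beta[1]) /
      sqrt(fit$table$wald[1])
    hits <- hits + (abs(fit$table$beta[1]) < 2 * se)
  }
  expect_gte(hits / 40, 0.9)
})

test_that("lr_test behaves on nested, identical and df-1 cases", {
  set.seed(5)
  n <- 150
  rec <- data.frame(time = rexp(n, 0.3), event = rbinom(n, 1, 0.9),
                    x = rnorm(n))
  rec$time <- rexp(n, 0.3 * exp(0.8 * rec$x))
  rec$z <- rnorm(n)
  f1 <- cox_fit(rec, "z")
  f2 <- cox_fit(rec, c("z", "x"))
  out <- lr_test(f1, f2)
  expect_equal(out$df, 1)
  expect_lt(out$p, 0.05)
  expect_equal(lr_test(f1, f1)$p, 1)
  ## chi-square reference: 2*dlogL = 3.84 at df 1 sits at p ~ 0.05
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 1e-2)
  expect_error(lr_test(f2, f1), "nested")
})

test_that("bh_adjust is the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  ## rank-1 p of 0.00018 among 10 tests adjusts to 0.0018
  p10 <- c(0.00018, seq(0.1, 0.9, length.out = 9))
  expect_equal(bh_adjust(p10)[1], 0.0018)
  p <- c(0.001, 0.5, 0.03, 0.8)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("wilcoxon signed-rank matches exhaustive sign enumeration at n = 6", {
  a <- c(1.2, 2.4, 0.7, 3.3, 2.2, 1.9)
  b <- c(0.8, 2.9, 0.1, 2.0, 2.5, 0.7)  # untied |differences| -> exact path
  ours <- wilcoxon_signed_rank(a, b)
  expect_equal(ours$p, oracle_wilcoxon_p(a - b), tolerance = 1e-12)

  expect_warning(res <- wilcoxon_signed_rank(1:4, 1:4), "zero difference")
  expect_equal(res$p, 1)

  set.seed(9)
  x <- rnorm(50); y <- x + 5 + rnorm(50, 0, 0.1)
  big <- wilcoxon_signed_rank(y, x)
  expect_lt(big$p, 1e-6)
})

test_that("the univariate TSH sweep yields the 10-row report layout", {
  fx <- small_cohort(n = 80, noise_sd = 0.3, seed = 13,
                     latent_sd = c(good = 0.2, poor = 0.2))
  tum <- estimate_abundance(fx$cohort$tumor, fx$markers, "tumor")
  str <- estimate_abundance(fx$cohort$stroma, fx$markers, "stroma")
  tt <- tsh_table(tum, str)
  sv <- censor_at(generate_survival(fx$cohort$groups, fx$config))
  sweep_tab <- univariate_tsh_sweep(tt, sv)
  expect_equal(nrow(sweep_tab), 10)
  expect_named(sweep_tab, c("feature", "beta", "hr", "ci_low", "ci_high",
                            "wald", "p", "corrected_p"))
  expect_true(all(sweep_tab$corrected_p >= sweep_tab$p))
  expect_true(all(is.finite(sweep_tab$beta)))
})
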