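test_that("centering subtracts the mean, stores it, and is idempotent", {
  x <- center(c(1, 2, 3))
  expect_equal(as.numeric(x), c(-1, 0, 1))
  expect_equal(attr(x, "center"), 2)
  expect_lt(abs(mean(center(rnorm(50, 100, 3)))), 1e-12)
  expect_equal(as.numeric(center(as.numeric(x))), as.numeric(x))
  expect_error(center(c(NA_real_, NA_real_)), class = "segspeech_schema_error")
})

test_that("design matrix has the published 9-column structure", {
  cohort <- small_cohort(n = 40, seed = 2)
  dm <- design_matrix(cohort, "seg_dmn")
  expect_equal(ncol(dm$X), 9)  # intercept, age, stroop, metric, 2 products,
                               # education, 2 project dummies
  expect_equal(sum(grepl("^project", colnames(dm$X))), 2)
  expect_equal(dm$X[, "age_x_metric"], dm$X[, "age_c"] * dm$X[, "metric_c"])
  expect_equal(dm$X[, "age_x_stroop"], dm$X[, "age_c"] * dm$X[, "stroop_c"])
  expect_lt(abs(mean(dm$X[, "age_c"])), 1e-12)
  expect_lt(abs(mean(dm$X[, "metric_c"])), 1e-12)
  # education stays in raw years
  expect_equal(dm$X[, "education"], as.numeric(cohort$education))
  expect_error(design_matrix(cohort, "not_a_column"),
               "not_a_column", class = "segspeech_schema_error")
})

test_that("OLS matches hand-computed normal equations on a toy problem", {
  X <- cbind("(Intercept)" = 1, x = c(0, 1, 2, 3))
  fit <- ols_fit(X, c(1, 2, 2, 4))
  expect_equal(fit$coefficients$estimate, c(0.9, 0.9))
  # exact linear data
  fit2 <- ols_fit(cbind("(Intercept)" = 1, x = 1:10), 2 * (1:10))
  expect_equal(fit2$coefficients$estimate, c(0, 2))
  expect_equal(fit2$r_squared, 1)
  expect_lt(max(abs(fit2$residuals)), 1e-12)
})

test_that("OLS equals the pseudoinverse oracle on random instances", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(20:50, 1)
    p <- sample(3:9, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
    y <- rnorm(n)
    fit <- ols_fit(X, y)
    expect_equal(fit$coefficients$estimate, pinv_coefs(X, y), tolerance = 1e-10)
    # residual orthogonality
    expect_lt(max(abs(crossprod(X, fit$residuals))), 1e-8)
    # full inference against lm
    lf <- lm(y ~ X - 1)
    sm <- summary(lf)$coefficients
    expect_equal(fit$coefficients$se, unname(sm[, 2]), tolerance = 1e-10)
    expect_equal(fit$coefficients$p, unname(sm[, 4]), tolerance = 1e-10)
    ci <- confint(lf)
    expect_equal(fit$coefficients$ci_lo, unname(ci[, 1]), tolerance = 1e-10)
    expect_equal(fit$coefficients$ci_hi, unname(ci[, 2]), tolerance = 1e-10)
  }
})

test_that("rank deficiency errors name the collinear columns", {
  X <- cbind("(Intercept)" = 1, a = 1:20, dup = 2 * (1:20))
  expect_error(ols_fit(X, rnorm(20)), "dup", class = "segspeech_rank_error")
  expect_error(ols_fit(X[1:2, ], rnorm(2)), class = "segspeech_degenerate_error")
})

test_that("Cook's distance matches the leave-one-out refit oracle", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 25
    X <- cbind("(Intercept)" = 1, x = rnorm(n), z = rnorm(n))
    y <- X[, 2] + rnorm(n)
    fit <- ols_fit(X, y)
    d <- cooks_screen(fit)$cooks_d
    expect_equal(unname(d), loo_cooks(X, y), tolerance = 1e-10)
  }
})

test_that("a single gross outlier in a line of points is the only flag", {
  x <- 1:21
  y <- 2 * x
  y[11] <- y[11] + 40
  fit <- ols_fit(cbind("(Intercept)" = 1, x = x), y)
  scr <- cooks_screen(fit)
  expect_equal(scr$flagged_ids, "11")
  expect_equal(scr$refit$n, 20)
  expect_equal(scr$refit$excluded_ids, "11")
  expect_equal(scr$refit$coefficients$estimate, c(0, 2), tolerance = 1e-10)
  # perfectly balanced data below threshold flags nothing
  fit2 <- ols_fit(cbind("(Intercept)" = 1, x = rep(c(-1, 1), 10)),
                  rep(c(-1, 1), 10) + rep(c(-0.1, 0.1), each = 10))
  scr2 <- cooks_screen(fit2)
  expect_length(scr2$flagged_ids, 0)
  expect_identical(scr2$refit$n, fit2$n)
})

test_that("BH q-values match the brute-force step-up definition", {
  expect_equal(bh_fdr(0.031), 0.031)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 6)), rep(0.2, 6))
  set.seed(14)
  for (m in c(3, 7, 12, 20)) {
    p <- runif(m)
    expect_equal(bh_fdr(p), stepup_bh(p))
  }
  # ties preserved
  p <- c(0.01, 0.01, 0.5, 0.5, 0.03)
  expect_equal(bh_fdr(p), stepup_bh(p))
  # families adjusted independently
  p2 <- c(0.01, 0.04, 0.01, 0.04)
  fam <- c("a", "a", "b", "b")
  expect_equal(bh_fdr(p2, fam), c(stepup_bh(p2[1:2]), stepup_bh(p2[3:4])))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "segspeech_parameter_error")
})

test_that("the battery always produces 18 models and two FDR families", {
  cohort <- small_cohort(n = 80, seed = 9)
  bat <- run_battery(cohort)
  expect_length(bat$fits, 18)
  expect_equal(nrow(bat$table), 36)  # metric main + interaction per model
  expect_equal(sum(bat$table$fdr_family == "metric_main"), 18)
  expect_equal(sum(bat$table$fdr_family == "age_x_metric"), 18)
  expect_true(all(bat$table$q >= 0 & bat$table$q <= 1))
  # q within a family matches a direct BH pass
  for (fam in c("metric_main", "age_x_metric")) {
    idx <- bat$table$fdr_family == fam
    expect_equal(bat$table$q[idx], stepup_bh(bat$table$p[idx]))
  }
  # within/between families use their own metric columns
  batw <- run_battery(cohort, family = "within")
  expect_length(batw$fits, 18)
})

test_that("battery is listwise-complete per model", {
  cohort <- small_cohort(n = 60, seed = 10)
  cohort$stroop[1:3] <- NA
  fit <- fit_disfluency_model(cohort, "revision_pct", "dmn", cooks = FALSE)
  expect_equal(fit$n, 57)
})

test_that("type-I error for the segregation term is calibrated under the null", {
  p <- generator_params()
  p$seg_slopes[] <- 0
  p$disfluency_coefs$age <- 0
  p$disfluency_coefs$seg <- 0
  p$disfluency_coefs$age_x_seg <- 0
  reps <- 500
  pvals <- vapply(seq_len(reps), function(r) {
    cohort <- simulate_cohort(p, seed = 40000 + r)
    fit <- fit_disfluency_model(cohort, "revision_pct", "dmn", cooks = FALSE)
    fit$coefficients$p[fit$coefficients$term == "metric_c"]
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
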