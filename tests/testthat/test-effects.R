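test_that("simple slope at offset 0 equals the focal coefficient exactly", {
  cohort <- small_cohort(n = 80, seed = 4)
  fit <- fit_disfluency_model(cohort, "repetition_pct", "dmn", cooks = FALSE)
  ss <- simple_slope(fit, offsets = 0)
  expect_identical(ss$slope,
                   fit$coefficients$estimate[fit$coefficients$term == "metric_c"])
  expect_identical(ss$se,
                   fit$coefficients$se[fit$coefficients$term == "metric_c"])
  expect_error(simple_slope(fit, interaction = "nope"),
               class = "segspeech_usage_error")
})

test_that("simple-slope SE matches a direct delta-method evaluation", {
  cohort <- small_cohort(n = 100, seed = 6)
  fit <- fit_disfluency_model(cohort, "repetition_pct", "dmn", cooks = FALSE)
  off <- c(-17.1, 5, 17.1)
  ss <- simple_slope(fit, offsets = off)
  V <- fit$vcov
  for (k in seq_along(off)) {
    g <- c(1, off[k])
    vv <- V[c("metric_c", "age_x_metric"), c("metric_c", "age_x_metric")]
    expect_equal(ss$se[k], sqrt(as.numeric(t(g) %*% vv %*% g)))
  }
})

test_that("published worked examples round-trip through the slope formula", {
  expect_lt(abs(conditional_slope(-0.64, 0.042, -17.1) - (-1.35)), 0.02)
  expect_lt(abs(conditional_slope(-0.64, 0.042, +17.1) - 0.08), 0.02)
})

test_that("Johnson-Neyman boundaries solve the hand-built quadratic", {
  # b_f = 1, b_i = 1, V = diag(0.04, 0.01), t_crit = 2:
  # roots at -1.5 and -7/12
  fit <- structure(
    list(
      coefficients = tibble::tibble(
        term = c("metric_c", "age_c", "age_x_metric"),
        estimate = c(1, 0, 1), se = c(0.2, 1, 0.1),
        t = 0, p = 1, ci_lo = 0, ci_hi = 0
      ),
      vcov = matrix(diag(c(0.04, 1, 0.01)), 3, 3,
                    dimnames = list(c("metric_c", "age_c", "age_x_metric"),
                                    c("metric_c", "age_c", "age_x_metric"))),
      df = 1e9,
      X = cbind(metric_c = 0, age_c = c(-10, 10), age_x_metric = 0)
    ),
    class = "segspeech_fit"
  )
  # with df huge, t_crit -> 1.96; force exactly 2 via alpha
  alpha <- 2 * pnorm(-2)
  jn <- johnson_neyman(fit, alpha = alpha)
  expect_equal(jn$t_crit, 2, tolerance = 1e-6)
  expect_equal(jn$all_roots, c(-1.5, -7 / 12), tolerance = 1e-6)
  expect_false(isTRUE(jn$significant_inside))
})

test_that("JN boundary identity holds and matches a grid-search oracle", {
  cohort <- small_cohort(n = 252, seed = 12)
  fit <- fit_disfluency_model(cohort, "repetition_pct", "dmn", cooks = FALSE)
  jn <- johnson_neyman(fit)
  expect_length(jn$all_roots, 2)
  b_f <- fit$coefficients$estimate[fit$coefficients$term == "metric_c"]
  b_i <- fit$coefficients$estimate[fit$coefficients$term == "age_x_metric"]
  V <- fit$vcov
  tstat <- function(x) {
    abs(b_f + b_i * x) /
      sqrt(V["metric_c", "metric_c"] + 2 * x * V["metric_c", "age_x_metric"] +
             x^2 * V["age_x_metric", "age_x_metric"])
  }
  for (r in jn$all_roots) {
    expect_equal(tstat(r), jn$t_crit, tolerance = 1e-8)
  }
  # grid-search oracle at 1e-4 steps: sign changes of |t| - t_crit
  grid <- seq(min(jn$all_roots) - 5, max(jn$all_roots) + 5, by = 1e-4)
  f <- tstat(grid) - jn$t_crit
  crossings <- grid[which(diff(sign(f)) != 0)]
  for (r in jn$all_roots) {
    expect_lt(min(abs(crossings - r)), 1e-3)
  }
})

test_that("mediation decomposition identities hold at machine precision", {
  for (seed in c(3, 17, 29)) {
    cohort <- small_cohort(n = 90, seed = seed, mode = "mediation")
    mp <- mediation_paths(cohort)
    est <- setNames(mp$paths$estimate, mp$paths$path)
    expect_equal(est[["a"]] * est[["b"]] + est[["c_prime"]], est[["c"]],
                 tolerance = 1e-12)
    med <- mediate(cohort, B = 100, seed = 1)
    expect_equal(med$acme$estimate, est[["a"]] * est[["b"]], tolerance = 1e-12)
    expect_equal(med$acme$estimate + med$ade$estimate, med$total$estimate,
                 tolerance = 1e-12)
  }
})

test_that("bootstrap mediation is seed-deterministic and null-calibrated", {
  cohort <- small_cohort(n = 120, seed = 7, mode = "mediation")
  m1 <- mediate(cohort, B = 200, seed = 42)
  m2 <- mediate(cohort, B = 200, seed = 42)
  expect_identical(m1$acme, m2$acme)
  expect_identical(m1$ade, m2$ade)
  expect_false(identical(m1$acme$ci, mediate(cohort, B = 200, seed = 43)$acme$ci))
  expect_error(mediate(cohort, B = 50), class = "segspeech_parameter_error")

  # mediator unrelated to outcome: ACME CI covers 0
  p <- generator_params(n_participants = 150)
  p$mediation_coefs$b <- 0
  null_cohort <- simulate_cohort(p, mode = "mediation", seed = 8)
  m0 <- mediate(null_cohort, B = 300, seed = 1)
  expect_lte(m0$acme$ci[1], 0)
  expect_gte(m0$acme$ci[2], 0)
})

test_that("mediation recovers a known decomposition at large n", {
  set.seed(61)
  n <- 2000
  age <- rnorm(n, 50, 10)
  age_c <- age - mean(age)
  m <- 0.5 * age_c + rnorm(n)
  y <- 0.2 * age_c + 0.4 * m + rnorm(n)
  data <- tibble::tibble(age = age, med = m, out = y)
  res <- mediate(data, treatment = "age", mediator = "med", outcome = "out",
                 covariates = character(), B = 300, seed = 2)
  expect_equal(res$acme$estimate, 0.2, tolerance = 0.03)
  expect_equal(res$prop_mediated$estimate, 0.5, tolerance = 0.05)
})

test_that("proportion mediated handles signs, zeros, and the printed case", {
  pm <- proportion_mediated(0.0012, 0.0046)
  expect_equal(pm$proportion, 0.2069, tolerance = 2e-4)
  expect_equal(100 * pm$proportion, 20.6, tolerance = 0.2)
  expect_false(pm$unstable)
  expect_equal(proportion_mediated(0.3, 0)$proportion, 1)
  expect_equal(proportion_mediated(0, 0.3)$proportion, 0)
  expect_true(proportion_mediated(0.4, -0.1)$unstable)
  expect_false(proportion_mediated(-0.002, -0.004)$unstable)
  und <- proportion_mediated(0.2, -0.2)
  expect_false(und$defined)
  expect_true(is.na(und$proportion))
})

test_that("serial mediation is licensed only when the metric predicts EF", {
  # null prerequisite: default generator has no segregation -> Stroop path
  cohort <- small_cohort(n = 200, seed = 19, mode = "mediation")
  res <- serial_check(cohort)
  expect_s3_class(res$prerequisite, "tbl_df")
  expect_false(res$licensed)
  expect_true(is.na(res$serial_indirect))

  # strong built-in path licenses the serial decomposition
  set.seed(77)
  n <- 300
  age <- rnorm(n, 50, 15)
  seg <- 0.5 - 0.002 * (age - 50) + rnorm(n, 0, 0.05)
  ef <- 60 - 400 * (seg - 0.5) + rnorm(n, 0, 10)
  y <- 3 + 0.004 * (age - 50) - 0.02 * ef + rnorm(n, 0, 0.3)
  data <- tibble::tibble(age = age, seg_dmn = seg, stroop = ef,
                         revision_pct = y,
                         education = 16, project = rep(c("a", "b"), n / 2))
  data$education <- sample(12:20, n, replace = TRUE)
  res2 <- serial_check(data, covariates = c("education", "project"))
  expect_true(res2$licensed)
  expect_false(is.na(res2$serial_indirect))
  # a1 ~ -0.002, d21 ~ -400, b2 ~ -0.02: the serial indirect effect is negative
  expect_lt(res2$serial_indirect, 0)
})
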