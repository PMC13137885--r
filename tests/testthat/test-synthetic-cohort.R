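test_that("generator parameters validate their invariants", {
  expect_error(generator_params(n_participants = 5),
               class = "segspeech_parameter_error")
  expect_error(generator_params(age_range = c(81, 20)),
               class = "segspeech_parameter_error")
  expect_error(generator_params(stroop_resid_sd = 0),
               class = "segspeech_parameter_error")
  p <- generator_params()
  expect_equal(p$n_participants, 252)
  expect_equal(p$age_mean, 46.83)
  expect_equal(p$age_sd, 17.1)
  expect_equal(p$stroop_slope, 1.72)
  expect_equal(unname(p$seg_slopes[["dmn"]]), -0.0023)
  expect_equal(p$mediation_coefs$a, -0.0023)
  expect_equal(p$mediation_coefs$b, -0.59)
  expect_equal(p$mediation_coefs$c_prime, 0.0046)
})

test_that("covariate simulation is seed-deterministic", {
  p <- generator_params(n_participants = 40)
  a <- simulate_covariates(p, seed = 9)
  b <- simulate_covariates(p, seed = 9)
  expect_identical(a, b)
  c <- simulate_covariates(p, seed = 10)
  expect_false(identical(a, c))
  # full-cohort determinism, including transcripts
  expect_identical(simulate_cohort(p, seed = 3), simulate_cohort(p, seed = 3))
  tr1 <- simulate_transcript(c(repetition = 4), 100, seed = 5)
  tr2 <- simulate_transcript(c(repetition = 4), 100, seed = 5)
  expect_identical(tr1, tr2)
})

test_that("noiseless Stroop generation recovers the slope exactly", {
  p <- generator_params(n_participants = 1000, stroop_resid_sd = 1e-12)
  cov <- simulate_covariates(p, seed = 2)
  b <- coef(lm(stroop ~ age, data = cov))[["age"]]
  expect_equal(b, 1.72, tolerance = 1e-8)
})

test_that("age distribution reproduces the cohort moments over replicates", {
  p <- generator_params()
  stats <- vapply(1:200, function(r) {
    a <- simulate_covariates(p, seed = 3000 + r)$age
    c(mean(a), sd(a), min(a), max(a))
  }, numeric(4))
  expect_equal(mean(stats[1, ]), 46.83, tolerance = 0.5)
  expect_equal(mean(stats[2, ]), 17.1, tolerance = 1.0)
  expect_gte(min(stats[3, ]), 20)
  expect_lte(max(stats[4, ]), 81)
})

test_that("zero-slope zero-noise disfluency generation returns intercepts", {
  p <- generator_params(n_participants = 30)
  p$disfluency_coefs$age <- 0
  p$disfluency_coefs$seg <- 0
  p$disfluency_coefs$age_x_seg <- 0
  p$disfluency_coefs$resid_sd <- rep(1e-300, 5)
  cohort <- simulate_cohort(p, seed = 4)
  for (i in seq_len(nrow(p$disfluency_coefs))) {
    expect_equal(cohort[[p$disfluency_coefs$outcome[i]]],
                 rep(p$disfluency_coefs$intercept[i], 30))
  }
  expect_equal(cohort$total_pct, rep(sum(p$disfluency_coefs$intercept), 30))
})

test_that("noiseless interaction generator refits to the coefficient exactly", {
  p <- generator_params(n_participants = 1000)
  i <- which(p$disfluency_coefs$outcome == "repetition_pct")
  p$disfluency_coefs$resid_sd[i] <- 1e-300
  cohort <- simulate_cohort(p, seed = 6)
  fit <- fit_disfluency_model(cohort, "repetition_pct", "dmn", cooks = FALSE)
  expect_equal(fit$coefficients$estimate[
    fit$coefficients$term == "age_x_metric"], 0.042, tolerance = 1e-9)
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "metric_c"],
               -0.63, tolerance = 1e-9)
})

test_that("mediation generator implies the printed total age effect", {
  p <- generator_params()
  implied <- p$mediation_coefs$a * p$mediation_coefs$b + p$mediation_coefs$c_prime
  expect_equal(implied, 0.005957)
  # agrees with the published (rounded) total effect at printed precision
  expect_lt(abs(implied - 0.006), 5e-4)
})

test_that("ground truth serializes and round-trips losslessly", {
  cohort <- small_cohort(n = 30, seed = 8, mode = "mediation")
  gt <- attr(cohort, "ground_truth")
  expect_s3_class(gt, "segspeech_ground_truth")
  path <- tempfile(fileext = ".json")
  write_ground_truth(gt, path)
  back <- read_ground_truth(path)
  expect_equal(back$mode, gt$mode)
  expect_equal(back$seed, gt$seed)
  expect_equal(back$seg_latent, gt$seg_latent)
  expect_equal(back$mediation_coefs$a, gt$mediation_coefs$a)
  expect_equal(as.data.frame(back$disfluency_coefs),
               as.data.frame(gt$disfluency_coefs))
})

test_that("timeseries generator hits trivial segregation endpoints", {
  atlas <- network_atlas()
  # W = B: segregation ~ 0
  p0 <- generator_params(
    n_timepoints = 2000,
    block_corr = list(within = c(language = 0.4, dmn = 0.4, md = 0.4),
                      between = 0.4)
  )
  m0 <- compute_network_metrics(simulate_timeseries(50, atlas, p0, seed = 1), atlas)
  expect_true(all(abs(m0$segregation) < 0.05))
  # B = 0: segregation ~ 1 (small epsilon from rectified sampling noise)
  p1 <- generator_params(
    n_timepoints = 2000,
    block_corr = list(within = c(language = 0.5, dmn = 0.5, md = 0.5),
                      between = 0)
  )
  m1 <- compute_network_metrics(simulate_timeseries(50, atlas, p1, seed = 1), atlas)
  expect_true(all(m1$segregation > 0.95))
})

test_that("timeseries generation is deterministic per participant index", {
  atlas <- network_atlas()
  p <- generator_params(n_timepoints = 150)
  a <- simulate_timeseries(60, atlas, p, seed = 2, participant_index = 3)
  b <- simulate_timeseries(60, atlas, p, seed = 2, participant_index = 3)
  c <- simulate_timeseries(60, atlas, p, seed = 2, participant_index = 4)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_error(
    simulate_timeseries(60, atlas, generator_params(n_timepoints = 50), seed = 1),
    class = "segspeech_parameter_error"
  )
})

test_that("non-positive-definite block request errors with the block values", {
  atlas <- network_atlas()
  p <- generator_params(
    n_timepoints = 300,
    block_corr = list(within = c(language = 0.1, dmn = 0.1, md = 0.1),
                      between = 1.2)
  )
  expect_error(simulate_timeseries(50, atlas, p, seed = 1),
               class = "segspeech_generator_error")
})

test_that("transcript generator inserts exact deterministic counts", {
  tr <- simulate_transcript(c(repetition = 5), n_words = 200, seed = 1)
  expect_equal(unname(tr$counts[["repetition"]]), 10L)
  expect_equal(tr$word_total, 200)
  z <- simulate_transcript(numeric(0), n_words = 50, seed = 1)
  expect_true(all(z$counts == 0L))
  expect_true(all(count_disfluencies(parse_chat(z$text)) == 0L))
  expect_error(simulate_transcript(c(filled = 60, repetition = 50), 100),
               class = "segspeech_parameter_error")
  expect_error(simulate_transcript(c(filled = -1), 100),
               class = "segspeech_parameter_error")
  expect_error(simulate_transcript(c(oops = 1), 100),
               class = "segspeech_parameter_error")
})
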