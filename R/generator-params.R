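#' Synthetic-cohort generator parameters
#'
#' Returns the parameter set that defines the simulated study conditions.
#' Defaults are calibrated to the published cohort: n = 252 adults with
#' observed age mean 46.83 y, SD 17.1 y on [20, 81]; Stroop interference
#' rising 1.72 ms/y; per-network segregation declining with age (DMN
#' -0.0023/y); disfluency outcomes following the fitted linear models; and
#' the mediation structure (a, b, c') = (-0.0023, -0.59, 0.0046) for
#' revisions. Residual SDs are back-calculated from the published standard
#' errors as `SE * SD(predictor) * sqrt(n)`, so simulated cohorts reproduce
#' the published sampling uncertainty, not an idealized low-noise regime.
#'
#' Outcome intercepts (baseline rates at mean age) are not published;
#' defaults are plausible naturalistic-speech rates chosen high enough that
#' the zero floor on percentages truncates a negligible share of draws under
#' the calibrated noise. Prolongations keep a low baseline, so their floor
#' produces realistic zero-inflation.
#'
#' @param ... Named overrides for any default component (see the returned
#'   list's names). Nested lists are merged shallowly.
#' @return A list of class `segspeech_params`.
#' @export
#' @examples
#' p <- generator_params(n_participants = 50)
#' p$mediation_coefs
generator_params <- function(...) {
  sd_age <- 17.1
  n_ref <- 252
  cal <- function(se, sd_pred = sd_age) se * sd_pred * sqrt(n_ref)
  seg_resid <- cal(0.001)                 # segregation-on-age models, SE 0.001
  sd_seg <- sqrt((0.0023 * sd_age)^2 + seg_resid^2)
  defaults <- list(
    n_participants = 252,
    age_mean = 46.83,
    age_sd = 17.1,
    age_range = c(20, 81),
    education_range = c(12, 22),
    projects = c("study1", "study2", "study3"),
    stroop_intercept = 60.45,
    stroop_slope = 1.72,
    stroop_resid_sd = cal(0.27),
    seg_intercepts = c(language = 0.5, dmn = 0.5, md = 0.5),
    seg_slopes = c(language = -0.002, dmn = -0.0023, md = -0.002),
    seg_resid_sd = c(language = seg_resid, dmn = seg_resid, md = seg_resid),
    within_fc_sd = 0.05,  # person-to-person spread of within-network z
    # per-outcome generative coefficients, percent units; seg terms refer to
    # DMN segregation (the network with published disfluency effects)
    disfluency_coefs = data.frame(
      outcome      = c("filled_pct", "unfilled_pct", "repetition_pct",
                       "revision_pct", "prolongation_pct"),
      intercept    = c(7.0, 6.0, 3.5, 3.0, 1.0),
      age          = c(-0.025, 0.017, 0.006, 0.006, -0.010),
      stroop       = c(0, 0, 0, 0, 0),
      seg          = c(0, 0, -0.63, -0.59, 0),
      age_x_stroop = c(0, 0, 0, 0, 0),
      age_x_seg    = c(0, 0, 0.042, 0, 0),
      resid_sd     = c(cal(0.008), cal(0.007), cal(0.014, sd_age * sd_seg),
                       cal(0.002), cal(0.008)),
      stringsAsFactors = FALSE
    ),
    mediation_coefs = list(
      a = -0.0023, b = -0.59, c_prime = 0.0046,
      m_intercept = 0.5, m_resid_sd = seg_resid,
      y_intercept = 3.0, y_resid_sd = cal(0.002)
    ),
    n_timepoints = 180,
    # block targets on the Fisher-z scale; between = NULL derives the
    # cross blocks from each participant's age-targeted segregation
    block_corr = list(within = c(language = 0.5, dmn = 0.5, md = 0.5),
                      between = NULL)
  )
  params <- modifyList(defaults, list(...))
  validate_params(params)
}

validate_params <- function(params) {
  if (params$n_participants < 10) {
    stop_segspeech("n_participants must be at least 10", "segspeech_parameter_error")
  }
  if (params$age_range[1] >= params$age_range[2]) {
    stop_segspeech("age_range low must be below high", "segspeech_parameter_error")
  }
  sds <- c(params$age_sd, params$stroop_resid_sd, params$seg_resid_sd,
           params$disfluency_coefs$resid_sd,
           params$mediation_coefs$m_resid_sd, params$mediation_coefs$y_resid_sd)
  if (any(!is.finite(sds)) || any(sds <= 0)) {
    stop_segspeech("all SDs must be positive and finite", "segspeech_parameter_error")
  }
  structure(params, class = "segspeech_params")
}

# Parent (mu0, sigma0) of a normal truncated to `range` whose *truncated*
# distribution has the requested mean and SD. The published moments describe
# the observed (already range-limited) sample, so the parent must be solved
# for; with a wide SD relative to the range this approaches a flat lifespan
# sampling design. Cached per parameter set.
.truncnorm_cache <- new.env(parent = emptyenv())

truncnorm_parent <- function(mean, sd, range) {
  key <- paste(format(c(mean, sd, range), digits = 15), collapse = "|")
  if (!is.null(.truncnorm_cache[[key]])) {
    return(.truncnorm_cache[[key]])
  }
  moments <- function(mu, sigma) {
    a <- (range[1] - mu) / sigma
    b <- (range[2] - mu) / sigma
    zz <- pnorm(b) - pnorm(a)
    m <- mu + sigma * (dnorm(a) - dnorm(b)) / zz
    v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / zz -
                      ((dnorm(a) - dnorm(b)) / zz)^2)
    c(m, sqrt(v))
  }
  max_sd <- diff(range) / sqrt(12)  # flat limit
  if (sd >= max_sd * 0.9999) {
    stop_segspeech(
      sprintf("requested truncated SD %.3f is infeasible on [%g, %g]", sd,
              range[1], range[2]),
      "segspeech_parameter_error"
    )
  }
  obj <- function(p) {
    if (p[2] <= 0) return(1e6)
    sum((moments(p[1], p[2]) - c(mean, sd))^2)
  }
  fit <- optim(c(mean, sd), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 10000))
  fit <- optim(fit$par, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 10000))
  out <- list(mu = fit$par[1], sigma = fit$par[2], range = range)
  .truncnorm_cache[[key]] <- out
  out
}

rtruncnorm_matched <- function(n, mean, sd, range) {
  p <- truncnorm_parent(mean, sd, range)
  lo <- pnorm((range[1] - p$mu) / p$sigma)
  hi <- pnorm((range[2] - p$mu) / p$sigma)
  p$mu + p$sigma * qnorm(runif(n, lo, hi))
}
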