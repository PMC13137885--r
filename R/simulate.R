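#' Simulate participant covariates
#'
#' Draws ages from a truncated normal whose truncated mean/SD match the
#' configured values on the configured range, integer education years,
#' a uniform three-level project label, a cognitive-screening score (MMSE
#' for study1, MoCA otherwise, all passing by construction since the cohort
#' emulates the post-screening analysis sample), and Stroop interference as
#' a linear-in-age draw with Gaussian noise.
#'
#' @param params A `segspeech_params` object (see [generator_params()]).
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A tibble with columns `id`, `age`, `education`, `project`,
#'   `mmse`, `moca`, `stroop`.
#' @export
#' @examples
#' cov <- simulate_covariates(generator_params(n_participants = 20), seed = 1)
#' summary(cov$age)
simulate_covariates <- function(params, seed = 1L) {
  params <- validate_params(unclass(params))
  n <- params$n_participants
  set.seed(seed)
  age <- rtruncnorm_matched(n, params$age_mean, params$age_sd, params$age_range)
  education <- sample(seq(params$education_range[1], params$education_range[2]),
                      n, replace = TRUE)
  project <- sample(params$projects, n, replace = TRUE)
  mmse <- ifelse(project == params$projects[1],
                 pmin(30L, 24L + sample(0:6, n, replace = TRUE,
                                        prob = c(1, 1, 2, 4, 8, 10, 6))), NA_integer_)
  moca <- ifelse(project == params$projects[1], NA_integer_,
                 pmin(30L, 26L + sample(0:4, n, replace = TRUE,
                                        prob = c(2, 4, 8, 10, 6))))
  stroop <- params$stroop_intercept +
    params$stroop_slope * (age - params$age_mean) +
    rnorm(n, 0, params$stroop_resid_sd)
  tibble::tibble(
    id = sprintf("p%03d", seq_len(n)),
    age = age, education = education, project = project,
    mmse = mmse, moca = moca, stroop = stroop
  )
}

#' Add per-network segregation (and within/between FC) to a cohort
#'
#' Direct linear generator: segregation for each network is intercept +
#' slope * (age - age_mean) + Gaussian noise. Companion within/between
#' connectivity columns are derived on the z scale: within-network FC gets
#' independent person-to-person spread (`within_fc_sd`) around the block
#' target, and between = within * (1 - segregation), so
#' `(within - between)/within` reproduces the drawn segregation exactly.
#' These columns feed the supplementary within/between metric families.
#'
#' @param cohort A covariate tibble from [simulate_covariates()].
#' @param params A `segspeech_params` object.
#' @param seed Integer seed.
#' @return The cohort with columns `seg_<network>`, `within_<network>`,
#'   `between_<network>` added.
#' @export
simulate_segregation <- function(cohort, params, seed = 1L) {
  params <- validate_params(unclass(params))
  require_columns(cohort, "age", "segregation generator")
  set.seed(seed)
  age_c <- cohort$age - params$age_mean
  for (net in c("language", "dmn", "md")) {
    seg <- params$seg_intercepts[[net]] + params$seg_slopes[[net]] * age_c +
      rnorm(nrow(cohort), 0, params$seg_resid_sd[[net]])
    w0 <- params$block_corr$within[[net]] +
      rnorm(nrow(cohort), 0, params$within_fc_sd)
    cohort[[paste0("seg_", net)]] <- seg
    cohort[[paste0("within_", net)]] <- w0
    cohort[[paste0("between_", net)]] <- w0 * (1 - seg)
  }
  cohort
}

#' Simulate disfluency outcomes for a cohort
#'
#' In `direct` mode each subtype percentage is drawn from its configured
#' linear model in centered age, centered Stroop, centered DMN segregation,
#' and the two interaction products, plus Gaussian noise. In `mediation`
#' mode DMN segregation is redrawn from the mediator model
#' (`a * age_c + noise`) and revisions follow the outcome model
#' (`c_prime * age_c + b * seg + noise`), with the remaining subtypes drawn
#' as in direct mode. Percentages are floored at 0 (rates cannot be
#' negative) and the total is the sum of the five subtypes. The exact
#' generative record is attached as a `ground_truth` attribute.
#'
#' @param cohort A cohort tibble with `age` (plus `stroop` and `seg_dmn`
#'   when the configured slopes reference them).
#' @param params A `segspeech_params` object.
#' @param mode `"direct"` or `"mediation"`.
#' @param seed Integer seed.
#' @return The cohort with `filled_pct`, `unfilled_pct`, `repetition_pct`,
#'   `revision_pct`, `prolongation_pct`, `total_pct` columns; ground truth in
#'   `attr(, "ground_truth")` (see [ground_truth()]).
#' @export
simulate_disfluency <- function(cohort, params, mode = c("direct", "mediation"),
                                seed = 1L) {
  params <- validate_params(unclass(params))
  mode <- match.arg(mode)
  require_columns(cohort, "age", "disfluency generator")
  coefs <- params$disfluency_coefs
  needs_stroop <- any(coefs$stroop != 0 | coefs$age_x_stroop != 0)
  needs_seg <- any(coefs$seg != 0 | coefs$age_x_seg != 0)
  if (needs_stroop) require_columns(cohort, "stroop", "disfluency generator")
  if (needs_seg && mode == "direct") {
    require_columns(cohort, "seg_dmn", "disfluency generator")
  }
  set.seed(seed)
  n <- nrow(cohort)
  age_c <- cohort$age - mean(cohort$age)
  med <- params$mediation_coefs
  if (mode == "mediation") {
    seg <- med$m_intercept + med$a * age_c + rnorm(n, 0, med$m_resid_sd)
    cohort$seg_dmn <- seg
    w0 <- params$block_corr$within[["dmn"]] +
      rnorm(n, 0, params$within_fc_sd)
    cohort$within_dmn <- w0
    cohort$between_dmn <- w0 * (1 - seg)
  }
  stroop_c <- if (needs_stroop) cohort$stroop - mean(cohort$stroop) else numeric(n)
  seg_c <- if ("seg_dmn" %in% names(cohort)) {
    cohort$seg_dmn - mean(cohort$seg_dmn)
  } else {
    numeric(n)
  }
  latent <- list()
  for (i in seq_len(nrow(coefs))) {
    row <- coefs[i, ]
    if (mode == "mediation" && row$outcome == "revision_pct") {
      mu <- med$y_intercept + med$c_prime * age_c +
        med$b * (cohort$seg_dmn - med$m_intercept)
      y <- mu + rnorm(n, 0, med$y_resid_sd)
    } else {
      mu <- row$intercept + row$age * age_c + row$stroop * stroop_c +
        row$seg * seg_c + row$age_x_stroop * age_c * stroop_c +
        row$age_x_seg * age_c * seg_c
      y <- mu + rnorm(n, 0, row$resid_sd)
    }
    latent[[row$outcome]] <- y
    cohort[[row$outcome]] <- pmax(y, 0)
  }
  cohort$total_pct <- cohort$filled_pct + cohort$unfilled_pct +
    cohort$repetition_pct + cohort$revision_pct + cohort$prolongation_pct
  attr(cohort, "ground_truth") <- ground_truth(
    seed = seed, mode = mode,
    disfluency_coefs = coefs,
    mediation_coefs = if (mode == "mediation") med else NULL,
    seg_latent = if ("seg_dmn" %in% names(cohort)) cohort$seg_dmn else NULL,
    floored = vapply(names(latent), function(k) sum(latent[[k]] < 0), integer(1))
  )
  cohort
}

#' Simulate a complete analysis-ready cohort
#'
#' Chains [simulate_covariates()], [simulate_segregation()], and
#' [simulate_disfluency()] with sub-seeds derived from `seed`.
#'
#' @inheritParams simulate_disfluency
#' @param seed Integer master seed.
#' @return An analysis-ready cohort tibble with ground truth attached.
#' @export
#' @examples
#' cohort <- simulate_cohort(generator_params(n_participants = 40), seed = 7)
#' names(cohort)
simulate_cohort <- function(params = generator_params(),
                            mode = c("direct", "mediation"), seed = 1L) {
  mode <- match.arg(mode)
  cohort <- simulate_covariates(params, seed = seed)
  cohort <- simulate_segregation(cohort, params, seed = seed + 1000L)
  simulate_disfluency(cohort, params, mode = mode, seed = seed + 2000L)
}

#' Ground-truth record for a simulated cohort
#'
#' Stores the exact generative coefficients, per-participant latent
#' segregation values, flooring counts, and the seed, so recovery tests can
#' compare fitted estimates against what was actually generated. Round-trips
#' losslessly through JSON via [write_ground_truth()] / [read_ground_truth()].
#'
#' @param ... Named components.
#' @return A list of class `segspeech_ground_truth`.
#' @export
ground_truth <- function(...) {
  structure(list(...), class = "segspeech_ground_truth")
}

#' @rdname ground_truth
#' @param gt A `segspeech_ground_truth` object.
#' @param path File path for the JSON record.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "segspeech_ground_truth"))
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$disfluency_coefs)) {
    raw$disfluency_coefs <- as.data.frame(raw$disfluency_coefs,
                                          stringsAsFactors = FALSE)
  }
  if (!is.null(raw$floored)) raw$floored <- unlist(raw$floored)
  do.call(ground_truth, raw)
}

#' Simulate a block-structured ROI time series for one participant
#'
#' Draws `n_timepoints` multivariate-normal samples over all atlas ROIs with
#' a block correlation structure. Block targets in `params$block_corr` are
#' expressed on the Fisher-z scale -- the scale on which all downstream
#' connectivity metrics are averaged -- so the expected segregation is
#' exactly `(within - between) / within` in those units. When
#' `params$block_corr$between` is `NULL` the blocks are solved so that the
#' participant's expected downstream segregation equals `seg_intercept +
#' seg_slope * (age - age_mean)` for each network under the asymmetric BNC
#' definitions; when `between` is a single value, all cross-network blocks
#' use it (age-independent), which is convenient for consistency checks.
#'
#' @param participant_age Age in years.
#' @param atlas A `segspeech_atlas`.
#' @param params A `segspeech_params` object.
#' @param seed Base seed; combined with `participant_index` so each
#'   participant's series is reproducible independently.
#' @param participant_index Integer index of the participant.
#' @return A `n_timepoints` x R numeric matrix with ROI identifiers as
#'   column names.
#' @export
simulate_timeseries <- function(participant_age, atlas, params, seed = 1L,
                                participant_index = 1L) {
  params <- validate_params(unclass(params))
  n_roi <- nrow(atlas)
  tt <- params$n_timepoints
  if (tt < 3 * n_roi) {
    stop_segspeech(
      sprintf("n_timepoints (%d) must be at least 3x the ROI count (%d)",
              tt, n_roi),
      "segspeech_parameter_error"
    )
  }
  sigma <- block_correlation(participant_age, atlas, params)
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10) {
    stop_segspeech(
      sprintf(
        "block covariance is not positive-definite (min eigenvalue %.3g); blocks: %s",
        ev, paste(sprintf("%s=%.3f", names(attr(sigma, "blocks")),
                          attr(sigma, "blocks")), collapse = ", ")
      ),
      "segspeech_generator_error"
    )
  }
  set.seed(seed + 7919L * (participant_index - 1L))
  ts <- MASS::mvrnorm(tt, mu = rep(0, n_roi), Sigma = sigma)
  colnames(ts) <- atlas$roi_id
  ts
}

# Build the R x R block correlation matrix. Block targets live on the
# Fisher-z scale (the scale of every downstream connectivity metric), so
# the segregation identity (w - b) / w holds by construction; targets are
# mapped to correlations with tanh when filling the covariance. With
# within-network z target zw and target segregation s, the cross-block z
# must be zw * (1 - s). DMN and MD share one cross block (their BNCs are
# identical by definition), so the DMN target fixes the DMN-MD block and
# the MD within-block is then solved back from the MD target.
block_correlation <- function(age, atlas, params) {
  nets <- c("language", "dmn", "md")
  w <- params$block_corr$within
  fixed_between <- params$block_corr$between
  if (is.null(fixed_between)) {
    s <- vapply(nets, function(net) {
      params$seg_intercepts[[net]] +
        params$seg_slopes[[net]] * (age - params$age_mean)
    }, numeric(1))
    z_dm <- w[["dmn"]] * (1 - s[["dmn"]])
    zw_md <- if (abs(1 - s[["md"]]) < 1e-12) w[["dmn"]] else z_dm / (1 - s[["md"]])
    within <- c(language = w[["language"]], dmn = w[["dmn"]], md = zw_md)
    b_lang <- w[["language"]] * (1 - s[["language"]])
    between <- c("dmn|language" = b_lang, "language|md" = b_lang, "dmn|md" = z_dm)
  } else {
    within <- c(language = w[["language"]], dmn = w[["dmn"]], md = w[["md"]])
    between <- c("dmn|language" = fixed_between, "language|md" = fixed_between,
                 "dmn|md" = fixed_between)
  }
  within <- tanh(within)
  between <- tanh(between)
  sigma <- matrix(0, nrow(atlas), nrow(atlas),
                  dimnames = list(atlas$roi_id, atlas$roi_id))
  for (a in nets) {
    ia <- atlas$network == a
    sigma[ia, ia] <- within[[a]]
    for (b in nets) {
      if (a == b) next
      key <- paste(sort(c(a, b)), collapse = "|")
      sigma[ia, atlas$network == b] <- between[[key]]
    }
  }
  diag(sigma) <- 1
  attr(sigma, "blocks") <- c(within, between)
  sigma
}

require_columns <- function(df, cols, where) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_segspeech(
      sprintf("%s: missing required column(s): %s", where,
              paste(missing, collapse = ", ")),
      "segspeech_schema_error"
    )
  }
  invisible(df)
}
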