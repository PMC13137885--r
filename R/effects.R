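#' Conditional (simple) slope from printed coefficients
#'
#' The focal predictor's conditional effect at a moderator offset:
#' `b_focal + b_interaction * offset`. Exposed separately so worked examples
#' can be evaluated directly from published coefficients.
#'
#' @param b_focal Focal main-effect coefficient (at moderator = 0, i.e., the
#'   moderator's mean in a centered model).
#' @param b_interaction Interaction coefficient.
#' @param offset Moderator value as an offset from its mean.
#' @return The conditional slope.
#' @export
#' @examples
#' conditional_slope(-0.64, 0.042, -17.1)  # one SD of age below the mean
conditional_slope <- function(b_focal, b_interaction, offset) {
  b_focal + b_interaction * offset
}

#' Simple-slope analysis of an interaction
#'
#' Conditional effect of the focal predictor at fixed moderator offsets,
#' with delta-method standard errors from the estimate covariance:
#' `SE = sqrt(V_ff + 2 * offset * V_fi + offset^2 * V_ii)`, and t/p on the
#' fit's residual degrees of freedom. At offset 0 the slope equals the
#' focal main-effect coefficient of the centered model exactly.
#'
#' @param fit A `segspeech_fit` containing the focal term, moderator term,
#'   and their interaction.
#' @param focal Focal term name (default the network metric).
#' @param moderator Moderator term name (default centered age).
#' @param offsets Moderator offsets (moderator units from its mean) at
#'   which to evaluate; default mean -1 SD / mean / mean +1 SD of age with
#'   SD estimated from the fit's data.
#' @param interaction Name of the interaction column.
#' @return A tibble of class `segspeech_simple_slopes` with `offset`,
#'   `slope`, `se`, `t`, `p`.
#' @export
simple_slope <- function(fit, focal = "metric_c", moderator = "age_c",
                         offsets = NULL, interaction = "age_x_metric") {
  stopifnot(inherits(fit, "segspeech_fit"))
  for (term in c(focal, moderator, interaction)) {
    if (!term %in% fit$coefficients$term) {
      stop_segspeech(sprintf("fit lacks term '%s'", term), "segspeech_usage_error")
    }
  }
  if (is.null(offsets)) {
    sd_mod <- sd(fit$X[, moderator])
    offsets <- c(-sd_mod, 0, sd_mod)
  }
  b_f <- coef_row(fit, focal)$estimate
  b_i <- coef_row(fit, interaction)$estimate
  v_ff <- fit$vcov[focal, focal]
  v_ii <- fit$vcov[interaction, interaction]
  v_fi <- fit$vcov[focal, interaction]
  slope <- conditional_slope(b_f, b_i, offsets)
  se <- sqrt(v_ff + 2 * offsets * v_fi + offsets^2 * v_ii)
  tval <- slope / se
  structure(
    tibble::tibble(
      offset = offsets, slope = slope, se = se, t = tval,
      p = 2 * pt(abs(tval), fit$df, lower.tail = FALSE)
    ),
    class = c("segspeech_simple_slopes", class(tibble::tibble()))
  )
}

#' Johnson-Neyman region of significance
#'
#' Solves for the moderator offsets at which the conditional effect's
#' |t| equals the critical value, i.e., the real roots of
#' `(b_f + b_i x)^2 = t_crit^2 (V_ff + 2 x V_fi + x^2 V_ii)`, and describes
#' the region of significance. Boundaries are reported only within the
#' observed moderator range; a quadratic with no real roots yields an
#' empty-boundary result, not an error.
#'
#' @inheritParams simple_slope
#' @param alpha Two-sided significance level (default 0.05).
#' @return A `segspeech_jn` list: `boundaries` (possibly empty numeric, as
#'   moderator offsets), `all_roots`, `significant_inside` (logical; `TRUE`
#'   when |t| exceeds the critical value between the two roots),
#'   `moderator_range`, `alpha`, `t_crit`, `df`.
#' @export
johnson_neyman <- function(fit, focal = "metric_c", moderator = "age_c",
                           interaction = "age_x_metric", alpha = 0.05) {
  stopifnot(inherits(fit, "segspeech_fit"))
  for (term in c(focal, moderator, interaction)) {
    if (!term %in% fit$coefficients$term) {
      stop_segspeech(sprintf("fit lacks term '%s'", term), "segspeech_usage_error")
    }
  }
  b_f <- coef_row(fit, focal)$estimate
  b_i <- coef_row(fit, interaction)$estimate
  v_ff <- fit$vcov[focal, focal]
  v_ii <- fit$vcov[interaction, interaction]
  v_fi <- fit$vcov[focal, interaction]
  t_crit <- qt(1 - alpha / 2, fit$df)
  # quadratic a x^2 + b x + c = 0 in the moderator offset
  qa <- b_i^2 - t_crit^2 * v_ii
  qb <- 2 * (b_f * b_i - t_crit^2 * v_fi)
  qc <- b_f^2 - t_crit^2 * v_ff
  mod_range <- range(fit$X[, moderator])
  roots <- numeric(0)
  if (abs(qa) < 1e-300) {
    if (abs(qb) > 0) roots <- -qc / qb
  } else {
    disc <- qb^2 - 4 * qa * qc
    if (disc >= 0) roots <- sort((-qb + c(-1, 1) * sqrt(disc)) / (2 * qa))
  }
  inside <- NA
  if (length(roots) == 2) {
    mid <- mean(roots)
    t_mid <- abs(conditional_slope(b_f, b_i, mid)) /
      sqrt(v_ff + 2 * mid * v_fi + mid^2 * v_ii)
    inside <- t_mid > t_crit
  }
  structure(
    list(
      boundaries = roots[roots >= mod_range[1] & roots <= mod_range[2]],
      all_roots = roots,
      significant_inside = inside,
      moderator_range = mod_range,
      alpha = alpha, t_crit = t_crit, df = fit$df
    ),
    class = "segspeech_jn"
  )
}

#' @export
print.segspeech_jn <- function(x, ...) {
  if (length(x$boundaries) == 0) {
    cat("<Johnson-Neyman: no significance boundary in the observed range>\n")
  } else {
    cat(sprintf(
      "<Johnson-Neyman: boundaries at moderator offset %s; effect significant %s>\n",
      paste(sprintf("%.3f", x$boundaries), collapse = ", "),
      if (isTRUE(x$significant_inside)) "between the roots" else "outside the roots"
    ))
  }
  invisible(x)
}

# fast path coefficients for bootstrap refits; returns c(a, b, c_prime, c)
mediation_path_coefs <- function(Xm, Xy, Xt, m, y) {
  am <- qr.coef(qr(Xm), m)
  by <- qr.coef(qr(Xy), y)
  ct <- qr.coef(qr(Xt), y)
  c(a = am[["treat"]], b = by[["mediator"]], c_prime = by[["treat"]],
    c = ct[["treat"]])
}

mediation_designs <- function(data, treatment, mediator, outcome, covariates) {
  n <- nrow(data)
  treat <- as.numeric(scale(data[[treatment]], scale = FALSE))
  med <- data[[mediator]]
  cov_cols <- list()
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.character(v) || is.factor(v)) {
      f <- factor(v)
      if (nlevels(f) > 1) {
        mm <- model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(cv, seq_len(ncol(mm)))
        for (j in seq_len(ncol(mm))) cov_cols[[colnames(mm)[j]]] <- mm[, j]
      }
    } else {
      cov_cols[[cv]] <- as.numeric(v)
    }
  }
  covm <- if (length(cov_cols)) do.call(cbind, cov_cols) else NULL
  base <- cbind("(Intercept)" = rep(1, n), treat = treat)
  Xm <- cbind(base, covm)
  Xy <- cbind(base[, 1, drop = FALSE], treat = treat, mediator = med, covm)
  Xt <- Xm
  list(Xm = Xm, Xy = Xy, Xt = Xt, m = med, y = data[[outcome]])
}

#' Point estimates of the mediation paths
#'
#' Fits the mediator model (`mediator ~ treatment + covariates`), the
#' outcome model (`outcome ~ treatment + mediator + covariates`), and the
#' total-effect model (`outcome ~ treatment + covariates`) by OLS on the
#' same complete-case sample, and returns the full inference for each path.
#' In this linear, same-sample, same-covariates setting the decomposition
#' identities `ACME = a * b` and `ACME + ADE = c` hold exactly.
#'
#' @param data A cohort tibble.
#' @param treatment,mediator,outcome Column names; the treatment is
#'   mean-centered before fitting.
#' @param covariates Covariate column names entering both models (factors
#'   are reference-coded).
#' @return A list with `paths` (tibble: term, estimate, se, t, p, ci) and
#'   the three `segspeech_fit`s.
#' @export
mediation_paths <- function(data, treatment = "age", mediator = "seg_dmn",
                            outcome = "revision_pct",
                            covariates = c("education", "project")) {
  vars <- c(treatment, mediator, outcome, covariates)
  require_columns(data, vars, "mediation_paths")
  data <- data[complete.cases(data[, vars]), , drop = FALSE]
  d <- mediation_designs(data, treatment, mediator, outcome, covariates)
  fit_m <- ols_fit(d$Xm, d$m)
  fit_y <- ols_fit(d$Xy, d$y)
  fit_t <- ols_fit(d$Xt, d$y)
  grab <- function(fit, term, label) {
    row <- coef_row(fit, term)
    tibble::tibble(path = label, estimate = row$estimate, se = row$se,
                   t = row$t, p = row$p, ci_lo = row$ci_lo, ci_hi = row$ci_hi)
  }
  paths <- rbind(
    grab(fit_m, "treat", "a"),
    grab(fit_y, "mediator", "b"),
    grab(fit_y, "treat", "c_prime"),
    grab(fit_t, "treat", "c")
  )
  list(paths = paths, fit_mediator = fit_m, fit_outcome = fit_y,
       fit_total = fit_t, n = nrow(data))
}

#' Nonparametric bootstrap mediation
#'
#' Decomposes the effect of a treatment on an outcome through a mediator:
#' ACME (indirect effect, `a * b`), ADE (direct effect, `c'`), total effect
#' (`c`), and proportion mediated, with percentile confidence intervals
#' from resampling whole participants with replacement and refitting both
#' models in each resample. Bootstrap p values are
#' `2 * min(share <= 0, share >= 0)`. Resamples that produce a non-finite
#' refit (e.g., a collapsed covariate level) are dropped and logged.
#'
#' @inheritParams mediation_paths
#' @param B Number of bootstrap resamples (>= 100; the study default is
#'   5000).
#' @param seed Integer seed; the same seed reproduces the intervals
#'   exactly.
#' @param conf_level Confidence level for the percentile intervals.
#' @return A `segspeech_mediation` list with `paths`, `acme`, `ade`,
#'   `total`, `prop_mediated` (each a list with `estimate`, `ci`, `p`),
#'   `B`, `B_used`, `dropped`, `seed`, `n`.
#' @export
#' @examples
#' cohort <- simulate_cohort(generator_params(n_participants = 80),
#'                           mode = "mediation", seed = 3)
#' med <- mediate(cohort, B = 199, seed = 1)
#' med$acme
mediate <- function(data, treatment = "age", mediator = "seg_dmn",
                    outcome = "revision_pct",
                    covariates = c("education", "project"),
                    B = 5000, seed = 1L, conf_level = 0.95) {
  if (B < 100) {
    stop_segspeech("B must be at least 100", "segspeech_parameter_error")
  }
  vars <- c(treatment, mediator, outcome, covariates)
  require_columns(data, vars, "mediate")
  data <- data[complete.cases(data[, vars]), , drop = FALSE]
  n <- nrow(data)
  point <- mediation_paths(data, treatment, mediator, outcome, covariates)
  est <- setNames(point$paths$estimate, point$paths$path)
  acme_hat <- est[["a"]] * est[["b"]]
  ade_hat <- est[["c_prime"]]
  total_hat <- est[["c"]]
  set.seed(seed)
  boot <- matrix(NA_real_, nrow = B, ncol = 3,
                 dimnames = list(NULL, c("acme", "ade", "total")))
  dropped <- 0L
  for (bb in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    co <- tryCatch({
      d <- mediation_designs(data[idx, , drop = FALSE], treatment, mediator,
                             outcome, covariates)
      mediation_path_coefs(d$Xm, d$Xy, d$Xt, d$m, d$y)
    }, error = function(e) rep(NA_real_, 4))
    if (any(!is.finite(co))) {
      dropped <- dropped + 1L
      next
    }
    boot[bb, ] <- c(co[["a"]] * co[["b"]], co[["c_prime"]], co[["c"]])
  }
  boot <- boot[is.finite(boot[, 1]), , drop = FALSE]
  alpha <- 1 - conf_level
  summarise_stat <- function(stat_hat, draws) {
    list(
      estimate = as.numeric(stat_hat),
      ci = as.numeric(quantile(draws, c(alpha / 2, 1 - alpha / 2), names = FALSE)),
      p = 2 * min(mean(draws <= 0), mean(draws >= 0))
    )
  }
  prop_draws <- boot[, "acme"] / (boot[, "acme"] + boot[, "ade"])
  structure(
    list(
      paths = point$paths,
      acme = summarise_stat(acme_hat, boot[, "acme"]),
      ade = summarise_stat(ade_hat, boot[, "ade"]),
      total = summarise_stat(total_hat, boot[, "total"]),
      prop_mediated = list(
        estimate = proportion_mediated(acme_hat, ade_hat)$proportion,
        ci = as.numeric(quantile(prop_draws, c(alpha / 2, 1 - alpha / 2),
                                 names = FALSE)),
        p = NA_real_
      ),
      B = B, B_used = nrow(boot), dropped = dropped, seed = seed, n = n
    ),
    class = "segspeech_mediation"
  )
}

#' @export
print.segspeech_mediation <- function(x, ...) {
  cat(sprintf(
    paste0("<mediation: n = %d, B = %d>\n",
           "  ACME  %+.5f [%.5f, %.5f] p = %.3f\n",
           "  ADE   %+.5f [%.5f, %.5f] p = %.3f\n",
           "  total %+.5f; proportion mediated %.3f\n"),
    x$n, x$B_used,
    x$acme$estimate, x$acme$ci[1], x$acme$ci[2], x$acme$p,
    x$ade$estimate, x$ade$ci[1], x$ade$ci[2], x$ade$p,
    x$total$estimate, x$prop_mediated$estimate
  ))
  invisible(x)
}

#' Proportion of the total effect that is mediated
#'
#' `ACME / (ACME + ADE)`. When the indirect and direct effects have
#' opposite signs the ratio is unstable (it can exceed 1 or be negative)
#' and is flagged as such; a zero total effect leaves the proportion
#' undefined.
#'
#' @param acme Indirect effect estimate.
#' @param ade Direct effect estimate.
#' @return A list with `proportion`, `unstable`, `defined`.
#' @export
#' @examples
#' proportion_mediated(0.0012, 0.0046)
proportion_mediated <- function(acme, ade) {
  total <- acme + ade
  if (!is.finite(total) || total == 0) {
    return(list(proportion = NA_real_, unstable = NA, defined = FALSE))
  }
  list(
    proportion = acme / total,
    unstable = sign(acme) * sign(ade) < 0 && acme != 0 && ade != 0,
    defined = TRUE
  )
}

#' Prerequisite check for serial mediation through executive function
#'
#' Serial mediation (age -> network metric -> EF -> disfluency) is only
#' licensed when the metric actually predicts EF. This reports the
#' prerequisite path (EF on the metric, controlling for age and
#' covariates); the full serial decomposition (a1 * d21 * b2) is returned
#' only when the prerequisite is significant, mirroring the analysis
#' protocol of not fitting unlicensed serial models.
#'
#' @param data A cohort tibble.
#' @param mediator Network metric column (first-stage mediator).
#' @param ef Executive-function column (second-stage mediator; default
#'   Stroop interference).
#' @param outcome Disfluency outcome column.
#' @param covariates Covariates for every model.
#' @param alpha Significance level for the prerequisite decision.
#' @return A list with `prerequisite` (tibble row: estimate/se/t/p of the
#'   metric -> EF path), `licensed` (logical), and `serial_indirect`
#'   (estimate `a1 * d21 * b2`, or `NA` when not licensed).
#' @export
serial_check <- function(data, mediator = "seg_dmn", ef = "stroop",
                         outcome = "revision_pct",
                         covariates = c("education", "project"),
                         alpha = 0.05) {
  vars <- c("age", mediator, ef, outcome, covariates)
  require_columns(data, vars, "serial_check")
  data <- data[complete.cases(data[, vars]), , drop = FALSE]
  n <- nrow(data)
  treat <- as.numeric(scale(data$age, scale = FALSE))
  dd <- mediation_designs(data, "age", mediator, ef, covariates)
  fit_ef <- ols_fit(dd$Xy, dd$y)  # ef ~ treat + mediator + covs
  prereq <- coef_row(fit_ef, "mediator")
  licensed <- prereq$p < alpha
  serial_indirect <- NA_real_
  if (licensed) {
    a1 <- coef_row(ols_fit(dd$Xm, data[[mediator]]), "treat")$estimate
    d21 <- prereq$estimate
    Xy2 <- cbind(dd$Xy[, c("(Intercept)", "treat", "mediator"), drop = FALSE],
                 ef = data[[ef]],
                 dd$Xy[, setdiff(colnames(dd$Xy),
                                 c("(Intercept)", "treat", "mediator")),
                       drop = FALSE])
    b2 <- coef_row(ols_fit(Xy2, data[[outcome]]), "ef")$estimate
    serial_indirect <- a1 * d21 * b2
  }
  list(
    prerequisite = tibble::tibble(
      path = paste(mediator, "->", ef), estimate = prereq$estimate,
      se = prereq$se, t = prereq$t, p = prereq$p
    ),
    licensed = licensed,
    serial_indirect = serial_indirect,
    n = n, alpha = alpha
  )
}
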