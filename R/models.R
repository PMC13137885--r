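#' Mean-center a numeric vector
#'
#' Subtracts the sample mean (computed over non-missing values) and stores
#' it in the `"center"` attribute for back-transformation. Idempotent up to
#' floating point.
#'
#' @param values Numeric vector with at least one finite value.
#' @return Centered vector with attribute `center`.
#' @export
center <- function(values) {
  if (!any(is.finite(values))) {
    stop_segspeech("cannot center an all-missing column", "segspeech_schema_error")
  }
  m <- mean(values, na.rm = TRUE)
  structure(values - m, center = m)
}

#' Design matrix for a disfluency model
#'
#' Builds the published base model structure: intercept, centered age,
#' centered Stroop, centered network metric, the two interaction products
#' of centered columns (age x Stroop, age x metric), education in raw
#' years, and reference-coded project indicators (two columns for three
#' projects).
#'
#' @param cohort A cohort tibble with `age`, `stroop`, `education`,
#'   `project`, and the metric column.
#' @param metric_col Name of the network metric column (e.g., `"seg_dmn"`).
#' @param include Character vector of optional term groups to include;
#'   defaults to the full published structure.
#' @return A list with `X` (numeric matrix with column names), `centers`
#'   (named means used for centering), and `terms`.
#' @export
design_matrix <- function(cohort, metric_col,
                          include = c("stroop", "metric", "interactions",
                                      "covariates")) {
  needed <- c("age",
              if ("stroop" %in% include) "stroop",
              if ("metric" %in% include) metric_col,
              if ("covariates" %in% include) c("education", "project"))
  require_columns(cohort, needed, "design_matrix")
  n <- nrow(cohort)
  age_c <- center(cohort$age)
  cols <- list("(Intercept)" = rep(1, n), age_c = as.numeric(age_c))
  centers <- c(age = attr(age_c, "center"))
  if ("stroop" %in% include) {
    stroop_c <- center(cohort$stroop)
    cols$stroop_c <- as.numeric(stroop_c)
    centers["stroop"] <- attr(stroop_c, "center")
  }
  if ("metric" %in% include) {
    metric_c <- center(cohort[[metric_col]])
    cols$metric_c <- as.numeric(metric_c)
    centers["metric"] <- attr(metric_c, "center")
  }
  if ("interactions" %in% include) {
    if (!is.null(cols$stroop_c)) cols$age_x_stroop <- cols$age_c * cols$stroop_c
    if (!is.null(cols$metric_c)) cols$age_x_metric <- cols$age_c * cols$metric_c
  }
  if ("covariates" %in% include) {
    cols$education <- as.numeric(cohort$education)
    project <- factor(cohort$project)
    if (nlevels(project) > 1) {
      dummies <- model.matrix(~project)[, -1, drop = FALSE]
      for (j in seq_len(ncol(dummies))) cols[[colnames(dummies)[j]]] <- dummies[, j]
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  rownames(X) <- NULL
  list(X = X, centers = centers, terms = names(cols), metric_col = metric_col)
}

#' Ordinary least squares with full inference
#'
#' QR-based least squares returning unstandardized estimates, standard
#' errors from the residual variance times the diagonal of (X'X)^-1,
#' t statistics, two-sided p values on n - p degrees of freedom, 95%
#' confidence intervals, and the full estimate covariance matrix.
#'
#' @param X Numeric design matrix (including the intercept column) with
#'   column names.
#' @param y Numeric outcome vector.
#' @param ids Optional row identifiers (used in exclusion reporting).
#' @return A `segspeech_fit` object: list with `coefficients` tibble
#'   (`term`, `estimate`, `se`, `t`, `p`, `ci_lo`, `ci_hi`), `vcov`, `df`,
#'   `sigma2`, `n`, `r_squared`, `residuals`, plus the `X`, `y`, `ids` it
#'   was fit to.
#' @export
#' @examples
#' X <- cbind("(Intercept)" = 1, x = c(0, 1, 2, 3))
#' ols_fit(X, c(1, 2, 2, 4))$coefficients
ols_fit <- function(X, y, ids = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) {
    stop_segspeech("length(y) must match nrow(X)", "segspeech_schema_error")
  }
  if (n <= p) {
    stop_segspeech(sprintf("need n > p (n = %d, p = %d)", n, p),
                   "segspeech_degenerate_error")
  }
  qx <- qr(X)
  if (qx$rank < p) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop_segspeech(
      sprintf("design matrix is rank deficient; collinear column(s): %s",
              paste(dropped, collapse = ", ")),
      "segspeech_rank_error"
    )
  }
  b <- qr.coef(qx, y)
  e <- as.numeric(y - X %*% b)
  df <- n - p
  sigma2 <- sum(e^2) / df
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  piv <- qx$pivot
  xtx_inv <- xtx_inv[order(piv), order(piv), drop = FALSE]
  vc <- sigma2 * xtx_inv
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- unname(sqrt(diag(vc)))
  b <- unname(b)
  tval <- b / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  tcrit <- qt(0.975, df)
  tss <- sum((y - mean(y))^2)
  structure(
    list(
      coefficients = tibble::tibble(
        term = colnames(X), estimate = as.numeric(b), se = se,
        t = as.numeric(tval), p = as.numeric(pval),
        ci_lo = as.numeric(b - tcrit * se), ci_hi = as.numeric(b + tcrit * se)
      ),
      vcov = vc, df = df, sigma2 = sigma2, n = n,
      r_squared = if (tss > 0) 1 - sum(e^2) / tss else NA_real_,
      residuals = e, X = X, y = y,
      ids = ids %||% as.character(seq_len(n)),
      excluded_ids = character()
    ),
    class = "segspeech_fit"
  )
}

#' @export
print.segspeech_fit <- function(x, ...) {
  cat(sprintf("<OLS fit: n = %d, df = %d, R^2 = %.3f>\n", x$n, x$df, x$r_squared))
  print(x$coefficients)
  invisible(x)
}

coef_row <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) {
    stop_segspeech(sprintf("term '%s' not in fit", term), "segspeech_usage_error")
  }
  fit$coefficients[i, ]
}

#' Cook's distance screening with one-pass refit
#'
#' Computes Cook's distance for every observation from the hat-matrix
#' leverages, `D_i = (e_i^2 / (p * s^2)) * h_i / (1 - h_i)^2`, flags rows
#' with `D_i` above the threshold (default 4/n), and refits once without
#' them. No iterative re-screening is performed.
#'
#' @param fit A `segspeech_fit`.
#' @param threshold Flagging threshold; default `4 / n`.
#' @return A list with `cooks_d` (per input row), `flagged_ids`, and
#'   `refit` (a `segspeech_fit` on the retained rows; identical to the
#'   input fit when nothing is flagged, with `excluded_ids` recorded).
#' @export
cooks_screen <- function(fit, threshold = NULL) {
  stopifnot(inherits(fit, "segspeech_fit"))
  n <- fit$n
  p <- ncol(fit$X)
  threshold <- threshold %||% (4 / n)
  xtx_inv <- fit$vcov / fit$sigma2
  h <- rowSums((fit$X %*% xtx_inv) * fit$X)
  d <- (fit$residuals^2 / (p * fit$sigma2)) * h / (1 - h)^2
  flagged <- which(d > threshold)
  if (length(flagged) > 0 && n - length(flagged) <= p) {
    warning("Cook's screening would leave n <= p; keeping the unscreened fit")
    flagged <- integer(0)
  }
  if (length(flagged) == 0) {
    refit <- fit
  } else {
    keep <- setdiff(seq_len(n), flagged)
    refit <- ols_fit(fit$X[keep, , drop = FALSE], fit$y[keep],
                     ids = fit$ids[keep])
    refit$excluded_ids <- fit$ids[flagged]
  }
  list(cooks_d = setNames(d, fit$ids), flagged_ids = fit$ids[flagged],
       refit = refit)
}

#' Benjamini-Hochberg q-values within families
#'
#' Step-up FDR adjustment applied independently within each family of
#' tests. Delegates to `stats::p.adjust(method = "BH")` per family.
#'
#' @param pvalues Numeric p values in `[0, 1]`.
#' @param family Optional vector of family labels (same length); `NULL`
#'   treats all p values as one family.
#' @return q-values in the input order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(pvalues, family = NULL) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop_segspeech("p values must lie in [0, 1]", "segspeech_parameter_error")
  }
  if (is.null(family)) {
    return(p.adjust(pvalues, method = "BH"))
  }
  if (length(family) != length(pvalues)) {
    stop_segspeech("family labels must match p values in length",
                   "segspeech_parameter_error")
  }
  q <- numeric(length(pvalues))
  for (f in unique(family)) {
    idx <- family == f
    q[idx] <- p.adjust(pvalues[idx], method = "BH")
  }
  q
}

battery_outcomes <- c("filled_pct", "unfilled_pct", "repetition_pct",
                      "revision_pct", "prolongation_pct", "total_pct")

metric_column <- function(family, network) {
  prefix <- switch(family, segregation = "seg", within = "within",
                   between = "between")
  paste0(prefix, "_", network)
}

#' Fit one disfluency model
#'
#' Fits `outcome ~ age_c + stroop_c + metric_c + age_c:stroop_c +
#' age_c:metric_c + education + project` by OLS on complete cases, with
#' single-pass Cook's-distance screening (threshold 4/n) before the final
#' fit.
#'
#' @param cohort An analysis-ready cohort tibble.
#' @param outcome Name of the disfluency outcome column.
#' @param network One of `"language"`, `"dmn"`, `"md"`.
#' @param family Metric family: `"segregation"`, `"within"`, or
#'   `"between"`.
#' @param cooks Apply Cook's screening (default `TRUE`).
#' @return A `segspeech_fit` for the screened sample, with
#'   `excluded_ids` listing screened-out participants and attributes
#'   `outcome`, `network`, `family`.
#' @export
fit_disfluency_model <- function(cohort, outcome, network,
                                 family = c("segregation", "within", "between"),
                                 cooks = TRUE) {
  family <- match.arg(family)
  metric_col <- metric_column(family, network)
  require_columns(cohort, c(outcome, metric_col), "fit_disfluency_model")
  vars <- c("age", "stroop", "education", "project", metric_col, outcome)
  cc <- complete.cases(cohort[, vars])
  data <- cohort[cc, , drop = FALSE]
  dm <- design_matrix(data, metric_col)
  fit <- ols_fit(dm$X, data[[outcome]],
                 ids = data$id %||% as.character(which(cc)))
  if (cooks) fit <- cooks_screen(fit)$refit
  attr(fit, "outcome") <- outcome
  attr(fit, "network") <- network
  attr(fit, "family") <- family
  attr(fit, "centers") <- dm$centers
  fit
}

#' Run the full 18-model battery
#'
#' Fits the base model once per network (language, DMN, MD) and disfluency
#' outcome (five subtypes plus total): 18 models. Two FDR families are then
#' adjusted independently with Benjamini-Hochberg: all 18 metric main
#' effects, and all 18 Age x Metric interaction terms.
#'
#' @inheritParams fit_disfluency_model
#' @return A `segspeech_battery`: list with `fits` (named list of 18
#'   `segspeech_fit`s), `table` (tidy tibble of the metric main effect and
#'   interaction rows with `q` attached), and `family`.
#' @export
#' @examples
#' cohort <- simulate_cohort(generator_params(n_participants = 60), seed = 2)
#' bat <- run_battery(cohort)
#' subset(bat$table, term == "metric_c" & q < 0.05)
run_battery <- function(cohort, family = c("segregation", "within", "between"),
                        cooks = TRUE) {
  family <- match.arg(family)
  grid <- expand.grid(network = c("language", "dmn", "md"),
                      outcome = battery_outcomes, stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  names(fits) <- paste(grid$network, grid$outcome, sep = ":")
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fit <- fit_disfluency_model(cohort, grid$outcome[i], grid$network[i],
                                family = family, cooks = cooks)
    fits[[i]] <- fit
    main <- coef_row(fit, "metric_c")
    inter <- coef_row(fit, "age_x_metric")
    rows[[i]] <- tibble::tibble(
      network = grid$network[i], outcome = grid$outcome[i],
      term = c("metric_c", "age_x_metric"),
      fdr_family = c("metric_main", "age_x_metric"),
      estimate = c(main$estimate, inter$estimate),
      se = c(main$se, inter$se), t = c(main$t, inter$t),
      p = c(main$p, inter$p),
      n_used = fit$n, n_excluded = length(fit$excluded_ids)
    )
  }
  table <- do.call(rbind, rows)
  table$q <- bh_fdr(table$p, table$fdr_family)
  structure(list(fits = fits, table = table, family = family),
            class = "segspeech_battery")
}

#' @export
print.segspeech_battery <- function(x, ...) {
  cat(sprintf("<model battery: %d fits, metric family = %s>\n",
              length(x$fits), x$family))
  print(x$table[x$table$q < 0.05, ])
  invisible(x)
}

#' Age-only effect model
#'
#' The simplified model isolating the age effect on one outcome while
#' controlling for education and project: `outcome ~ age_c + education +
#' project`.
#'
#' @param cohort An analysis-ready cohort tibble.
#' @param outcome Name of the outcome column (a disfluency percentage,
#'   `stroop`, or a network metric).
#' @return A `segspeech_fit`.
#' @export
fit_age_model <- function(cohort, outcome) {
  require_columns(cohort, c("age", "education", "project", outcome),
                  "fit_age_model")
  cc <- complete.cases(cohort[, c("age", "education", "project", outcome)])
  data <- cohort[cc, , drop = FALSE]
  dm <- design_matrix(data, metric_col = NULL, include = "covariates")
  fit <- ols_fit(dm$X, data[[outcome]],
                 ids = data$id %||% as.character(which(cc)))
  attr(fit, "outcome") <- outcome
  fit
}
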