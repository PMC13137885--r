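#' Pipeline configuration
#'
#' Assembles (and validates) the configuration driving [run_pipeline()].
#' Every field has a default; a YAML file with any subset of the fields can
#' be loaded with [read_pipeline_config()].
#'
#' @param ... Named overrides. Recognised fields: `seed`, `mode`
#'   (`"direct"`/`"mediation"`), `generator` (list of [generator_params()]
#'   overrides), `family` (metric family for the battery), `alpha`,
#'   `q_threshold`, `bootstrap_B`, `write_transcripts` (simulate and re-parse
#'   CHAT transcripts, using the parsed rates as the analysis outcomes),
#'   `transcript_words`, `screening` (apply cognitive screening rules),
#'   `out_dir` (write covariates/metrics/report files when non-`NULL`),
#'   `probe` (list with `network`, `outcome`), `mediation` (list with
#'   `mediator`, `outcome`).
#' @return A list of class `segspeech_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    mode = "direct",
    generator = list(),
    family = "segregation",
    alpha = 0.05,
    q_threshold = 0.05,
    bootstrap_B = 5000L,
    write_transcripts = FALSE,
    transcript_words = 200L,
    screening = TRUE,
    out_dir = NULL,
    probe = list(network = "dmn", outcome = "repetition_pct"),
    mediation = list(mediator = "seg_dmn", outcome = "revision_pct")
  )
  config <- modifyList(defaults, list(...))
  if (!config$mode %in% c("direct", "mediation")) {
    stop_segspeech("mode must be 'direct' or 'mediation'", "segspeech_parameter_error")
  }
  structure(config, class = "segspeech_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop_segspeech(sprintf("config file not found: %s", path), "segspeech_io_error")
  }
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw %||% list())
}

#' Apply participant-level screening rules
#'
#' Excludes participants who fail cognitive screening (MMSE < 24 for
#' MMSE-administered participants, MoCA < 26 for MoCA-administered ones —
#' each participant carries whichever instrument their study used) or who
#' are missing key variables (age, Stroop, any referenced network metric,
#' or any disfluency outcome present in `key_vars`). Returns an itemized
#' exclusion log so counts reconcile.
#'
#' @param cohort A cohort tibble.
#' @param key_vars Columns whose missingness excludes a participant.
#' @param apply_cognitive Apply the MMSE/MoCA rules when those columns
#'   exist.
#' @return A list with `retained` (tibble), `excluded` (tibble: `id`,
#'   `reason`), `n_in`, `n_retained`.
#' @export
#' @examples
#' cohort <- tibble::tibble(id = c("a", "b"), mmse = c(23, 28), moca = NA,
#'                          age = c(30, 40), stroop = c(50, 60))
#' screen_participants(cohort, key_vars = c("age", "stroop"))$excluded
screen_participants <- function(cohort,
                                key_vars = intersect(
                                  c("age", "stroop", "seg_language", "seg_dmn",
                                    "seg_md", battery_outcomes),
                                  names(cohort)
                                ),
                                apply_cognitive = TRUE) {
  missing_cols <- setdiff(key_vars, names(cohort))
  if (length(missing_cols)) {
    stop_segspeech(
      sprintf("screening rule references absent column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "segspeech_schema_error"
    )
  }
  ids <- cohort$id %||% as.character(seq_len(nrow(cohort)))
  reason <- rep(NA_character_, nrow(cohort))
  if (apply_cognitive && "mmse" %in% names(cohort)) {
    fail <- !is.na(cohort$mmse) & cohort$mmse < 24
    reason[fail & is.na(reason)] <- "failed cognitive screening (MMSE < 24)"
  }
  if (apply_cognitive && "moca" %in% names(cohort)) {
    fail <- !is.na(cohort$moca) & cohort$moca < 26
    reason[fail & is.na(reason)] <- "failed cognitive screening (MoCA < 26)"
  }
  if (length(key_vars)) {
    incomplete <- !complete.cases(cohort[, key_vars, drop = FALSE])
    reason[incomplete & is.na(reason)] <- "missing key variables"
  }
  keep <- is.na(reason)
  list(
    retained = cohort[keep, , drop = FALSE],
    excluded = tibble::tibble(id = ids[!keep], reason = reason[!keep]),
    n_in = nrow(cohort),
    n_retained = sum(keep)
  )
}

#' Run the full analysis pipeline
#'
#' Simulate (or accept) a cohort, optionally round-trip disfluency outcomes
#' through generated CHAT transcripts and the parser, screen participants,
#' fit the 18-model battery with FDR control, probe the configured
#' interaction with simple slopes and a Johnson-Neyman analysis, run
#' bootstrap mediation, and assemble a machine-readable run report whose
#' participant counts reconcile at every stage.
#'
#' @param config A `segspeech_config` (see [pipeline_config()]).
#' @param cohort Optional user-supplied cohort tibble; when `NULL` one is
#'   simulated from `config$generator`.
#' @return A `segspeech_report` list (see [validate_run_report()]).
#' @export
#' @examples
#' rep <- run_pipeline(pipeline_config(
#'   generator = list(n_participants = 60), bootstrap_B = 199
#' ))
#' rep$counts
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "segspeech_config"))
  params <- do.call(generator_params, config$generator)
  simulated <- is.null(cohort)
  if (simulated) {
    cohort <- simulate_cohort(params, mode = config$mode, seed = config$seed)
  }
  n_in <- nrow(cohort)
  transcript_info <- NULL
  if (config$write_transcripts) {
    cohort <- roundtrip_transcripts(cohort, config)
    transcript_info <- list(words_per_transcript = config$transcript_words)
  }
  if (config$screening) {
    screened <- screen_participants(cohort)
  } else {
    screened <- list(retained = cohort,
                     excluded = tibble::tibble(id = character(),
                                               reason = character()),
                     n_in = n_in, n_retained = n_in)
  }
  analysis <- screened$retained
  battery <- run_battery(analysis, family = config$family)
  probe_fit <- battery$fits[[paste(config$probe$network, config$probe$outcome,
                                   sep = ":")]]
  slopes <- simple_slope(probe_fit)
  jn <- johnson_neyman(probe_fit, alpha = config$alpha)
  med <- mediate(analysis,
                 mediator = config$mediation$mediator,
                 outcome = config$mediation$outcome,
                 B = config$bootstrap_B, seed = config$seed)
  serial <- serial_check(analysis,
                         mediator = config$mediation$mediator,
                         outcome = config$mediation$outcome,
                         alpha = config$alpha)
  cooks_excluded <- unlist(lapply(battery$fits, function(f) f$excluded_ids))
  report <- structure(
    list(
      software = list(package = "segspeech",
                      version = as.character(utils::packageVersion("segspeech"))),
      seed = config$seed,
      config_hash = config_hash(config),
      counts = list(
        n_in = n_in,
        n_screened_out = nrow(screened$excluded),
        n_analysis = nrow(analysis),
        cooks_flagged_per_model = lengths(lapply(battery$fits,
                                                 function(f) f$excluded_ids))
      ),
      exclusions = screened$excluded,
      battery = battery$table,
      significant = battery$table[battery$table$q < config$q_threshold, ],
      probe = list(
        network = config$probe$network, outcome = config$probe$outcome,
        simple_slopes = as.data.frame(slopes),
        johnson_neyman = list(
          boundaries = jn$boundaries,
          significant_inside = jn$significant_inside,
          t_crit = jn$t_crit, alpha = jn$alpha
        )
      ),
      mediation = list(
        mediator = config$mediation$mediator,
        outcome = config$mediation$outcome,
        paths = as.data.frame(med$paths),
        acme = med$acme, ade = med$ade, total = med$total,
        prop_mediated = med$prop_mediated,
        B = med$B, B_used = med$B_used, dropped = med$dropped
      ),
      serial = list(
        prerequisite = as.data.frame(serial$prerequisite),
        licensed = serial$licensed,
        serial_indirect = serial$serial_indirect
      ),
      transcripts = transcript_info
    ),
    class = "segspeech_report"
  )
  if (nrow(analysis) != n_in - nrow(screened$excluded)) {
    stop_segspeech("participant counts do not reconcile across stages",
                   "segspeech_internal_error")
  }
  if (!is.null(config$out_dir)) {
    write_run_outputs(report, cohort, config$out_dir)
  }
  report
}

roundtrip_transcripts <- function(cohort, config) {
  rate_cols <- c(filled = "filled_pct", unfilled = "unfilled_pct",
                 repetition = "repetition_pct", revision = "revision_pct",
                 prolongation = "prolongation_pct")
  for (i in seq_len(nrow(cohort))) {
    rates <- vapply(rate_cols, function(cc) cohort[[cc]][i], numeric(1))
    tr <- simulate_transcript(rates, n_words = config$transcript_words,
                              seed = config$seed + i)
    counts <- count_disfluencies(parse_chat(tr$text))
    profile <- disfluency_profile(counts, tr$word_total)
    for (k in names(rate_cols)) cohort[[rate_cols[[k]]]][i] <-
        profile[[rate_cols[[k]]]]
    cohort$total_pct[i] <- profile$total_pct
  }
  cohort
}

config_hash <- function(config) {
  flat <- paste(utils::capture.output(utils::str(unclass(config))), collapse = "\n")
  # stable polynomial rolling hash (mod 2^31 - 1); avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(flat)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_run_outputs <- function(report, cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  write.csv(report$battery, file.path(out_dir, "battery.csv"), row.names = FALSE)
  write_run_report(report, file.path(out_dir, "report.json"))
  invisible(out_dir)
}

#' Write / validate a pipeline run report
#'
#' Reports serialize to JSON. [validate_run_report()] checks a report
#' against the JSON schema shipped at
#' `system.file("schema", "run_report_schema.json", package = "segspeech")`:
#' every required property must be present with the declared type, and the
#' participant counts must reconcile.
#'
#' @param report A `segspeech_report`.
#' @param path Output JSON path.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "segspeech_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", na = "null")
  invisible(path)
}

#' @rdname write_run_report
#' @return `TRUE` invisibly; errors describe the first violated schema rule.
#' @export
validate_run_report <- function(report) {
  schema_path <- system.file("schema", "run_report_schema.json",
                             package = "segspeech")
  schema <- jsonlite::read_json(schema_path)
  rep_list <- unclass(report)
  for (prop in schema$required) {
    if (is.null(rep_list[[prop]])) {
      stop_segspeech(sprintf("run report is missing required field '%s'", prop),
                     "segspeech_schema_error")
    }
  }
  type_of <- function(x) {
    if (is.list(x)) "object"
    else if (is.character(x)) "string"
    else if (is.numeric(x)) "number"
    else if (is.logical(x)) "boolean"
    else "unknown"
  }
  for (prop in names(schema$properties)) {
    want <- schema$properties[[prop]]$type
    if (is.null(rep_list[[prop]]) || is.null(want)) next
    have <- type_of(rep_list[[prop]])
    if (is.data.frame(rep_list[[prop]])) have <- "object"
    if (have != want && !(want == "integer" && have == "number")) {
      stop_segspeech(
        sprintf("run report field '%s' has type %s, schema requires %s",
                prop, have, want),
        "segspeech_schema_error"
      )
    }
  }
  counts <- rep_list$counts
  if (counts$n_in != counts$n_analysis + counts$n_screened_out) {
    stop_segspeech("run report counts do not reconcile", "segspeech_schema_error")
  }
  invisible(TRUE)
}
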