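#' Parse a CHAT-subset transcript
#'
#' Parses the documented subset of CHAT transcription conventions:
#'
#' * `@...` header lines and `%...` dependent tiers are skipped.
#' * Main tiers are `*PAR:` (any speaker code) followed by tokens and an
#'   utterance terminator (`.`, `?`, `!`).
#' * `&-word` is a filled-pause token (not a spoken word).
#' * `(1.5)` is a timed silent pause in seconds; `(.)`/`(..)`/`(...)` are
#'   untimed pauses with unknown duration.
#' * `<material> [/]` marks a verbatim repetition and `<material> [//]` a
#'   revision (retrace with correction); a bare `word [/]`/`word [//]`
#'   retraces that single word. Retraced material is excluded from the word
#'   count; the resumed production is counted.
#' * A colon inside a word (`s:oup`) marks segmental prolongation; the word
#'   itself still counts.
#'
#' Unknown markers (e.g., `&=laughs`, unrecognised bracket codes) are
#' collected as warnings, not errors. A structurally malformed main tier
#' (a `*` line with no `:` separator) is a parse error naming the line.
#'
#' The word total counts spoken words: filler tokens, pause marks, event
#' markers, and retraced material are excluded, and an unmarked verbatim
#' run (`the the the`) counts as one word, so a repeated word enters the
#' denominator exactly once.
#'
#' @param text A single string (or character vector of lines) of transcript
#'   text.
#' @return A `segspeech_transcript`: list with `words` (tibble: `word`,
#'   `raw`, `utterance`, `prolonged`), `events` (tibble: `type`,
#'   `utterance`, `duration`), `word_total`, and `warnings`.
#' @export
#' @examples
#' t <- parse_chat("*PAR:\tthe &-uh the the frog went [//] hopped away .")
#' count_disfluencies(t)
parse_chat <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  words <- list()
  events <- list()
  warnings <- character()
  utt <- 0L
  for (li in seq_along(lines)) {
    line <- trimws(lines[li])
    if (line == "" || startsWith(line, "@") || startsWith(line, "%")) next
    if (!startsWith(line, "*")) {
      warnings <- c(warnings, sprintf("line %d: unrecognised tier skipped", li))
      next
    }
    sep <- regexpr(":", line, fixed = TRUE)
    if (sep < 0) {
      stop_segspeech(
        sprintf("line %d: malformed main tier (no ':' separator)", li),
        "segspeech_parse_error"
      )
    }
    utt <- utt + 1L
    content <- trimws(substring(line, sep + 1))
    tokens <- strsplit(content, "\\s+")[[1]]
    tokens <- tokens[tokens != ""]
    i <- 1L
    while (i <= length(tokens)) {
      tok <- tokens[i]
      if (tok %in% c(".", "?", "!")) {
        i <- i + 1L
        next
      }
      if (startsWith(tok, "&-")) {
        events[[length(events) + 1L]] <-
          list(type = "filled_token", utterance = utt, duration = NA_real_)
        i <- i + 1L
        next
      }
      if (grepl("^&=", tok)) {
        warnings <- c(warnings, sprintf("line %d: nonspeech marker '%s' skipped", li, tok))
        i <- i + 1L
        next
      }
      m <- regmatches(tok, regexec("^\\(([0-9]+(?:\\.[0-9]+)?)\\)$", tok))[[1]]
      if (length(m) == 2) {
        events[[length(events) + 1L]] <-
          list(type = "pause", utterance = utt, duration = as.numeric(m[2]))
        i <- i + 1L
        next
      }
      if (grepl("^\\(\\.+\\)$", tok)) {
        events[[length(events) + 1L]] <-
          list(type = "pause", utterance = utt, duration = NA_real_)
        i <- i + 1L
        next
      }
      if (startsWith(tok, "<")) {
        j <- i
        while (j <= length(tokens) && !endsWith(tokens[j], ">")) j <- j + 1L
        if (j > length(tokens)) {
          stop_segspeech(
            sprintf("line %d: unterminated '<' group", li),
            "segspeech_parse_error"
          )
        }
        marker <- if (j + 1L <= length(tokens)) tokens[j + 1L] else ""
        if (marker %in% c("[/]", "[//]")) {
          events[[length(events) + 1L]] <- list(
            type = if (marker == "[/]") "repetition_marked" else "revision_marked",
            utterance = utt, duration = NA_real_
          )
          i <- j + 2L  # retraced material excluded from the word stream
        } else {
          warnings <- c(warnings,
                        sprintf("line %d: '<...>' group without retrace marker", li))
          grp <- gsub("[<>]", "", tokens[i:j])
          for (g in grp[grp != ""]) {
            words[[length(words) + 1L]] <- word_record(g, utt)
          }
          i <- j + 1L
        }
        next
      }
      if (startsWith(tok, "[")) {
        # bare-word retrace: the preceding word is the retraced material
        if (tok %in% c("[/]", "[//]") && length(words)) {
          last <- words[[length(words)]]
          if (last$utterance == utt) {
            words[[length(words)]] <- NULL
            events[[length(events) + 1L]] <- list(
              type = if (tok == "[/]") "repetition_marked" else "revision_marked",
              utterance = utt, duration = NA_real_
            )
            i <- i + 1L
            next
          }
        }
        # unknown bracket code, possibly spanning tokens: "[x 2]"
        j <- i
        while (j <= length(tokens) && !endsWith(tokens[j], "]")) j <- j + 1L
        j <- min(j, length(tokens))
        warnings <- c(warnings,
                      sprintf("line %d: unknown code '%s' skipped", li,
                              paste(tokens[i:j], collapse = " ")))
        i <- j + 1L
        next
      }
      words[[length(words) + 1L]] <- word_record(tok, utt)
      i <- i + 1L
    }
  }
  words_df <- if (length(words)) {
    tibble::tibble(
      word = vapply(words, `[[`, character(1), "word"),
      raw = vapply(words, `[[`, character(1), "raw"),
      utterance = vapply(words, `[[`, integer(1), "utterance"),
      prolonged = vapply(words, `[[`, logical(1), "prolonged")
    )
  } else {
    tibble::tibble(word = character(), raw = character(),
                   utterance = integer(), prolonged = logical())
  }
  events_df <- if (length(events)) {
    tibble::tibble(
      type = vapply(events, `[[`, character(1), "type"),
      utterance = vapply(events, `[[`, integer(1), "utterance"),
      duration = vapply(events, `[[`, numeric(1), "duration")
    )
  } else {
    tibble::tibble(type = character(), utterance = integer(), duration = numeric())
  }
  structure(
    list(
      words = words_df,
      events = events_df,
      word_total = count_collapsed_words(words_df),
      warnings = warnings
    ),
    class = "segspeech_transcript"
  )
}

word_record <- function(tok, utt) {
  clean <- gsub("[.,!?]+$", "", tok)
  prolonged <- grepl("[a-zA-Z]:", clean)
  list(word = tolower(gsub(":", "", clean)), raw = tok,
       utterance = utt, prolonged = prolonged)
}

# verbatim immediate-repeat runs within an utterance count as one word
count_collapsed_words <- function(words_df) {
  if (!nrow(words_df)) return(0L)
  keep <- c(TRUE, !(words_df$word[-1] == words_df$word[-nrow(words_df)] &
                      words_df$utterance[-1] == words_df$utterance[-nrow(words_df)]))
  sum(keep)
}

repeat_runs <- function(words_df) {
  if (nrow(words_df) < 2) return(0L)
  same <- words_df$word[-1] == words_df$word[-nrow(words_df)] &
    words_df$utterance[-1] == words_df$utterance[-nrow(words_df)]
  # one event per maximal run: count starts of TRUE stretches
  sum(same & !c(FALSE, same[-length(same)]))
}

#' Count the five disfluency subtypes in a parsed transcript
#'
#' * **filled**: `&-` filler tokens plus lexical fillers from a configurable
#'   lexicon matched (longest phrase first, non-overlapping) in the spoken
#'   word stream; lexical-filler words still count toward the word total.
#' * **unfilled**: timed pauses whose duration strictly exceeds
#'   `pause_threshold` seconds (a pause of exactly 1.0 s is not counted).
#' * **repetition**: `[/]`-marked retraces plus unmarked verbatim
#'   immediate-repeat runs within an utterance (one event per run).
#' * **revision**: `[//]`-marked retraces.
#' * **prolongation**: words carrying a colon lengthening mark.
#'
#' @param transcript A `segspeech_transcript` from [parse_chat()].
#' @param filler_lexicon Character vector of lexical fillers (phrases
#'   allowed).
#' @param pause_threshold Silence duration in seconds above which a pause is
#'   counted (default 1.0).
#' @return Named integer vector over `filled`, `unfilled`, `repetition`,
#'   `revision`, `prolongation`.
#' @export
count_disfluencies <- function(transcript,
                               filler_lexicon = c("um", "uh", "you know", "like"),
                               pause_threshold = 1.0) {
  stopifnot(inherits(transcript, "segspeech_transcript"))
  ev <- transcript$events
  wd <- transcript$words
  filled <- sum(ev$type == "filled_token") +
    lexicon_matches(wd, filler_lexicon)
  unfilled <- sum(ev$type == "pause" & !is.na(ev$duration) &
                    ev$duration > pause_threshold)
  repetition <- sum(ev$type == "repetition_marked") + repeat_runs(wd)
  revision <- sum(ev$type == "revision_marked")
  prolongation <- sum(wd$prolonged)
  c(filled = as.integer(filled), unfilled = as.integer(unfilled),
    repetition = as.integer(repetition), revision = as.integer(revision),
    prolongation = as.integer(prolongation))
}

lexicon_matches <- function(words_df, lexicon) {
  if (!nrow(words_df) || !length(lexicon)) return(0L)
  phrases <- strsplit(tolower(lexicon), "\\s+")
  phrases <- phrases[order(-lengths(phrases))]
  n_match <- 0L
  for (u in unique(words_df$utterance)) {
    w <- words_df$word[words_df$utterance == u]
    i <- 1L
    while (i <= length(w)) {
      hit <- FALSE
      for (ph in phrases) {
        k <- length(ph)
        if (i + k - 1L <= length(w) && all(w[i:(i + k - 1L)] == ph)) {
          n_match <- n_match + 1L
          i <- i + k
          hit <- TRUE
          break
        }
      }
      if (!hit) i <- i + 1L
    }
  }
  n_match
}

#' Proportional disfluency profile
#'
#' Converts subtype counts to percentages of the word total. The total is
#' the sum of the five subtype percentages.
#'
#' @param counts Named counts as returned by [count_disfluencies()].
#' @param word_total Number of spoken words (> 0).
#' @param task_id Optional task label.
#' @return A one-row tibble with `*_pct` columns, `total_pct`, `word_total`,
#'   `task_id`.
#' @export
disfluency_profile <- function(counts, word_total, task_id = NA_character_) {
  if (word_total <= 0) {
    stop_segspeech("word_total must be positive; rates are undefined otherwise",
                   "segspeech_degenerate_error")
  }
  pct <- 100 * counts / word_total
  tibble::tibble(
    filled_pct = pct[["filled"]],
    unfilled_pct = pct[["unfilled"]],
    repetition_pct = pct[["repetition"]],
    revision_pct = pct[["revision"]],
    prolongation_pct = pct[["prolongation"]],
    total_pct = sum(pct),
    word_total = word_total,
    task_id = task_id
  )
}

#' Average disfluency profiles across elicitation tasks
#'
#' Participants with two speech tasks (picture-book narration and an
#' open-ended prompt) get the unweighted elementwise mean of their two
#' profiles; a single profile passes through unchanged.
#'
#' @param profiles A tibble of 1 or 2 rows as returned by
#'   [disfluency_profile()].
#' @return A one-row tibble in the same format (`task_id` = `"averaged"`
#'   when two tasks were combined).
#' @export
average_tasks <- function(profiles) {
  if (nrow(profiles) < 1 || nrow(profiles) > 2) {
    stop_segspeech("average_tasks expects 1 or 2 profiles per participant",
                   "segspeech_usage_error")
  }
  if (nrow(profiles) == 1) return(profiles)
  cols <- c("filled_pct", "unfilled_pct", "repetition_pct", "revision_pct",
            "prolongation_pct", "total_pct", "word_total")
  out <- profiles[1, ]
  for (cc in cols) out[[cc]] <- mean(profiles[[cc]])
  out$task_id <- "averaged"
  out
}

#' Stroop interference score
#'
#' Mean reaction time on incongruent trials minus mean reaction time on
#' congruent trials, in milliseconds. Error trials are excluded by default.
#'
#' @param trials A data frame with columns `condition` (`"congruent"` /
#'   `"incongruent"`), `rt_ms` (> 0), and optionally `correct` (logical).
#' @param correct_only Drop incorrect trials first (default `TRUE`).
#' @return Interference in ms.
#' @export
#' @examples
#' stroop_interference(data.frame(
#'   condition = c("congruent", "congruent", "incongruent", "incongruent"),
#'   rt_ms = c(500, 520, 600, 640)
#' ))
stroop_interference <- function(trials, correct_only = TRUE) {
  require_columns(trials, c("condition", "rt_ms"), "stroop_interference")
  if (correct_only && "correct" %in% names(trials)) {
    trials <- trials[as.logical(trials$correct), , drop = FALSE]
  }
  if (any(trials$rt_ms <= 0)) {
    stop_segspeech("reaction times must be positive", "segspeech_schema_error")
  }
  cong <- trials$rt_ms[trials$condition == "congruent"]
  incong <- trials$rt_ms[trials$condition == "incongruent"]
  if (!length(cong) || !length(incong)) {
    stop_segspeech("need at least one trial per condition", "segspeech_degenerate_error")
  }
  mean(incong) - mean(cong)
}
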