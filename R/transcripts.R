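#' Simulate a CHAT-style transcript with known disfluency counts
#'
#' Emits a transcript in the documented CHAT subset (see [parse_chat()]) in
#' which disfluency events are inserted at exactly
#' `round(rate * n_words / 100)` per subtype, at seeded positions. The
#' returned insertion log is the round-trip oracle for the parser: for any
#' seed, [count_disfluencies()] on the generated text must reproduce it
#' exactly. Base words are drawn from a small vocabulary that avoids filler
#' lexicon entries and accidental immediate repeats, so every counted event
#' is an inserted one.
#'
#' @param rates Named numeric vector of per-100-word rates with names among
#'   `filled`, `unfilled`, `repetition`, `revision`, `prolongation`
#'   (missing subtypes default to 0). All rates must lie in `[0, 100]` and
#'   sum to at most 100.
#' @param n_words Number of spoken words in the transcript (>= 1).
#' @param seed Integer seed.
#' @return A list with `text` (single string, CHAT subset), `counts` (named
#'   integer vector over the five subtypes), and `word_total` (= `n_words`).
#' @export
#' @examples
#' tr <- simulate_transcript(c(repetition = 5, filled = 2), n_words = 100, seed = 1)
#' tr$counts
simulate_transcript <- function(rates, n_words, seed = 1L) {
  subtypes <- c("filled", "unfilled", "repetition", "revision", "prolongation")
  full <- setNames(numeric(5), subtypes)
  if (length(rates)) {
    unknown <- setdiff(names(rates), subtypes)
    if (length(unknown)) {
      stop_segspeech(
        sprintf("unknown disfluency subtype(s): %s", paste(unknown, collapse = ", ")),
        "segspeech_parameter_error"
      )
    }
    full[names(rates)] <- rates
  }
  if (any(full < 0 | full > 100)) {
    stop_segspeech("rates must lie in [0, 100]", "segspeech_parameter_error")
  }
  if (sum(full) > 100) {
    stop_segspeech("rates must sum to at most 100", "segspeech_parameter_error")
  }
  if (n_words < 1) {
    stop_segspeech("n_words must be at least 1", "segspeech_parameter_error")
  }
  counts <- setNames(as.integer(round(full * n_words / 100)), subtypes)
  if (sum(counts) > n_words) {
    stop_segspeech("rounded event counts exceed the word count", "segspeech_parameter_error")
  }
  set.seed(seed)
  vocab <- c("frog", "went", "over", "into", "tree", "boy", "dog", "jar",
             "window", "forest", "then", "and", "looked", "under", "found",
             "house", "night", "ran", "fell", "called")
  words <- character(n_words)
  prev <- ""
  for (i in seq_len(n_words)) {
    repeat {
      w <- sample(vocab, 1)
      if (w != prev) break
    }
    words[i] <- w
    prev <- w
  }
  # one event at most per word slot
  slots <- sample.int(n_words, sum(counts))
  assign_type <- rep(subtypes, counts)
  rendered <- words
  for (k in seq_along(slots)) {
    i <- slots[k]
    w <- words[i]
    rendered[i] <- switch(
      assign_type[k],
      filled = paste(sample(c("&-um", "&-uh"), 1), w),
      unfilled = paste(sprintf("(%.1f)", round(runif(1, 1.1, 3.0), 1)), w),
      repetition = sprintf("<%s> [/] %s", w, w),
      revision = sprintf("<%s> [//] %s", sample(setdiff(vocab, w), 1), w),
      prolongation = sub("^(.)", "\\1:", w)
    )
  }
  per_line <- 10
  lines <- split(rendered, ceiling(seq_along(rendered) / per_line))
  body <- vapply(lines, function(x) paste0("*PAR:\t", paste(x, collapse = " "), " ."),
                 character(1))
  text <- paste(c("@Begin", "@Participants:\tPAR Participant", body, "@End"),
                collapse = "\n")
  list(text = text, counts = counts, word_total = n_words)
}
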