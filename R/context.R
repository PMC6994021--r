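# Context resolution: rule-based negation detection (NegEx-style window with
# scope terminators) and temporal-expression resolution to calendar dates.

#' Default negation cue table
#'
#' Bundled, editable list of negation cues and scope terminators
#' (`inst/extdata/negation_cues.csv`).
#'
#' @return Tibble with columns `token`, `role` (`negator` / `terminator`).
#' @export
default_negation_cues <- function() {
  readr::read_csv(
    system.file("extdata", "negation_cues.csv", package = "forumlot", mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE
  )
}

.negation_token_regex <- "[a-z0-9']+(?:-[a-z0-9']+)*"

#' Is a treatment mention negated?
#'
#' A mention is negated when a negation cue occurs within the `window`
#' tokens immediately preceding it in the same sentence, unless a scope
#' terminator (but, however, although, ...) stands between the cue and the
#' mention.
#'
#' @param sentence Sentence text (cleaned).
#' @param mention_start 1-based character position where the mention begins.
#' @param cues Cue table, see [default_negation_cues()].
#' @param window Number of preceding tokens scanned.
#' @return Logical.
#' @examples
#' detect_negation("I did not take temozolomide", 16)
#' @export
detect_negation <- function(sentence, mention_start,
                            cues = default_negation_cues(), window = 5L) {
  lower <- tolower(sentence)
  m <- gregexpr(.negation_token_regex, lower, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(FALSE)
  }
  len <- attr(m, "match.length")
  tok <- substring(lower, m, m + len - 1L)
  preceding <- which(m + len - 1L < mention_start)
  if (length(preceding) == 0L) {
    return(FALSE)
  }
  win <- utils::tail(preceding, window)
  toks <- tok[win]
  negators <- cues$token[cues$role == "negator"]
  terminators <- cues$token[cues$role == "terminator"]
  cue_pos <- which(toks %in% negators)
  if (length(cue_pos) == 0L) {
    return(FALSE)
  }
  term_pos <- which(toks %in% terminators)
  # a cue scopes the mention unless a terminator lies strictly between them
  any(vapply(cue_pos, function(cp) !any(term_pos > cp), logical(1)))
}

.month_names <- c(
  "january", "february", "march", "april", "may", "june", "july",
  "august", "september", "october", "november", "december"
)
.number_words <- c(
  one = 1, two = 2, three = 3, four = 4, five = 5, six = 6, seven = 7,
  eight = 8, nine = 9, ten = 10, eleven = 11, twelve = 12, a = 1, an = 1
)

word_to_n <- function(w) {
  if (grepl("^\\d+$", w)) as.integer(w) else as.integer(.number_words[[w]])
}

shift_units <- function(date, n, unit) {
  switch(unit,
    day = date + n,
    week = date + 7L * n,
    month = date %m+% months(as.integer(n)),
    year = date %m+% lubridate::years(as.integer(n))
  )
}

#' Resolve the calendar date a sentence refers to
#'
#' Handles absolute month expressions ("in March 2014", "3/2014"; day fixed
#' to 15), relative expressions ("three months ago", "2 weeks ago", "last
#' year", "yesterday", and future forms like "next month" or "in two
#' weeks"), and otherwise defaults to the post date. Total: always returns a
#' date and a resolution rule. Precedence: explicit date, then relative
#' offset, then default.
#'
#' @param sentence Sentence text.
#' @param post_date Date of the post.
#' @return List with `event_date` (Date) and `resolution_rule` (one of
#'   `"explicit_date"`, `"relative_offset"`, `"post_date_default"`).
#' @examples
#' resolve_time("I received temozolomide three months ago", as.Date("2015-06-20"))
#' @export
resolve_time <- function(sentence, post_date) {
  lower <- tolower(sentence)
  post_date <- as.Date(post_date)

  month_rx <- paste0("\\b(", paste(.month_names, collapse = "|"), ")\\s+((?:19|20)\\d{2})\\b")
  m <- regmatches(lower, regexec(month_rx, lower, perl = TRUE))[[1]]
  if (length(m) == 3L) {
    mo <- match(m[2], .month_names)
    return(list(
      event_date = as.Date(sprintf("%s-%02d-15", m[3], mo)),
      resolution_rule = "explicit_date"
    ))
  }
  num_rx <- "\\b(0?[1-9]|1[0-2])\\s*/\\s*((?:19|20)\\d{2})\\b"
  m <- regmatches(lower, regexec(num_rx, lower, perl = TRUE))[[1]]
  if (length(m) == 3L) {
    return(list(
      event_date = as.Date(sprintf("%s-%02d-15", m[3], as.integer(m[2]))),
      resolution_rule = "explicit_date"
    ))
  }

  nums <- paste(c("\\d{1,3}", names(.number_words)), collapse = "|")
  rel_rx <- paste0("\\b(", nums, ")\\s+(day|week|month|year)s?\\s+(?:ago|back|earlier)\\b")
  m <- regmatches(lower, regexec(rel_rx, lower, perl = TRUE))[[1]]
  if (length(m) == 3L) {
    return(list(
      event_date = shift_units(post_date, -word_to_n(m[2]), m[3]),
      resolution_rule = "relative_offset"
    ))
  }
  m <- regmatches(lower, regexec("\\blast\\s+(day|week|month|year)\\b", lower, perl = TRUE))[[1]]
  if (length(m) == 2L) {
    return(list(
      event_date = shift_units(post_date, -1L, m[2]),
      resolution_rule = "relative_offset"
    ))
  }
  if (grepl("\\byesterday\\b", lower)) {
    return(list(event_date = post_date - 1L, resolution_rule = "relative_offset"))
  }
  m <- regmatches(lower, regexec("\\bnext\\s+(day|week|month|year)\\b", lower, perl = TRUE))[[1]]
  if (length(m) == 2L) {
    return(list(
      event_date = shift_units(post_date, 1L, m[2]),
      resolution_rule = "relative_offset"
    ))
  }
  m <- regmatches(lower, regexec(
    paste0("\\bin\\s+(", nums, ")\\s+(day|week|month|year)s?\\b"), lower,
    perl = TRUE
  ))[[1]]
  if (length(m) == 3L) {
    return(list(
      event_date = shift_units(post_date, word_to_n(m[2]), m[3]),
      resolution_rule = "relative_offset"
    ))
  }
  if (grepl("\\btomorrow\\b", lower)) {
    return(list(event_date = post_date + 1L, resolution_rule = "relative_offset"))
  }
  list(event_date = post_date, resolution_rule = "post_date_default")
}

#' Filter and date treatment mentions
#'
#' Applies the three conjunctive gates in pipeline order: the sentence must
#' be classified as stating treatment receipt, the mention must not be
#' negated, and the resolved event date must not lie more than `future_slack`
#' days after the post date (future-dated treatment talk is intent, not
#' receipt). Surviving mentions carry their resolved event date.
#'
#' @param mentions Mention table from [mentions_table()].
#' @param sentences Sentence table from [tokenize_posts()] (provides text).
#' @param verdicts Tibble `user_id`, `post_id`, `sentence_index`, `label`
#'   with the classifier verdict (`receipt` / `non_receipt`) for every
#'   mention-bearing sentence; a missing verdict is an error.
#' @param cues Negation cue table.
#' @param window Negation window (tokens).
#' @param future_slack Days of tolerated future-dating.
#' @return Tibble of resolved mentions: sentence keys, `canonical`,
#'   `negated` (always `FALSE` for retained rows), `event_date`,
#'   `resolution_rule`.
#' @export
resolve_mentions <- function(mentions, sentences, verdicts,
                             cues = default_negation_cues(), window = 5L,
                             future_slack = 30L) {
  key <- c("user_id", "post_id", "sentence_index")
  empty <- tibble(
    user_id = character(), forum = character(),
    post_date = as.Date(character()), post_id = integer(),
    sentence_index = integer(), canonical = character(), negated = logical(),
    event_date = as.Date(character()), resolution_rule = character()
  )
  if (nrow(mentions) == 0L) {
    return(empty)
  }
  sen <- sentences |> select(dplyr::all_of(key), "text")
  df <- mentions |>
    inner_join(sen, by = key) |>
    left_join(verdicts |> select(dplyr::all_of(key), "label"), by = key)
  if (nrow(df) < nrow(mentions)) abort("mention without a matching sentence")
  if (anyNA(df$label)) abort("missing classifier verdict for a mention's sentence")

  # resolve each distinct sentence once
  sent_keys <- df |> distinct(dplyr::across(dplyr::all_of(c(key, "text", "post_date"))))
  res <- lapply(seq_len(nrow(sent_keys)), function(i) {
    resolve_time(sent_keys$text[i], sent_keys$post_date[i])
  })
  sent_keys$event_date <- as.Date(vapply(res, function(r) as.character(r$event_date), character(1)))
  sent_keys$resolution_rule <- vapply(res, `[[`, character(1), "resolution_rule")

  df <- df |> inner_join(
    sent_keys |> select(dplyr::all_of(key), "event_date", "resolution_rule"),
    by = key
  )
  df$negated <- vapply(seq_len(nrow(df)), function(i) {
    detect_negation(df$text[i], df$start[i], cues = cues, window = window)
  }, logical(1))

  kept <- df |>
    filter(
      .data$label == "receipt",
      !.data$negated,
      .data$event_date <= .data$post_date + future_slack
    ) |>
    select(
      "user_id", "forum", "post_date", "post_id", "sentence_index",
      "canonical", "negated", "event_date", "resolution_rule"
    )
  kept
}
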