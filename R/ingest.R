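# Corpus ingestion: read post dumps, clean text, tokenize into sentences,
# derive stable user ids, and restrict to users with at least one treatment
# mention.

#' Clean raw forum text
#'
#' Removes URLs and characters outside a fixed whitelist (letters, digits,
#' space, and `. , ! ? ' - /`), then collapses whitespace. Sentence
#' terminators are deliberately kept so that [split_sentences()] still sees
#' boundaries. Casing is preserved; lowercasing happens at feature time.
#' The operation is idempotent.
#'
#' @param x Character vector of raw post texts.
#' @return Character vector of cleaned texts (possibly `""`).
#' @examples
#' clean_text("started ipi!! see http://x.co/a")
#' @export
clean_text <- function(x) {
  x <- gsub("(?i)\\b(?:https?://|www\\.)\\S+", " ", x, perl = TRUE)
  x <- gsub("[^A-Za-z0-9 .,!?'/-]", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

.abbreviations <- c(
  "dr", "mr", "mrs", "ms", "st", "prof", "vs", "etc", "approx", "fig",
  "jan", "feb", "mar", "apr", "jun", "jul", "aug", "sep", "sept", "oct",
  "nov", "dec"
)

#' Split cleaned text into sentences
#'
#' Boundaries are `.`, `!` or `?` followed by whitespace; a guard list of
#' common abbreviations ("Dr.", "vs.", month abbreviations, ...) suppresses
#' spurious splits. Concatenating the result (modulo boundary whitespace)
#' reproduces the input.
#'
#' @param x A single cleaned text (length-1 character).
#' @return Character vector of sentences; `character(0)` for empty input.
#' @examples
#' split_sentences("I took ipi. It worked.")
#' split_sentences("Dr. Smith started me on nivo.")
#' @export
split_sentences <- function(x) {
  stopifnot(length(x) == 1L)
  if (is.na(x) || !nzchar(trimws(x))) {
    return(character(0))
  }
  guard <- paste0("(?i)\\b(", paste(.abbreviations, collapse = "|"), ")\\.")
  y <- gsub(guard, "\\1\u0001", x, perl = TRUE)
  parts <- strsplit(y, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  parts <- gsub("\u0001", ".", parts, fixed = TRUE)
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Derive a stable opaque user id from username and forum
#'
#' The same username on two forums yields two distinct ids (one forum account
#' is taken to be one patient). Ids are deterministic fixed-width hex strings
#' (FNV-1a hash of forum + username).
#'
#' @param username,forum Non-empty character vectors (recycled together).
#' @return Character vector of 8-character hex ids.
#' @export
make_user_id <- function(username, forum) {
  if (any(!nzchar(username)) || any(is.na(username))) {
    abort("username must be non-empty")
  }
  if (any(!nzchar(forum)) || any(is.na(forum))) {
    abort("forum must be non-empty")
  }
  h <- fnv1a32(paste(forum, username, sep = "\u001f"))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

parse_post_date <- function(x) {
  if (inherits(x, "Date")) {
    return(x)
  }
  x <- as.character(x)
  out <- as.Date(rep(NA_character_, length(x)))
  for (fmt in c("%Y-%m-%d", "%Y/%m/%d", "%m/%d/%Y", "%B %d, %Y", "%b %d, %Y")) {
    idx <- which(is.na(out))
    if (length(idx) == 0L) break
    out[idx] <- as.Date(x[idx], format = fmt)
  }
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    abort(paste0(
      "unparseable post date(s): ",
      paste(utils::head(bad, 3L), collapse = ", ")
    ))
  }
  out
}

#' Read forum posts from a JSONL dump
#'
#' One JSON object per line with fields `username`, `forum`, `post_date`
#' (ISO-8601 or common US formats; unparseable dates fail loudly) and `text`.
#'
#' @param path Path to a JSONL file.
#' @return A tibble with columns `username`, `forum`, `post_date`, `text`.
#' @seealso [write_posts_jsonl()]
#' @export
read_posts_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  tibble(
    username = vapply(recs, function(r) as.character(r$username), character(1)),
    forum = vapply(recs, function(r) as.character(r$forum), character(1)),
    post_date = parse_post_date(vapply(recs, function(r) as.character(r$post_date), character(1))),
    text = vapply(recs, function(r) as.character(r$text), character(1))
  )
}

#' Write forum posts as JSONL
#'
#' @param posts Tibble with columns `username`, `forum`, `post_date`, `text`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_posts_jsonl <- function(posts, path) {
  lines <- vapply(seq_len(nrow(posts)), function(i) {
    jsonlite::toJSON(
      list(
        username = posts$username[i],
        forum = posts$forum[i],
        post_date = format(posts$post_date[i], "%Y-%m-%d"),
        text = posts$text[i]
      ),
      auto_unbox = TRUE
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Build the analytic sentence table from raw posts
#'
#' Deduplicates identical (username, forum, post_date, text) posts, derives
#' user ids, cleans the text and splits it into sentences. The result is
#' sorted chronologically within user (earliest post first).
#'
#' @param posts Tibble as returned by [read_posts_jsonl()].
#' @return A tibble of sentence records: `user_id`, `username`, `forum`,
#'   `post_date`, `post_id` (per-user chronological index), `sentence_index`
#'   (0-based within post), `text` (cleaned sentence).
#' @export
tokenize_posts <- function(posts) {
  stopifnot(all(c("username", "forum", "post_date", "text") %in% names(posts)))
  posts <- posts |>
    mutate(post_date = parse_post_date(.data$post_date)) |>
    distinct(.data$username, .data$forum, .data$post_date, .data$text) |>
    mutate(user_id = make_user_id(.data$username, .data$forum)) |>
    arrange(.data$user_id, .data$post_date, .data$text) |>
    group_by(.data$user_id) |>
    mutate(post_id = row_number()) |>
    ungroup()
  sentences <- lapply(seq_len(nrow(posts)), function(i) {
    s <- split_sentences(clean_text(posts$text[i]))
    if (length(s) == 0L) {
      return(NULL)
    }
    tibble(
      user_id = posts$user_id[i],
      username = posts$username[i],
      forum = posts$forum[i],
      post_date = posts$post_date[i],
      post_id = posts$post_id[i],
      sentence_index = seq_along(s) - 1L,
      text = s
    )
  })
  out <- bind_rows(sentences)
  if (nrow(out) == 0L) {
    return(tibble(
      user_id = character(), username = character(), forum = character(),
      post_date = as.Date(character()), post_id = integer(),
      sentence_index = integer(), text = character()
    ))
  }
  arrange(out, .data$user_id, .data$post_date, .data$post_id, .data$sentence_index)
}

#' Keep only users with at least one treatment mention
#'
#' The filter is user-level: all sentences of a user with one or more lexicon
#' matches anywhere are retained; every sentence of a user with none is
#' dropped.
#'
#' @param records Sentence table from [tokenize_posts()].
#' @param lexicon A treatment lexicon, see [load_lexicon()].
#' @return Filtered sentence table.
#' @export
filter_treatment_users <- function(records, lexicon = default_lexicon()) {
  if (nrow(records) == 0L) {
    return(records)
  }
  hits <- find_mentions(records$text, lexicon)
  keep <- unique(records$user_id[hits$item])
  records[records$user_id %in% keep, , drop = FALSE]
}
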