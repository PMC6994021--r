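# Shared fixtures: everything is built in code at test time.

tiny_posts <- function() {
  tibble::tibble(
    username = c("alice", "alice", "bob", "carol"),
    forum = c("melanoma.org", "melanoma.org", "melanoma.org", "cancer-compass"),
    post_date = as.Date(c("2014-03-20", "2014-09-10", "2015-02-01", "2015-06-01")),
    text = c(
      "Started ipilimumab in March 2014. Feeling hopeful.",
      "I started dabrafenib and trametinib in September 2014.",
      "I did not take temozolomide. My last scan came back stable.",
      "No treatments to report here, just checking in."
    )
  )
}

# resolved-mention rows for line-assignment tests
resolved_row <- function(user_id, drug, event_date, post_date = event_date) {
  tibble::tibble(
    user_id = user_id, forum = "melanoma.org",
    post_date = as.Date(post_date), post_id = 1L, sentence_index = 0L,
    canonical = drug, negated = FALSE, event_date = as.Date(event_date),
    resolution_rule = "explicit_date"
  )
}

resolved_rows <- function(user_id, drugs, dates) {
  dplyr::bind_rows(Map(function(d, dt) resolved_row(user_id, d, dt), drugs, dates))
}

write_lexicon_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  readr::write_csv(rows, path)
  path
}

# truth vs recovered line comparison (regimen sets and line numbers)
lines_frame <- function(truth) {
  truth |>
    dplyr::transmute(
      user_id = forumlot::make_user_id(username, forum),
      line_number = line_number,
      regimen = forumlot::normalize_regimen(regimen)
    ) |>
    dplyr::arrange(user_id, line_number) |>
    as.data.frame()
}

recovered_frame <- function(lines) {
  lines |>
    dplyr::transmute(
      user_id = patient_id,
      line_number = line_number,
      regimen = regimen
    ) |>
    dplyr::arrange(user_id, line_number) |>
    as.data.frame()
}
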