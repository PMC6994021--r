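# Line-of-therapy derivation: chronological per-patient timelines and
# numbered lines with combination and adjuvant rules.

#' Canonicalize a regimen label
#'
#' Regimens compare as sorted sets of canonical drug names. Labels like
#' "Dabrafenib and Trametinib", "ipi/nivo" or "trametinib+dabrafenib" all
#' normalize to the same string (lowercased drugs sorted and joined with
#' `+`).
#'
#' @param x Character vector of regimen labels.
#' @return Normalized labels.
#' @export
normalize_regimen <- function(x) {
  vapply(x, function(lbl) {
    parts <- strsplit(tolower(lbl), "\\s*(?:\\+|/|,|\\band\\b)\\s*", perl = TRUE)[[1]]
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    paste(sort(parts), collapse = "+")
  }, character(1), USE.NAMES = FALSE)
}

regimen_label <- function(drugs) paste(sort(unique(drugs)), collapse = "+")

#' Build a single patient's treatment-event timeline
#'
#' Events are deduplicated at (drug, calendar month) granularity, keeping
#' the earliest date within the month, and sorted by date with same-date
#' ties ordered alphabetically by drug for determinism.
#'
#' @param resolved Resolved mentions of one user ([resolve_mentions()]).
#' @return Tibble `user_id`, `event_date`, `drug`.
#' @export
build_timeline <- function(resolved) {
  if (nrow(resolved) == 0L) {
    return(tibble(user_id = character(), event_date = as.Date(character()), drug = character()))
  }
  if (length(unique(resolved$user_id)) > 1L) {
    abort("build_timeline expects mentions of a single user")
  }
  resolved |>
    mutate(month = format(.data$event_date, "%Y-%m")) |>
    group_by(.data$user_id, .data$canonical, .data$month) |>
    summarise(event_date = min(.data$event_date), .groups = "drop") |>
    rename(drug = "canonical") |>
    arrange(.data$event_date, .data$drug) |>
    select("user_id", "event_date", "drug")
}

#' Assign numbered lines of therapy to a timeline
#'
#' Rules: (1) the first non-adjuvant event opens line 1; (2) a drug whose
#' first event falls within `combo_window_days` of the current line's start
#' joins that line's regimen; (3) a drug not in the current regimen
#' appearing after the window closes the line and opens the next; (4)
#' re-mentions of current-regimen drugs never advance lines; (5) events that
#' would leave a line's regimen as interferon-only or docetaxel-only are
#' skipped (adjuvant monotherapy is not a line); (6) interferon/docetaxel
#' falling inside a multi-drug window do count as combination members.
#'
#' @param timeline Timeline from [build_timeline()].
#' @param combo_window_days Combination window in days (default 28, the
#'   usual claims-analytics convention).
#' @param lexicon Lexicon supplying the adjuvant-only drug set.
#' @return Tibble `patient_id`, `line_number`, `regimen` (normalized label),
#'   `start_date`.
#' @export
assign_lines <- function(timeline, combo_window_days = 28L,
                         lexicon = default_lexicon()) {
  empty <- tibble(
    patient_id = character(), line_number = integer(),
    regimen = character(), start_date = as.Date(character())
  )
  if (nrow(timeline) == 0L) {
    return(empty)
  }
  tl <- arrange(timeline, .data$event_date, .data$drug)
  al <- assign_lines_core(tl$drug, tl$event_date, lexicon$adjuvant, combo_window_days)
  if (length(al$regimens) == 0L) {
    return(empty)
  }
  tibble(
    patient_id = timeline$user_id[1L],
    line_number = seq_along(al$regimens),
    regimen = vapply(al$regimens, regimen_label, character(1)),
    start_date = al$starts
  )
}

# Core line-assignment over parallel (drug, date) vectors sorted by date
# then drug. Lines are anchored by non-adjuvant events; adjuvant events
# then join a line when falling inside [start, start + window] (rule 6) and
# are skipped otherwise (rule 5).
assign_lines_core <- function(drugs, dates, adjuvant, combo_window_days) {
  is_adj <- drugs %in% adjuvant
  core_drug <- drugs[!is_adj]
  core_date <- dates[!is_adj]
  if (length(core_drug) == 0L) {
    return(list(regimens = list(), starts = as.Date(character())))
  }
  starts <- as.Date(character())
  regimens <- list()
  cur <- NULL
  cur_start <- NULL
  for (i in seq_along(core_drug)) {
    d <- core_drug[i]
    dt <- core_date[i]
    if (is.null(cur)) {
      cur <- d
      cur_start <- dt
    } else if (d %in% cur) {
      next # re-mention of a current-regimen drug never advances lines
    } else if (as.numeric(dt - cur_start) <= combo_window_days) {
      cur <- c(cur, d)
    } else {
      starts <- c(starts, cur_start)
      regimens <- c(regimens, list(cur))
      cur <- d
      cur_start <- dt
    }
  }
  starts <- c(starts, cur_start)
  regimens <- c(regimens, list(cur))
  if (any(is_adj)) {
    adj_drug <- drugs[is_adj]
    adj_date <- dates[is_adj]
    for (i in seq_along(adj_drug)) {
      offs <- as.numeric(adj_date[i] - starts)
      ok <- which(offs >= 0 & offs <= combo_window_days)
      if (length(ok) > 0L) {
        regimens[[ok[1L]]] <- unique(c(regimens[[ok[1L]]], adj_drug[i]))
      }
    }
  }
  list(regimens = regimens, starts = starts)
}

#' Derive lines of therapy for every patient
#'
#' Equivalent to [build_timeline()] + [assign_lines()] per user, but
#' deduplicates events in one pass across the whole cohort.
#'
#' @param resolved Resolved-mention table (any number of users).
#' @param combo_window_days Combination window in days.
#' @param lexicon Treatment lexicon.
#' @return Tibble of lines across patients (schema of [assign_lines()]).
#' @export
derive_lines <- function(resolved, combo_window_days = 28L,
                         lexicon = default_lexicon()) {
  empty <- tibble(
    patient_id = character(), line_number = integer(),
    regimen = character(), start_date = as.Date(character())
  )
  if (nrow(resolved) == 0L) {
    return(empty)
  }
  events <- resolved |>
    mutate(month = format(.data$event_date, "%Y-%m")) |>
    group_by(.data$user_id, .data$canonical, .data$month) |>
    summarise(event_date = min(.data$event_date), .groups = "drop") |>
    arrange(.data$user_id, .data$event_date, .data$canonical)
  adjuvant <- lexicon$adjuvant
  by_user <- split(
    list(drug = events$canonical, date = events$event_date) |> as.data.frame(),
    events$user_id
  )
  ids <- character(0)
  nums <- integer(0)
  regs <- character(0)
  starts <- as.Date(character())
  for (uid in names(by_user)) {
    ev <- by_user[[uid]]
    al <- assign_lines_core(ev$drug, ev$date, adjuvant, combo_window_days)
    k <- length(al$regimens)
    if (k == 0L) next
    ids <- c(ids, rep(uid, k))
    nums <- c(nums, seq_len(k))
    regs <- c(regs, vapply(al$regimens, regimen_label, character(1)))
    starts <- c(starts, al$starts)
  }
  tibble(
    patient_id = ids, line_number = nums, regimen = regs, start_date = starts
  )
}

#' Patient counts by treatment line
#'
#' Counts of patients with at least one, two and three lines, with
#' percentages relative to the first-line count (one decimal). Lines beyond
#' the third are counted when `max_line` is raised.
#'
#' @param lines Line table ([derive_lines()] or comparator lines).
#' @param max_line Deepest line to report.
#' @return Tibble `line_number`, `n_patients`, `pct` (percent of first-line
#'   patients; `NA` when there are none).
#' @export
line_counts <- function(lines, max_line = 3L) {
  ks <- seq_len(max_line)
  n <- vapply(ks, function(k) {
    if (nrow(lines) == 0L) 0L else length(unique(lines$patient_id[lines$line_number >= k]))
  }, integer(1))
  pct <- if (n[1] == 0L) rep(NA_real_, max_line) else round(100 * n / n[1], 1)
  tibble(line_number = ks, n_patients = n, pct = pct)
}
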