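# Cohort comparison: frequency matching on first-line year, per-line
# treatment proportions with Wald 95% intervals, and CI-overlap concordance.

#' Wald 95% half-width, in percentage points
#'
#' `100 * 1.96 * sqrt(p * (1 - p) / n)`. The Wald form is used throughout:
#' unlike Wilson or Clopper-Pearson it can extend below zero for small
#' proportions, which is the behaviour of the published estimates this
#' package is benchmarked against (e.g. a third-line 1.4% +/- 2.7% cell).
#'
#' @param p Proportion(s) on the 0-1 scale.
#' @param n Denominator(s).
#' @return Half-width(s) in percentage points (unrounded).
#' @export
wald_halfwidth <- function(p, n) {
  stopifnot(all(p >= 0 & p <= 1), all(n > 0))
  100 * 1.96 * sqrt(p * (1 - p) / n)
}

#' Per-line treatment proportions with 95% intervals
#'
#' The denominator is the number of patients with at least `line_number`
#' lines; the numerator counts patients whose line-`line_number` regimen
#' equals the regimen label (set equality via [normalize_regimen()]).
#' Reported proportions and half-widths are rounded to one decimal; the
#' unrounded values are kept alongside.
#'
#' @param lines Line table (`patient_id`, `line_number`, `regimen`).
#' @param line_number Line to tabulate.
#' @param regimens Regimen labels to report (any format accepted by
#'   [normalize_regimen()]); default: the `top_k` most frequent.
#' @param top_k Number of regimens when `regimens` is `NULL`.
#' @param source Source name stamped on each row.
#' @return Tibble: `source`, `line_number`, `regimen`, `numerator`,
#'   `denominator`, `proportion`, `half_width` (both %, 1 decimal),
#'   `proportion_raw`, `half_width_raw`.
#' @export
proportion_table <- function(lines, line_number, regimens = NULL, top_k = 6L,
                             source = "cohort") {
  at_line <- lines[lines$line_number == line_number, , drop = FALSE]
  den <- length(unique(lines$patient_id[lines$line_number >= line_number]))
  if (den == 0L) {
    abort(paste0("no patients with line ", line_number))
  }
  at_line$regimen <- normalize_regimen(at_line$regimen)
  tab <- at_line |>
    count(.data$regimen, name = "numerator") |>
    arrange(desc(.data$numerator), .data$regimen)
  if (is.null(regimens)) {
    tab <- head(tab, top_k)
  } else {
    want <- normalize_regimen(regimens)
    tab <- tibble(regimen = want) |>
      left_join(tab, by = "regimen") |>
      mutate(numerator = ifelse(is.na(.data$numerator), 0L, .data$numerator))
  }
  p <- tab$numerator / den
  tibble(
    source = source,
    line_number = as.integer(line_number),
    regimen = tab$regimen,
    numerator = as.integer(tab$numerator),
    denominator = den,
    proportion = round(100 * p, 1),
    half_width = round(wald_halfwidth(p, den), 1),
    proportion_raw = 100 * p,
    half_width_raw = wald_halfwidth(p, den)
  )
}

#' Do two reported 95% intervals overlap?
#'
#' Overlap is evaluated on the reported (rounded) values as closed
#' intervals: touching endpoints count as overlap.
#'
#' @param p1,h1 First proportion and half-width (percent scale).
#' @param p2,h2 Second proportion and half-width.
#' @return Logical vector.
#' @export
ci_overlap <- function(p1, h1, p2, h2) {
  eps <- 1e-9
  (p1 - h1) <= (p2 + h2) + eps & (p2 - h2) <= (p1 + h1) + eps
}

#' Overlap verdict for two proportion estimates
#'
#' @param est1,est2 Single rows of a [proportion_table()] (same line and
#'   regimen, else an error).
#' @return Logical.
#' @export
overlap_estimates <- function(est1, est2) {
  stopifnot(nrow(est1) == 1L, nrow(est2) == 1L)
  if (est1$line_number != est2$line_number ||
    normalize_regimen(est1$regimen) != normalize_regimen(est2$regimen)) {
    abort("estimates refer to different line/regimen cells")
  }
  ci_overlap(est1$proportion, est1$half_width, est2$proportion, est2$half_width)
}

#' Frequency-match comparator patients to a social-media year distribution
#'
#' For every first-line initiation year, `min(pool_count, ratio * sm_count)`
#' comparator patients are drawn uniformly at random (seeded). Social-media
#' patients whose year has an empty pool are reported as dropped. Matched
#' per-year counts are a function of the counts alone, so they are identical
#' across seeds; only the sampled identities differ.
#'
#' @param sm_years Tibble `year`, `n` (social-media first-line years) or a
#'   named vector.
#' @param pool Tibble of comparator patients: `patient_id`, `database`,
#'   `first_line_year` (one row per patient).
#' @param ratio Matching ratio (default 4).
#' @param seed Integer seed.
#' @return A `matched_cohort`: list with `matched` (selected patients),
#'   `per_year` (database, year, sm_n, pool_n, matched_n), `dropped_sm_years`.
#' @export
frequency_match <- function(sm_years, pool, ratio = 4L, seed = 1L) {
  stopifnot(ratio >= 1L)
  if (!is.data.frame(sm_years)) {
    sm_years <- tibble(year = as.integer(names(sm_years)), n = as.integer(sm_years))
  }
  pool <- distinct(pool, .data$patient_id, .data$database, .data$first_line_year)
  out_matched <- list()
  out_years <- list()
  for (db in sort(unique(pool$database))) {
    pdb <- pool[pool$database == db, , drop = FALSE]
    for (r in seq_len(nrow(sm_years))) {
      yr <- sm_years$year[r]
      smn <- sm_years$n[r]
      ids <- sort(pdb$patient_id[pdb$first_line_year == yr])
      m <- min(length(ids), ratio * smn)
      sel <- if (m > 0L) {
        withr::with_seed(
          derive_seed(seed, paste0("match:", db, ":", yr)),
          sample(ids, m)
        )
      } else {
        character(0)
      }
      out_years[[length(out_years) + 1L]] <- tibble(
        database = db, year = yr, sm_n = smn,
        pool_n = length(ids), matched_n = m
      )
      if (m > 0L) {
        out_matched[[length(out_matched) + 1L]] <- tibble(
          database = db, patient_id = sel, first_line_year = yr
        )
      }
    }
  }
  per_year <- bind_rows(out_years)
  dropped <- per_year |>
    filter(.data$pool_n == 0L, .data$sm_n > 0L) |>
    select("database", "year", "sm_n")
  structure(
    list(
      matched = if (length(out_matched) > 0L) {
        bind_rows(out_matched)
      } else {
        tibble(
          database = character(), patient_id = character(),
          first_line_year = integer()
        )
      },
      per_year = per_year,
      dropped_sm_years = dropped
    ),
    class = "matched_cohort"
  )
}

#' @export
print.matched_cohort <- function(x, ...) {
  tot <- x$per_year |>
    group_by(.data$database) |>
    summarise(matched = sum(.data$matched_n), .groups = "drop")
  cat("<matched_cohort>\n")
  for (i in seq_len(nrow(tot))) {
    cat(" ", tot$database[i], ":", tot$matched[i], "patients\n")
  }
  invisible(x)
}

#' Pairwise overlap grid between a reference source and databases
#'
#' @param estimates Stacked [proportion_table()] rows for several sources
#'   over the same line/regimen cells.
#' @param reference_source Source compared against every other source.
#' @return Long tibble: one row per (line, regimen, database) with both
#'   estimates and the `overlap` flag.
#' @export
compare_sources <- function(estimates, reference_source = "social_media") {
  ref <- estimates |>
    filter(.data$source == reference_source) |>
    select("line_number", "regimen",
      ref_proportion = "proportion", ref_half_width = "half_width"
    )
  db <- estimates |> filter(.data$source != reference_source)
  rows <- db |>
    inner_join(ref, by = c("line_number", "regimen")) |>
    mutate(overlap = ci_overlap(
      .data$ref_proportion, .data$ref_half_width,
      .data$proportion, .data$half_width
    )) |>
    select(
      "line_number", "regimen",
      database = "source", db_proportion = "proportion",
      db_half_width = "half_width", "ref_proportion", "ref_half_width",
      "overlap"
    )
  rows
}

#' Concordance summary over an overlap grid
#'
#' @param rows Output of [compare_sources()].
#' @return List: `rows` (input), `any_overlap` (per line/regimen), `by_line`
#'   (count and fraction of regimens with at least one overlapping
#'   database).
#' @export
concordance_report <- function(rows) {
  if (nrow(rows) == 0L) {
    return(list(
      rows = rows,
      any_overlap = tibble(line_number = integer(), regimen = character(), any_overlap = logical()),
      by_line = tibble(line_number = integer(), n_regimens = integer(), n_any_overlap = integer(), fraction = double())
    ))
  }
  any_tab <- rows |>
    group_by(.data$line_number, .data$regimen) |>
    summarise(any_overlap = any(.data$overlap), .groups = "drop")
  by_line <- any_tab |>
    group_by(.data$line_number) |>
    summarise(
      n_regimens = n(),
      n_any_overlap = sum(.data$any_overlap),
      fraction = sum(.data$any_overlap) / n(),
      .groups = "drop"
    )
  list(rows = rows, any_overlap = any_tab, by_line = by_line)
}
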