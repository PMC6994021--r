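# Published reference estimates from a validation study that compared
# melanoma treatment patterns derived from four US patient forums against
# four EMR/claims databases (Flatiron, McKesson, MarketScan, PharMetrics+).
# Entered as code so the package's statistical conventions (Wald intervals,
# closed-interval overlap on reported values) can be benchmarked against
# printed numbers without shipping any proprietary data.

.ref_sources <- c("flatiron", "mckesson", "marketscan", "pharmetrics", "social_media")

#' Published per-line treatment proportion estimates
#'
#' The six most common regimens per line (lines 1-3) for each of the four
#' EMR/claims databases and the social-media cohort, as printed: proportion
#' and Wald 95% half-width in percent (one decimal), plus the publication's
#' concordance annotation (`concordant`: whether the database cell was
#' marked as overlapping the social-media interval; `NA` for the
#' social-media rows themselves, which are the reference).
#'
#' @return Tibble: `line_number`, `regimen`, `source`, `proportion`,
#'   `half_width`, `concordant`.
#' @seealso [reference_line_denominators()], [reference_year_counts()]
#' @export
reference_estimates <- function() {
  w <- function(line, regimen, source, proportion, half_width, concordant) {
    tibble(
      line_number = line, regimen = regimen, source = source,
      proportion = proportion, half_width = half_width, concordant = concordant
    )
  }
  rows <- list(
    # line 1
    w(1L, "ipilimumab", "flatiron", 24.8, 1.6, FALSE),
    w(1L, "ipilimumab", "mckesson", 45.2, 4.1, TRUE),
    w(1L, "ipilimumab", "marketscan", 16.7, 1.3, FALSE),
    w(1L, "ipilimumab", "pharmetrics", 34.9, 3.4, FALSE),
    w(1L, "ipilimumab", "social_media", 42.2, 3.4, NA),
    w(1L, "pembrolizumab", "flatiron", 13.6, 1.3, TRUE),
    w(1L, "pembrolizumab", "mckesson", 18.8, 3.2, FALSE),
    w(1L, "pembrolizumab", "marketscan", 5.8, 0.8, FALSE),
    w(1L, "pembrolizumab", "pharmetrics", 12.5, 2.4, TRUE),
    w(1L, "pembrolizumab", "social_media", 11.3, 2.2, NA),
    w(1L, "vemurafenib", "flatiron", 10.2, 1.2, TRUE),
    w(1L, "vemurafenib", "mckesson", 1.3, 0.9, FALSE),
    w(1L, "vemurafenib", "marketscan", 5.4, 0.8, FALSE),
    w(1L, "vemurafenib", "pharmetrics", 5.1, 1.6, FALSE),
    w(1L, "vemurafenib", "social_media", 13.3, 2.3, NA),
    w(1L, "dabrafenib+trametinib", "flatiron", 9.7, 1.1, FALSE),
    w(1L, "dabrafenib+trametinib", "mckesson", 2.1, 1.2, FALSE),
    w(1L, "dabrafenib+trametinib", "marketscan", 4.3, 0.7, TRUE),
    w(1L, "dabrafenib+trametinib", "pharmetrics", 6.2, 1.7, TRUE),
    w(1L, "dabrafenib+trametinib", "social_media", 5.5, 1.6, NA),
    w(1L, "ipilimumab+nivolumab", "flatiron", 9.4, 1.1, FALSE),
    w(1L, "ipilimumab+nivolumab", "mckesson", 13.8, 2.9, FALSE),
    w(1L, "ipilimumab+nivolumab", "marketscan", 3.5, 0.6, FALSE),
    w(1L, "ipilimumab+nivolumab", "pharmetrics", 9.7, 2.1, TRUE),
    w(1L, "ipilimumab+nivolumab", "social_media", 6.0, 1.6, NA),
    w(1L, "nivolumab", "flatiron", 8.7, 1.1, FALSE),
    w(1L, "nivolumab", "mckesson", 13.6, 2.8, FALSE),
    w(1L, "nivolumab", "marketscan", 3.1, 0.6, TRUE),
    w(1L, "nivolumab", "pharmetrics", 11.5, 2.3, FALSE),
    w(1L, "nivolumab", "social_media", 4.4, 1.4, NA),
    # line 2
    w(2L, "pembrolizumab", "flatiron", 18.6, 2.5, TRUE),
    w(2L, "pembrolizumab", "mckesson", 35.8, 5.8, FALSE),
    w(2L, "pembrolizumab", "marketscan", 8.1, 1.6, FALSE),
    w(2L, "pembrolizumab", "pharmetrics", 23.9, 4.5, FALSE),
    w(2L, "pembrolizumab", "social_media", 16.4, 4.8, NA),
    w(2L, "dabrafenib+trametinib", "flatiron", 13.7, 2.2, FALSE),
    w(2L, "dabrafenib+trametinib", "mckesson", 1.9, 1.7, FALSE),
    w(2L, "dabrafenib+trametinib", "marketscan", 6.1, 1.4, TRUE),
    w(2L, "dabrafenib+trametinib", "pharmetrics", 9.4, 3.1, TRUE),
    w(2L, "dabrafenib+trametinib", "social_media", 6.6, 3.2, NA),
    w(2L, "ipilimumab", "flatiron", 13.7, 2.2, FALSE),
    w(2L, "ipilimumab", "mckesson", 6.9, 3.1, FALSE),
    w(2L, "ipilimumab", "marketscan", 9.1, 1.7, FALSE),
    w(2L, "ipilimumab", "pharmetrics", 15.0, 3.8, TRUE),
    w(2L, "ipilimumab", "social_media", 24.3, 5.6, NA),
    w(2L, "nivolumab", "flatiron", 11.2, 2.0, TRUE),
    w(2L, "nivolumab", "mckesson", 34.6, 5.8, FALSE),
    w(2L, "nivolumab", "marketscan", 4.8, 1.3, FALSE),
    w(2L, "nivolumab", "pharmetrics", 12.7, 3.5, TRUE),
    w(2L, "nivolumab", "social_media", 11.5, 4.2, NA),
    w(2L, "ipilimumab+nivolumab", "flatiron", 5.8, 1.5, FALSE),
    w(2L, "ipilimumab+nivolumab", "mckesson", 10.0, 3.6, TRUE),
    w(2L, "ipilimumab+nivolumab", "marketscan", 3.2, 1.0, FALSE),
    w(2L, "ipilimumab+nivolumab", "pharmetrics", 3.8, 2.0, FALSE),
    w(2L, "ipilimumab+nivolumab", "social_media", 8.4, 3.6, NA),
    w(2L, "temozolomide", "flatiron", 5.3, 1.4, TRUE),
    w(2L, "temozolomide", "mckesson", 0.8, 1.1, FALSE),
    w(2L, "temozolomide", "marketscan", 4.6, 1.2, TRUE),
    w(2L, "temozolomide", "pharmetrics", 4.4, 2.2, TRUE),
    w(2L, "temozolomide", "social_media", 3.5, 2.4, NA),
    # line 3
    w(3L, "pembrolizumab", "flatiron", 15.3, 3.9, FALSE),
    w(3L, "pembrolizumab", "mckesson", 22.7, 10.1, FALSE),
    w(3L, "pembrolizumab", "marketscan", 4.1, 1.7, TRUE),
    w(3L, "pembrolizumab", "pharmetrics", 18.2, 6.1, FALSE),
    w(3L, "pembrolizumab", "social_media", 4.1, 4.6, NA),
    w(3L, "dabrafenib+trametinib", "flatiron", 12.9, 3.6, TRUE),
    w(3L, "dabrafenib+trametinib", "mckesson", 0.0, 0.0, FALSE),
    w(3L, "dabrafenib+trametinib", "marketscan", 7.0, 2.2, TRUE),
    w(3L, "dabrafenib+trametinib", "pharmetrics", 13.0, 5.3, TRUE),
    w(3L, "dabrafenib+trametinib", "social_media", 9.6, 6.8, NA),
    w(3L, "nivolumab", "flatiron", 12.0, 3.5, TRUE),
    w(3L, "nivolumab", "mckesson", 22.7, 10.1, TRUE),
    w(3L, "nivolumab", "marketscan", 5.3, 1.9, FALSE),
    w(3L, "nivolumab", "pharmetrics", 16.9, 5.9, TRUE),
    w(3L, "nivolumab", "social_media", 19.2, 9.0, NA),
    w(3L, "ipilimumab", "flatiron", 9.2, 3.1, TRUE),
    w(3L, "ipilimumab", "mckesson", 9.1, 6.9, TRUE),
    w(3L, "ipilimumab", "marketscan", 7.0, 2.2, FALSE),
    w(3L, "ipilimumab", "pharmetrics", 10.4, 4.8, TRUE),
    w(3L, "ipilimumab", "social_media", 16.4, 8.5, NA),
    w(3L, "ipilimumab+nivolumab", "flatiron", 8.9, 3.1, TRUE),
    w(3L, "ipilimumab+nivolumab", "mckesson", 18.2, 9.3, TRUE),
    w(3L, "ipilimumab+nivolumab", "marketscan", 2.5, 1.4, FALSE),
    w(3L, "ipilimumab+nivolumab", "pharmetrics", 2.6, 2.5, FALSE),
    w(3L, "ipilimumab+nivolumab", "social_media", 12.3, 7.5, NA),
    w(3L, "temozolomide", "flatiron", 4.9, 2.3, TRUE),
    w(3L, "temozolomide", "mckesson", 0.0, 0.0, FALSE),
    w(3L, "temozolomide", "marketscan", 3.3, 1.5, TRUE),
    w(3L, "temozolomide", "pharmetrics", 5.2, 3.5, FALSE),
    w(3L, "temozolomide", "social_media", 1.4, 2.7, NA)
  )
  bind_rows(rows)
}

#' Published per-line patient counts (line denominators)
#'
#' Number of patients contributing data at first, second and third line in
#' each source, with the printed retention percentages.
#'
#' @return Tibble: `source`, `line_number`, `n`, `pct`.
#' @export
reference_line_denominators <- function() {
  tibble(
    source = rep(.ref_sources, each = 3L),
    line_number = rep(1:3, times = 5L),
    n = c(
      2666L, 930L, 326L,
      560L, 260L, 66L,
      3268L, 1108L, 514L,
      739L, 339L, 154L,
      817L, 226L, 73L
    ),
    pct = c(
      100.0, 34.9, 12.2,
      100.0, 46.4, 11.8,
      100.0, 33.9, 15.7,
      100.0, 45.9, 20.8,
      100.0, 27.7, 8.9
    )
  )
}

#' Published first-line initiation-year distributions
#'
#' Patients per year of first-line treatment initiation (2011-2017) in each
#' source, after 4:1 frequency matching of the databases to the social-media
#' cohort.
#'
#' @return Tibble: `source`, `year`, `n`.
#' @export
reference_year_counts <- function() {
  years <- 2011:2017
  tibble(
    source = rep(.ref_sources, each = length(years)),
    year = rep(years, times = 5L),
    n = c(
      104L, 233L, 366L, 519L, 508L, 508L, 428L,
      10L, 24L, 35L, 130L, 127L, 127L, 107L,
      160L, 384L, 560L, 720L, 508L, 508L, 428L,
      28L, 44L, 126L, 180L, 127L, 127L, 107L,
      40L, 96L, 140L, 180L, 127L, 127L, 107L
    )
  )
}
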