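test_that("Wald half-widths match closed-form hand computations", {
  expect_equal(round(wald_halfwidth(0.5, 100), 1), 9.8)
  expect_equal(round(wald_halfwidth(0.422, 817), 1), 3.4)
  expect_equal(wald_halfwidth(0, 500), 0)
  expect_equal(wald_halfwidth(1, 500), 0)
  expect_error(wald_halfwidth(1.2, 100))
})

test_that("proportion tables use line denominators and regimen-set equality", {
  lines <- dplyr::bind_rows(
    tibble::tibble(
      patient_id = sprintf("p%02d", 1:10), line_number = 1L,
      regimen = c(rep("ipilimumab", 4), rep("nivolumab+ipilimumab", 3), rep("vemurafenib", 3)),
      start_date = as.Date("2015-03-15")
    ),
    tibble::tibble(
      patient_id = sprintf("p%02d", 1:4), line_number = 2L,
      regimen = "pembrolizumab", start_date = as.Date("2016-01-15")
    )
  )
  pt <- proportion_table(lines, 1L, top_k = 2L, source = "sm")
  expect_equal(pt$denominator, c(10L, 10L))
  expect_equal(pt$regimen[1], "ipilimumab")
  expect_equal(pt$proportion[1], 40.0)
  expect_equal(pt$half_width[1], round(100 * 1.96 * sqrt(0.4 * 0.6 / 10), 1))
  # label order inside a combination is irrelevant
  pt2 <- proportion_table(lines, 1L, regimens = "Ipilimumab and Nivolumab", source = "sm")
  expect_equal(pt2$numerator, 3L)
  # unseen regimen reports a zero numerator
  pt3 <- proportion_table(lines, 1L, regimens = "dacarbazine", source = "sm")
  expect_equal(pt3$numerator, 0L)
  expect_equal(pt3$half_width, 0)
  expect_error(proportion_table(lines, 3L), "no patients")
})

test_that("interval overlap is closed on reported values", {
  expect_true(ci_overlap(42.2, 3.4, 45.2, 4.1))
  expect_false(ci_overlap(42.2, 3.4, 24.8, 1.6))
  # endpoints touching at 7.6 count as overlap
  expect_true(ci_overlap(6.0, 1.6, 9.7, 2.1))
  est1 <- tibble::tibble(
    source = "sm", line_number = 1L, regimen = "ipilimumab",
    proportion = 42.2, half_width = 3.4
  )
  est2 <- est1
  est2$source <- "mckesson"
  est2$proportion <- 45.2
  est2$half_width <- 4.1
  expect_true(overlap_estimates(est1, est2))
  est3 <- est2
  est3$regimen <- "nivolumab"
  expect_error(overlap_estimates(est1, est3), "different")
})

test_that("frequency matching caps at ratio x count and at the pool", {
  pool <- tibble::tibble(
    patient_id = c(sprintf("a%04d", 1:600), sprintf("b%04d", 1:104)),
    database = rep(c("dbA", "dbB"), c(600, 104)),
    first_line_year = c(rep(2013L, 600), rep(2011L, 104))
  )
  sm <- tibble::tibble(year = c(2011L, 2013L, 2017L), n = c(40L, 140L, 10L))
  mc <- frequency_match(sm, pool, ratio = 4L, seed = 1L)
  per <- mc$per_year
  expect_equal(per$matched_n[per$database == "dbA" & per$year == 2013], 560L)
  expect_equal(per$matched_n[per$database == "dbB" & per$year == 2011], 104L)
  # empty pool for a requested year -> those patients are reported dropped
  expect_true(all(c(2017L) %in% mc$dropped_sm_years$year))
  expect_equal(nrow(mc$matched), 560L + 104L)
})

test_that("matching is seed-reproducible and counts are seed-invariant", {
  pool <- tibble::tibble(
    patient_id = sprintf("x%04d", 1:500), database = "dbA",
    first_line_year = rep(2011:2015, each = 100)
  )
  sm <- tibble::tibble(year = 2011:2015, n = c(10L, 20L, 30L, 40L, 50L))
  m1 <- frequency_match(sm, pool, seed = 7L)
  m2 <- frequency_match(sm, pool, seed = 7L)
  m3 <- frequency_match(sm, pool, seed = 8L)
  expect_identical(m1$matched, m2$matched)
  expect_identical(m1$per_year, m3$per_year)
  expect_false(identical(m1$matched$patient_id, m3$matched$patient_id))
})

test_that("concordance summarises any-overlap per line", {
  est <- dplyr::bind_rows(
    tibble::tibble(
      source = "social_media", line_number = 1L,
      regimen = c("ipilimumab", "nivolumab"),
      proportion = c(40, 10), half_width = c(3, 2)
    ),
    tibble::tibble(
      source = "dbA", line_number = 1L,
      regimen = c("ipilimumab", "nivolumab"),
      proportion = c(44, 30), half_width = c(2, 3)
    ),
    tibble::tibble(
      source = "dbB", line_number = 1L,
      regimen = c("ipilimumab", "nivolumab"),
      proportion = c(50, 13), half_width = c(2, 2)
    )
  )
  rows <- compare_sources(est)
  rep <- concordance_report(rows)
  ao <- rep$any_overlap
  expect_true(ao$any_overlap[ao$regimen == "ipilimumab"]) # via dbA
  expect_true(ao$any_overlap[ao$regimen == "nivolumab"]) # via dbB
  expect_equal(rep$by_line$fraction, 1)
  # all-identical estimates overlap everywhere
  est2 <- est
  est2$proportion <- 20
  est2$half_width <- 1
  expect_true(all(compare_sources(est2)$overlap))
  # single-source input: no database rows, empty summary
  solo <- est[est$source == "social_media", ]
  rep2 <- concordance_report(compare_sources(solo))
  expect_equal(nrow(rep2$any_overlap), 0L)
})
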