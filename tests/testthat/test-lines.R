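test_that("timelines dedup at (drug, month) and break date ties alphabetically", {
  r <- resolved_rows("u1", rep("ipilimumab", 3),
    c("2014-03-02", "2014-03-15", "2014-03-28")
  )
  tl <- build_timeline(r)
  expect_equal(nrow(tl), 1L)
  expect_equal(tl$event_date, as.Date("2014-03-02"))
  r2 <- resolved_rows("u1", c("nivolumab", "ipilimumab"), rep("2014-03-10", 2))
  tl2 <- build_timeline(r2)
  expect_equal(tl2$drug, c("ipilimumab", "nivolumab"))
  expect_equal(nrow(build_timeline(r[0, ])), 0L)
  expect_error(
    build_timeline(dplyr::bind_rows(r, resolved_row("u2", "nivolumab", "2014-04-01"))),
    "single user"
  )
})

test_that("line assignment follows the combination and adjuvant rules", {
  lex <- default_lexicon()
  # adjuvant monotherapy is never a line
  only_ifn <- build_timeline(resolved_row("u1", "interferon", "2013-01-15"))
  expect_equal(nrow(assign_lines(only_ifn, lexicon = lex)), 0L)
  # same-day combination shares one line
  combo <- build_timeline(resolved_rows("u1",
    c("ipilimumab", "nivolumab"), rep("2014-03-15", 2)
  ))
  al <- assign_lines(combo, lexicon = lex)
  expect_equal(al$line_number, 1L)
  expect_equal(al$regimen, "ipilimumab+nivolumab")
  # hand-applied rules 1-3 with the 28-day window
  tl <- build_timeline(resolved_rows("u1",
    c("ipilimumab", "dabrafenib", "trametinib"),
    c("2014-03-15", "2014-09-15", "2014-09-15")
  ))
  al2 <- assign_lines(tl, lexicon = lex)
  expect_equal(al2$regimen, c("ipilimumab", "dabrafenib+trametinib"))
  expect_equal(al2$line_number, 1:2)
  expect_equal(al2$start_date, as.Date(c("2014-03-15", "2014-09-15")))
  # re-mentions never advance lines; a new drug after the window does
  tl3 <- build_timeline(resolved_rows("u1",
    c("ipilimumab", "ipilimumab", "pembrolizumab"),
    c("2014-03-15", "2014-07-15", "2015-01-15")
  ))
  al3 <- assign_lines(tl3, lexicon = lex)
  expect_equal(al3$regimen, c("ipilimumab", "pembrolizumab"))
  # adjuvant inside a multi-drug window joins the combination (rule 6)
  tl4 <- build_timeline(resolved_rows("u1",
    c("pembrolizumab", "docetaxel"), c("2015-02-15", "2015-03-01")
  ))
  al4 <- assign_lines(tl4, lexicon = lex)
  expect_equal(al4$regimen, "docetaxel+pembrolizumab")
  # an adjuvant event outside every window is skipped entirely (rule 5)
  tl5 <- build_timeline(resolved_rows("u1",
    c("interferon", "ipilimumab"), c("2013-01-15", "2014-03-15")
  ))
  al5 <- assign_lines(tl5, lexicon = lex)
  expect_equal(al5$regimen, "ipilimumab")
})

test_that("assigned lines are invariant to input mention order", {
  drugs <- c("ipilimumab", "nivolumab", "pembrolizumab", "dabrafenib", "trametinib")
  dates <- c("2015-01-15", "2015-01-20", "2015-08-15", "2016-02-15", "2016-02-20")
  base <- resolved_rows("u1", drugs, dates)
  ref <- assign_lines(build_timeline(base))
  withr::with_seed(1, {
    for (k in 1:5) {
      perm <- base[sample(nrow(base)), ]
      expect_equal(assign_lines(build_timeline(perm)), ref)
    }
  })
})

test_that("adding a later new drug never decreases the number of lines", {
  base <- resolved_rows("u1", c("ipilimumab", "pembrolizumab"),
    c("2014-03-15", "2014-11-15")
  )
  n0 <- nrow(assign_lines(build_timeline(base)))
  more <- dplyr::bind_rows(base, resolved_row("u1", "nivolumab", "2015-06-15"))
  n1 <- nrow(assign_lines(build_timeline(more)))
  expect_gte(n1, n0)
  expect_equal(n1, n0 + 1L)
})

test_that("derive_lines matches per-user assign_lines and line_counts round correctly", {
  r <- dplyr::bind_rows(
    resolved_rows("u1", c("ipilimumab", "pembrolizumab"), c("2014-03-15", "2014-11-15")),
    resolved_rows("u2", "vemurafenib", "2013-05-15"),
    resolved_rows("u3", c("dabrafenib", "trametinib"), rep("2016-01-15", 2))
  )
  all_lines <- derive_lines(r)
  per_user <- dplyr::bind_rows(lapply(split(r, r$user_id), function(x) {
    assign_lines(build_timeline(x))
  }))
  expect_equal(
    dplyr::arrange(all_lines, patient_id, line_number),
    dplyr::arrange(per_user, patient_id, line_number)
  )
  lc <- line_counts(all_lines)
  expect_equal(lc$n_patients, c(3L, 1L, 0L))
  expect_equal(lc$pct, c(100.0, 33.3, 0.0))
  lc0 <- line_counts(all_lines[0, ])
  expect_equal(lc0$n_patients, c(0L, 0L, 0L))
  expect_true(all(is.na(lc0$pct)))
})

test_that("line retention percentages follow the one-decimal reporting convention", {
  # cohort shaped like the published social-media retention: 817/226/73
  lines <- dplyr::bind_rows(
    tibble::tibble(
      patient_id = sprintf("p%03d", 1:817), line_number = 1L,
      regimen = "ipilimumab", start_date = as.Date("2014-06-15")
    ),
    tibble::tibble(
      patient_id = sprintf("p%03d", 1:226), line_number = 2L,
      regimen = "pembrolizumab", start_date = as.Date("2015-06-15")
    ),
    tibble::tibble(
      patient_id = sprintf("p%03d", 1:73), line_number = 3L,
      regimen = "nivolumab", start_date = as.Date("2016-06-15")
    )
  )
  lc <- line_counts(lines)
  expect_equal(lc$n_patients, c(817L, 226L, 73L))
  expect_equal(lc$pct, c(100.0, 27.7, 8.9))
})
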