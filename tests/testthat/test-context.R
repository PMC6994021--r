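test_that("negation cues fire inside the 5-token window with terminator scope", {
  # mention positions computed by hand on the lowercased sentence
  expect_true(detect_negation("I did not take temozolomide", 16))
  expect_false(detect_negation("I took ipilimumab", 8))
  # "no" six tokens back, and "but" terminates its scope anyway
  s <- "They said no to surgery but I started nivolumab"
  expect_false(detect_negation(s, regexpr("nivolumab", s)))
  expect_true(detect_negation("my doctor said no to pembrolizumab", 22))
  expect_true(detect_negation("I never started dabrafenib", 17))
  # cue further than 5 tokens before the mention is out of scope
  far <- "not that it matters one bit honestly ipilimumab helped"
  expect_false(detect_negation(far, regexpr("ipilimumab", far)))
})

test_that("temporal resolution handles absolute, relative and default forms", {
  r <- resolve_time("I received temozolomide three months ago", as.Date("2015-06-20"))
  expect_equal(r$event_date, as.Date("2015-03-20"))
  expect_equal(r$resolution_rule, "relative_offset")
  r2 <- resolve_time("started ipi in March 2014", as.Date("2016-01-01"))
  expect_equal(r2$event_date, as.Date("2014-03-15"))
  expect_equal(r2$resolution_rule, "explicit_date")
  r3 <- resolve_time("I am on nivo", as.Date("2016-02-01"))
  expect_equal(r3$event_date, as.Date("2016-02-01"))
  expect_equal(r3$resolution_rule, "post_date_default")
  expect_equal(
    resolve_time("began pembro 3/2014 at the clinic", as.Date("2016-01-01"))$event_date,
    as.Date("2014-03-15")
  )
  expect_equal(
    resolve_time("got it 2 weeks ago", as.Date("2016-02-15"))$event_date,
    as.Date("2016-02-01")
  )
  expect_equal(
    resolve_time("started last month", as.Date("2016-03-31"))$event_date,
    as.Date("2016-02-29")
  )
  expect_equal(
    resolve_time("I will start pembro next month", as.Date("2016-01-10"))$event_date,
    as.Date("2016-02-10")
  )
})

test_that("resolve_time is total over arbitrary generated sentences", {
  cfg <- sim_config(n_patients = 40, noise = 0.3, seed = 9)
  rendered <- render_posts(generate_truth(cfg), cfg)
  recs <- tokenize_posts(rendered$posts)
  post <- as.Date("2016-06-10")
  for (i in seq_len(nrow(recs))) {
    r <- resolve_time(recs$text[i], post)
    expect_s3_class(r$event_date, "Date")
    expect_false(is.na(r$event_date))
    expect_true(r$resolution_rule %in%
      c("explicit_date", "relative_offset", "post_date_default"))
  }
})

test_that("resolve_mentions applies the conjunctive gates and errors on missing verdicts", {
  posts <- tibble::tibble(
    username = "u", forum = "f",
    post_date = as.Date(c("2015-04-01", "2015-04-02", "2015-04-03", "2015-04-04")),
    text = c(
      "I started ipilimumab in March 2015.", # receipt, affirmative
      "I did not take temozolomide.", # receipt verdict but negated
      "My mom started nivolumab last month.", # classifier says non_receipt
      "I will start pembrolizumab in two months." # future-dated intent
    )
  )
  recs <- tokenize_posts(posts)
  mentions <- mentions_table(recs)
  verdicts <- dplyr::distinct(mentions, user_id, post_id, sentence_index)
  verdicts$label <- c("receipt", "receipt", "non_receipt", "receipt")
  out <- resolve_mentions(mentions, recs, verdicts)
  expect_equal(out$canonical, "ipilimumab")
  expect_equal(out$event_date, as.Date("2015-03-15"))
  expect_equal(out$resolution_rule, "explicit_date")
  expect_error(
    resolve_mentions(mentions, recs, verdicts[-1, ]),
    "missing classifier verdict"
  )
})

test_that("filter order does not matter: gates are conjunctive", {
  posts <- tibble::tibble(
    username = "u", forum = "f",
    post_date = as.Date("2015-04-01") + 0:2,
    text = c(
      "I started ipilimumab in March 2015.",
      "I never got dacarbazine.",
      "Started vemurafenib infusions last month."
    )
  )
  recs <- tokenize_posts(posts)
  mentions <- mentions_table(recs)
  verdicts <- dplyr::distinct(mentions, user_id, post_id, sentence_index)
  verdicts$label <- "receipt"
  keep_all <- resolve_mentions(mentions, recs, verdicts)
  # applying the negation gate on a pre-filtered mention set gives the same rows
  not_negated <- mentions[!vapply(seq_len(nrow(mentions)), function(i) {
    s <- recs$text[recs$post_id == mentions$post_id[i] & recs$user_id == mentions$user_id[i]]
    detect_negation(s[mentions$sentence_index[i] + 1L], mentions$start[i])
  }, logical(1)), ]
  pre <- resolve_mentions(not_negated, recs, verdicts)
  expect_equal(as.data.frame(keep_all), as.data.frame(pre))
  expect_setequal(keep_all$canonical, c("ipilimumab", "vemurafenib"))
})
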