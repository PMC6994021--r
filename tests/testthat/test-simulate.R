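test_that("degenerate probabilities give degenerate journeys", {
  cfg <- sim_config(n_patients = 25, p_second_line = 0, p_third_line = 0, seed = 1)
  tr <- generate_truth(cfg)
  expect_equal(nrow(tr), 25L)
  expect_true(all(tr$line_number == 1L))
  # point mass on one regimen/year
  rd <- tibble::tibble(
    year = rep(2014L, 3), line = 1:3, regimen = "ipilimumab", weight = 1
  )
  cfg2 <- sim_config(
    n_patients = 10, years = 2014L, year_weights = 1,
    p_second_line = 0, regimen_distribution = rd, seed = 2
  )
  tr2 <- generate_truth(cfg2)
  expect_equal(nrow(tr2), 10L)
  expect_true(all(tr2$regimen == "ipilimumab"))
  expect_true(all(format(tr2$start_date, "%Y") == "2014"))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(p_second_line = 1.2), "configuration error")
  expect_error(sim_config(year_weights = c(0.5, 0.5)), "configuration error")
  bad_rd <- tibble::tibble(year = 2014L, line = 1L, regimen = "a", weight = 0.7)
  expect_error(sim_config(regimen_distribution = bad_rd), "configuration error")
  expect_error(
    sim_config(comparator_pools = list(dbA = c(`2014` = -1))),
    "configuration error"
  )
})

test_that("empirical first-line year shares converge to the configured weights", {
  cfg <- sim_config(n_patients = 10000, seed = 123)
  tr <- generate_truth(cfg)
  shares <- tr |>
    dplyr::filter(line_number == 1L) |>
    dplyr::count(year = as.integer(format(start_date, "%Y"))) |>
    dplyr::mutate(share = 100 * n / sum(n))
  published <- c(4.9, 11.8, 17.1, 22.0, 15.5, 15.5, 13.1)
  expect_equal(shares$year, 2011:2017)
  expect_true(all(abs(shares$share - published) < 2))
  # retention probabilities at their defaults
  lc <- line_counts(dplyr::select(tr, patient_id, line_number))
  expect_lt(abs(lc$pct[2] - 27.7), 2)
})

test_that("zero-noise rendering yields affirmative posts that resolve to the line month", {
  cfg <- sim_config(n_patients = 1, noise = 0, p_second_line = 0, seed = 5)
  tr <- generate_truth(cfg)
  rendered <- render_posts(tr, cfg)
  recs <- tokenize_posts(rendered$posts)
  mentions <- mentions_table(recs)
  expect_gte(nrow(mentions), 1L)
  hit <- dplyr::inner_join(
    mentions,
    dplyr::select(recs, user_id, post_id, sentence_index, text),
    by = c("user_id", "post_id", "sentence_index")
  )
  drugs <- strsplit(tr$regimen[1], "+", fixed = TRUE)[[1]]
  expect_true(all(drugs %in% hit$canonical))
  months <- vapply(seq_len(nrow(hit)), function(i) {
    format(resolve_time(hit$text[i], hit$post_date[i])$event_date, "%Y-%m")
  }, character(1))
  expect_true(all(months == format(tr$start_date[1], "%Y-%m")))
  expect_false(any(vapply(seq_len(nrow(hit)), function(i) {
    detect_negation(hit$text[i], hit$start[i])
  }, logical(1))))
})

test_that("negation-only decoys all match the negation cue grammar", {
  cfg <- sim_config(n_patients = 30, noise = 0, negation_rate = 1, seed = 6)
  tr <- generate_truth(cfg)
  rendered <- render_posts(tr, cfg)
  decoy_sentences <- rendered$labels[rendered$labels$label == "non_receipt", ]
  decoy_sentences <- decoy_sentences[
    vapply(decoy_sentences$sentence, function(s) {
      nrow(find_mentions(s)) > 0
    }, logical(1)),
  ]
  expect_gte(nrow(decoy_sentences), 30L * 0.9)
  for (s in decoy_sentences$sentence) {
    m <- find_mentions(s)
    expect_true(detect_negation(s, m$start[1]), info = s)
  }
})

test_that("typo rate 1 keeps every drug surface detectable at one edit", {
  cfg <- sim_config(n_patients = 25, noise = 0, typo_rate = 1, seed = 7)
  tr <- generate_truth(cfg)
  rendered <- render_posts(tr, cfg)
  lex <- default_lexicon()
  truth_drugs <- sort(unique(unlist(strsplit(tr$regimen, "+", fixed = TRUE))))
  receipt <- rendered$labels[rendered$labels$label == "receipt", ]
  found <- character(0)
  all_d <- integer(0)
  for (s in receipt$sentence) {
    m <- find_mentions(s, lex)
    expect_gte(nrow(m), 1L) # 100% recall on a one-edit corpus
    found <- c(found, m$canonical)
    # each emitted surface is exactly one edit from a surface of its drug
    for (i in seq_len(nrow(m))) {
      forms <- lex$surfaces$variant[lex$surfaces$canonical == m$canonical[i]]
      all_d <- c(all_d, min(utils::adist(m$surface[i], forms)))
    }
  }
  expect_true(all(all_d == 1L))
  expect_true(all(truth_drugs %in% found))
})

test_that("comparator tables honour the configured pools and are byte-reproducible", {
  pools <- list(dbA = c(`2014` = 0), dbB = c(`2014` = 25, `2016` = 5))
  cfg <- sim_config(n_patients = 5, comparator_pools = pools, seed = 11)
  cmp <- render_comparators(cfg)
  expect_false("dbA" %in% cmp$database)
  b14 <- cmp[cmp$database == "dbB" & cmp$first_line_year == 2014, ]
  expect_equal(length(unique(b14$patient_id)), 25L)
  expect_true(all(format(b14$start_date[b14$line_number == 1], "%Y") == "2014"))
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  readr::write_csv(render_comparators(cfg), f1)
  readr::write_csv(render_comparators(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
})

test_that("generation is fully reproducible under a fixed seed", {
  cfg <- sim_config(n_patients = 40, seed = 99)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1, t2)
  r1 <- render_posts(t1, cfg)
  r2 <- render_posts(t2, cfg)
  expect_identical(r1, r2)
})

test_that("truth journeys never use adjuvant monotherapy as a line", {
  cfg <- sim_config(n_patients = 300, seed = 17)
  tr <- generate_truth(cfg)
  expect_false(any(tr$regimen %in% c("interferon", "docetaxel")))
  # line numbers consecutive from 1, dates strictly increasing
  per <- split(tr, tr$patient_id)
  expect_true(all(vapply(per, function(j) {
    identical(j$line_number, seq_len(nrow(j))) && !is.unsorted(j$start_date, strictly = TRUE)
  }, logical(1))))
})
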