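# Synthetic cohort generator: ground-truth patient journeys rendered as
# (a) noisy forum posts with sentence-level labels and (b) comparator
# cohort tables, so every downstream stage has labeled inputs.

.forums <- c(
  "melanoma.org", "melanoma-international", "cancer-compass",
  "cancer-survival-network"
)
# forum shares roughly proportional to the reported per-forum post volumes
.forum_weights <- c(0.80, 0.18, 0.014, 0.006)

# Fixed, versioned sentence material. Sentences are composed from shared
# slots (subject, receipt verb, drug, temporal phrase) so the classes share
# most of their vocabulary and differ in short cue words (first- vs
# third-person subjects, negators, future markers), as real forum language
# does: "I started X last month" (receipt) vs "My mom started X last month"
# (hearsay) vs "I will start X next month" (intent).
.slots <- list(
  verbs_past = c("started", "began", "received", "got", "tried", "went on"),
  subjects_third = c(
    "My mom", "My friend", "My neighbor", "My sister",
    "A friend from group", "Someone from my support group"
  ),
  receipt_suffix = c(
    "", "", "", " and so far so good", " at the cancer center",
    " after my last scan"
  ),
  # circumstantial clauses drawn by every sentence type: shared vocabulary
  # across classes, free of drug names, negators and temporal expressions
  clauses = c(
    "after talking it over with my family",
    "since the trial slot opened",
    "once the insurance cleared",
    "right before the holidays",
    "while we were still at the old clinic",
    "per the tumor board recommendation",
    "at the university hospital",
    "alongside the usual blood work",
    "after a long chat with the nurse",
    "despite the travel involved",
    "with the second opinion in hand",
    "following the biopsy results",
    "after the port was placed",
    "around the time of my birthday",
    "when the swelling finally went down",
    "as part of the new plan",
    "with high hopes on our end",
    "after so many scans and so much waiting",
    "once the paperwork went through",
    "at the clinic downtown",
    "during a really stressful stretch",
    "after we moved closer to the center",
    "on the advice of the specialist",
    "with the whole family on board",
    "just as the weather turned",
    "after my labs came back fine",
    "while juggling work and appointments",
    "because the first plan stalled",
    "with some hesitation on my part",
    "after reading everything I could find",
    "once my counts recovered",
    "at the same infusion center as before",
    "following a rough few weeks",
    "when my energy finally returned",
    "with my daughter driving me in",
    "after the insurance appeal"
  )
)

# append a circumstantial clause with fixed probability; all sentence types
# share the same clause pool
maybe_clause <- function(s, p = 0.75) {
  if (stats::runif(1) >= p) {
    return(s)
  }
  clause <- paste(sample(.slots$clauses, sample(1:2, 1L)), collapse = " ")
  sub("([.?])$", paste0(" ", clause, "\\1"), s)
}

.templates <- list(
  receipt_fixed = c(
    "My oncologist put me on {drug} {when}.",
    "First dose of {drug} was {when}.",
    "Started {drug} infusions {when}."
  ),
  receipt_nowhen = c(
    "I just had my first dose of {drug}.",
    "Today I started {drug}.",
    "They started me on {drug} this week."
  ),
  negation = c(
    "I did not take {drug}.",
    "I never started {drug}.",
    "I did not get {drug} {when}.",
    "My doctor said no to {drug}.",
    "We decided not to start {drug}.",
    "I refused {drug} because of the side effects.",
    "Insurance denied {drug} for me."
  ),
  intent = c(
    "I will start {drug} next month.",
    "I am starting {drug} next month.",
    "We are scheduled to begin {drug} in two weeks.",
    "My onc wants me on {drug} next month.",
    "Thinking hard about {drug} as the next step."
  ),
  hearsay_fixed = c(
    "Anyone here tried {drug}?",
    "What are the side effects of {drug}?",
    "My neighbor was on {drug} for a year.",
    "Someone posted that {drug} worked for them."
  ),
  adjuvant = c(
    "I was on {drug} after my surgery.",
    "Did a year of {drug} as adjuvant therapy."
  ),
  filler = c(
    "Fingers crossed for everyone here.",
    "Side effects have been manageable so far.",
    "Feeling hopeful about this one.",
    "Thanks for all the support on this board.",
    "Trying to stay positive."
  ),
  offtopic = c(
    "My last scan came back stable.",
    "Anyone else dealing with fatigue lately?",
    "I was diagnosed in {month} {year}.",
    "Sending good thoughts to everyone today.",
    "The waiting between scans is the hardest part.",
    "My insurance paperwork finally went through, check http://example.com/forms for the forms."
  )
)

squeeze <- function(x) trimws(gsub("\\s+", " ", x))

compose_receipt <- function(drug_text, when) {
  if (is.na(when)) {
    return(fill_template(sample(.templates$receipt_nowhen, 1L), drug_text))
  }
  if (stats::runif(1) < 0.35) {
    return(fill_template(sample(.templates$receipt_fixed, 1L), drug_text, when))
  }
  subj <- sample(c("I", "I", "I", "We"), 1L)
  verb <- sample(.slots$verbs_past, 1L)
  suffix <- sample(.slots$receipt_suffix, 1L)
  squeeze(paste0(subj, " ", verb, " ", drug_text, " ", when, suffix, "."))
}

compose_hearsay <- function(drug_text, when) {
  if (stats::runif(1) < 0.25) {
    return(fill_template(sample(.templates$hearsay_fixed, 1L), drug_text))
  }
  subj <- sample(.slots$subjects_third, 1L)
  verb <- sample(.slots$verbs_past, 1L)
  squeeze(paste0(subj, " ", verb, " ", drug_text, " ",
    if (is.na(when)) "recently" else when, "."))
}

.month_titles <- c(
  "January", "February", "March", "April", "May", "June", "July",
  "August", "September", "October", "November", "December"
)

#' Default year/line regimen distribution
#'
#' Per-year, per-line categorical weights over regimen labels, reflecting
#' the era structure of advanced-melanoma treatment in 2011-2017:
#' chemotherapy/ipilimumab/vemurafenib before 2014, PD-1 inhibitors from
#' 2014, and combination immunotherapy plus BRAF/MEK doublets from 2015.
#' Weights sum to one within each (year, line) cell.
#'
#' @return Tibble: `year`, `line`, `regimen`, `weight`.
#' @export
default_regimen_distribution <- function() {
  cell <- function(years, line, regimens, weights) {
    stopifnot(abs(sum(weights) - 1) < 1e-9)
    tidyr::expand_grid(year = years, line = line, tibble(regimen = regimens, weight = weights))
  }
  bind_rows(
    cell(2011:2013, 1L,
      c("ipilimumab", "vemurafenib", "temozolomide", "dacarbazine", "interleukin-2"),
      c(0.40, 0.20, 0.15, 0.15, 0.10)
    ),
    cell(2014L, 1L,
      c("ipilimumab", "pembrolizumab", "nivolumab", "vemurafenib",
        "dabrafenib+trametinib", "temozolomide", "dacarbazine"),
      c(0.35, 0.15, 0.10, 0.15, 0.10, 0.10, 0.05)
    ),
    cell(2015:2017, 1L,
      c("ipilimumab", "pembrolizumab", "nivolumab", "ipilimumab+nivolumab",
        "dabrafenib+trametinib", "vemurafenib", "temozolomide"),
      c(0.20, 0.20, 0.15, 0.15, 0.15, 0.10, 0.05)
    ),
    cell(2011:2013, 2:3,
      c("vemurafenib", "temozolomide", "dacarbazine", "interleukin-2",
        "carboplatin+paclitaxel"),
      c(0.25, 0.25, 0.20, 0.15, 0.15)
    ),
    cell(2014L, 2:3,
      c("pembrolizumab", "nivolumab", "ipilimumab", "dabrafenib+trametinib",
        "temozolomide", "vemurafenib"),
      c(0.25, 0.20, 0.20, 0.15, 0.10, 0.10)
    ),
    cell(2015:2017, 2:3,
      c("pembrolizumab", "nivolumab", "ipilimumab", "ipilimumab+nivolumab",
        "dabrafenib+trametinib", "temozolomide", "vemurafenib"),
      c(0.25, 0.20, 0.15, 0.10, 0.15, 0.10, 0.05)
    )
  )
}

#' Default comparator pool sizes
#'
#' Patients per database and first-line year available for matching,
#' mirroring the published post-matching cohort structure.
#'
#' @return Named list: database -> named integer vector (year -> count).
#' @export
default_comparator_pools <- function() {
  yc <- reference_year_counts()
  dbs <- setdiff(unique(yc$source), "social_media")
  stats::setNames(lapply(dbs, function(db) {
    sub <- yc[yc$source == db, ]
    stats::setNames(sub$n, sub$year)
  }), dbs)
}

#' Simulation configuration
#'
#' Defaults encode the study conditions this generator emulates: the
#' published social-media first-line year distribution over 2011-2017
#' (40, 96, 140, 180, 127, 127, 107 of 817), second/third-line retention
#' (226/817 and 73/226), and a single `noise` dial that sets the typo,
#' negated-mention, off-topic and intent rates together (individual rates
#' can be overridden).
#'
#' @param n_patients Number of simulated patients.
#' @param years First-line initiation year span.
#' @param year_weights Per-year first-line weights (sum to 1).
#' @param p_second_line P(a patient has a second line).
#' @param p_third_line P(third line | second line).
#' @param noise Master noise rate applied to `typo_rate`, `negation_rate`,
#'   `offtopic_rate`, `intent_rate` and `p_adjuvant_decoy` unless these are
#'   given explicitly.
#' @param typo_rate Probability a drug surface form carries one edit.
#' @param negation_rate Probability a patient posts a negated decoy mention.
#' @param offtopic_rate Probability a patient posts off-topic chatter.
#' @param intent_rate Probability a patient posts future-intent drug talk.
#' @param hearsay_rate Probability a patient posts about someone else's
#'   treatment or asks about a drug (affirmative-looking non-receipt).
#' @param p_adjuvant_decoy Probability of an adjuvant interferon decoy
#'   exposure before first line.
#' @param p_brand Probability a brand/abbreviation surface form is used.
#' @param p_relative_date Probability a receipt sentence phrases its date
#'   relative to the post date rather than as an absolute month.
#' @param p_remention Probability a line gets a second, later post.
#' @param p_filler Probability a receipt post carries a filler sentence.
#' @param regimen_distribution See [default_regimen_distribution()].
#' @param comparator_pools See [default_comparator_pools()].
#' @param seed Master RNG seed; stage streams are derived from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 1000L,
                       years = 2011:2017,
                       year_weights = c(40, 96, 140, 180, 127, 127, 107) / 817,
                       p_second_line = 226 / 817,
                       p_third_line = 73 / 226,
                       noise = 0.1,
                       typo_rate = noise,
                       negation_rate = noise,
                       offtopic_rate = noise,
                       intent_rate = noise,
                       hearsay_rate = noise,
                       p_adjuvant_decoy = noise,
                       p_brand = 0.3,
                       p_relative_date = 0.5,
                       p_remention = 0.35,
                       p_filler = 0.5,
                       regimen_distribution = default_regimen_distribution(),
                       comparator_pools = default_comparator_pools(),
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), years = as.integer(years),
    year_weights = year_weights, p_second_line = p_second_line,
    p_third_line = p_third_line, typo_rate = typo_rate,
    negation_rate = negation_rate, offtopic_rate = offtopic_rate,
    intent_rate = intent_rate, hearsay_rate = hearsay_rate,
    p_adjuvant_decoy = p_adjuvant_decoy,
    p_brand = p_brand, p_relative_date = p_relative_date,
    p_remention = p_remention, p_filler = p_filler,
    regimen_distribution = regimen_distribution,
    comparator_pools = comparator_pools, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(
    cfg$p_second_line, cfg$p_third_line, cfg$typo_rate, cfg$negation_rate,
    cfg$offtopic_rate, cfg$intent_rate, cfg$hearsay_rate,
    cfg$p_adjuvant_decoy, cfg$p_brand,
    cfg$p_relative_date, cfg$p_remention, cfg$p_filler, cfg$year_weights
  )
  if (any(probs < 0 | probs > 1) || anyNA(probs)) {
    abort("configuration error: all probabilities must lie in [0, 1]")
  }
  if (length(cfg$year_weights) != length(cfg$years)) {
    abort("configuration error: year_weights must match years")
  }
  if (abs(sum(cfg$year_weights) - 1) > 1e-9) {
    abort("configuration error: year_weights must sum to 1")
  }
  rd <- cfg$regimen_distribution
  if (is.null(rd) || nrow(rd) == 0L) {
    abort("configuration error: empty regimen distribution")
  }
  sums <- rd |>
    group_by(.data$year, .data$line) |>
    summarise(s = sum(.data$weight), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-9)) {
    abort("configuration error: regimen weights must sum to 1 per (year, line)")
  }
  pools <- unlist(cfg$comparator_pools)
  if (length(pools) > 0L && any(pools < 0)) {
    abort("configuration error: comparator pool counts must be >= 0")
  }
  invisible(cfg)
}

regimen_drugs <- function(label) strsplit(label, "+", fixed = TRUE)[[1]]

# Lookup of regimen-distribution cells keyed by "year:line" (years and
# lines outside the configured grid are clamped to the nearest cell).
regimen_cells <- function(rd) {
  key <- paste(rd$year, rd$line, sep = ":")
  cells <- lapply(split(seq_len(nrow(rd)), key), function(i) {
    list(
      regimen = rd$regimen[i], weight = rd$weight[i],
      drugs = lapply(rd$regimen[i], regimen_drugs)
    )
  })
  list(
    cells = cells,
    year_range = range(rd$year), line_max = max(rd$line)
  )
}

# Vector of regimen labels for (year, line) pairs, each drug-disjoint from
# the corresponding `exclude` regimen. Consecutive truth regimens are drawn
# disjoint from the immediately preceding line: forum text cannot
# distinguish continuation or re-challenge of a current drug from a new
# line, so the generator does not model it.
sample_regimens <- function(cells, years, line, exclude = NULL) {
  years <- pmin(pmax(years, cells$year_range[1]), cells$year_range[2])
  line <- min(line, cells$line_max)
  vapply(seq_along(years), function(i) {
    cell <- cells$cells[[paste(years[i], line, sep = ":")]]
    excl <- if (is.null(exclude)) character(0) else regimen_drugs(exclude[i])
    for (try in 1:25) {
      j <- sample.int(length(cell$regimen), 1L, prob = cell$weight)
      if (!any(cell$drugs[[j]] %in% excl)) {
        return(cell$regimen[j])
      }
    }
    ok <- which(!vapply(cell$drugs, function(d) any(d %in% excl), logical(1)))
    cell$regimen[ok[sample.int(length(ok), 1L)]]
  }, character(1))
}

# Line tables for a vector of first-line years (one journey per element),
# using the current RNG stream. Returns a tibble with `idx` identifying the
# journey.
sample_journeys <- function(first_years, cfg) {
  n <- length(first_years)
  cells <- regimen_cells(cfg$regimen_distribution)
  start1 <- as.Date(sprintf("%d-%02d-15", first_years, sample.int(12L, n, replace = TRUE)))
  reg1 <- sample_regimens(cells, first_years, 1L)
  has2 <- stats::runif(n) < cfg$p_second_line
  out <- list(tibble(
    idx = seq_len(n), line_number = 1L, regimen = reg1, start_date = start1
  ))
  if (any(has2)) {
    i2 <- which(has2)
    start2 <- start1[i2] %m+% months(sample(3:18, length(i2), replace = TRUE))
    reg2 <- sample_regimens(cells, lubridate::year(start2), 2L, exclude = reg1[i2])
    out[[2]] <- tibble(idx = i2, line_number = 2L, regimen = reg2, start_date = start2)
    has3 <- stats::runif(length(i2)) < cfg$p_third_line
    if (any(has3)) {
      i3 <- i2[has3]
      start3 <- start2[has3] %m+% months(sample(3:18, length(i3), replace = TRUE))
      reg3 <- sample_regimens(cells, lubridate::year(start3), 3L, exclude = reg2[has3])
      out[[3]] <- tibble(idx = i3, line_number = 3L, regimen = reg3, start_date = start3)
    }
  }
  bind_rows(out) |> arrange(.data$idx, .data$line_number)
}

#' Generate ground-truth patient journeys
#'
#' Each patient gets a forum, a unique username, a first-line year drawn
#' from the configured distribution, and one to three lines of therapy with
#' drug-disjoint consecutive regimens and 3-18 month gaps. Truth regimens
#' are never interferon-only or docetaxel-only; adjuvant interferon appears
#' only as a decoy exposure flag consumed by [render_posts()].
#'
#' @param config A [sim_config()].
#' @return Tibble: `patient_id`, `username`, `forum`, `line_number`,
#'   `regimen`, `start_date`, plus attribute `decoys` (tibble of adjuvant
#'   decoy exposures: `patient_id`, `drug`, `event_date`).
#' @export
generate_truth <- function(config) {
  validate_sim_config(config)
  withr::with_seed(derive_seed(config$seed, "truth"), {
    n <- config$n_patients
    forum <- sample(.forums, n, replace = TRUE, prob = .forum_weights)
    username <- sprintf("member%05d", seq_len(n))
    first_year <- config$years[
      sample.int(length(config$years), n, replace = TRUE, prob = config$year_weights)
    ]
    journeys <- sample_journeys(first_year, config)
    truth <- journeys |>
      mutate(
        patient_id = sprintf("sm%05d", .data$idx),
        username = username[.data$idx],
        forum = forum[.data$idx]
      ) |>
      select("patient_id", "username", "forum", "line_number", "regimen", "start_date")
    has_decoy <- stats::runif(n) < config$p_adjuvant_decoy
    first_starts <- truth |>
      filter(.data$line_number == 1L) |>
      arrange(.data$patient_id)
    decoys <- tibble(
      patient_id = first_starts$patient_id[has_decoy],
      drug = "interferon",
      event_date = first_starts$start_date[has_decoy] %m+%
        months(-sample(6:18, sum(has_decoy), replace = TRUE))
    )
    attr(truth, "decoys") <- decoys
    truth
  })
}

apply_typo <- function(word) {
  letters_pool <- letters
  i <- sample.int(nchar(word), 1L)
  op <- sample(c("sub", "del", "ins"), 1L)
  chars <- strsplit(word, "")[[1]]
  if (op == "sub") {
    repl <- sample(setdiff(letters_pool, chars[i]), 1L)
    chars[i] <- repl
  } else if (op == "del" && nchar(word) > 6L) {
    chars <- chars[-i]
  } else {
    chars <- append(chars, sample(letters_pool, 1L), after = i)
  }
  paste(chars, collapse = "")
}

# Surface realization of one drug: brand/abbreviation with prob p_brand,
# else canonical; a typo (single edit) only ever lands on a single-token
# surface of length >= 6 so the lexicon's bounded fuzzy match can always
# recover it (for multi-word names the typo goes on an eligible variant).
drug_surface <- function(drug, cfg, lexicon) {
  if (stats::runif(1) < cfg$typo_rate) {
    pool <- lexicon$surfaces$variant[lexicon$surfaces$canonical == drug]
    pool <- pool[!grepl(" ", pool) & nchar(pool) >= 6L]
    target <- if (drug %in% pool) drug else sample(pool, 1L)
    return(apply_typo(target))
  }
  if (stats::runif(1) < cfg$p_brand) {
    variants <- lexicon$surfaces$variant[
      lexicon$surfaces$canonical == drug & lexicon$surfaces$variant != drug
    ]
    if (length(variants) > 0L) {
      return(sample(variants, 1L))
    }
  }
  drug
}

regimen_surface <- function(regimen, cfg, lexicon) {
  drugs <- regimen_drugs(regimen)
  paste(vapply(drugs, drug_surface, character(1), cfg = cfg, lexicon = lexicon),
    collapse = " and "
  )
}

.number_words_out <- c(
  "one", "two", "three", "four", "five", "six", "seven", "eight", "nine",
  "ten", "eleven", "twelve"
)

# Temporal phrase for an event seen from post_date; chosen so that
# resolve_time() recovers the event month exactly.
when_phrase <- function(event_date, post_date, cfg) {
  k <- month_index(post_date) - month_index(event_date)
  relative <- stats::runif(1) < cfg$p_relative_date
  if (k == 0L || (!relative)) {
    if (k == 0L && relative) {
      return(NA_character_) # same-month: no expression, post-date default
    }
    mo <- as.integer(format(event_date, "%m"))
    return(sprintf("in %s %s", .month_titles[mo], format(event_date, "%Y")))
  }
  if (k == 1L) {
    return(sample(c("last month", "one month ago"), 1L))
  }
  num <- if (stats::runif(1) < 0.5) .number_words_out[k] else as.character(k)
  sprintf("%s months ago", num)
}

fill_template <- function(template, drug_text = NULL, when = NULL) {
  s <- template
  if (!is.null(drug_text)) s <- sub("{drug}", drug_text, s, fixed = TRUE)
  if (!is.null(when)) s <- sub("{when}", when, s, fixed = TRUE)
  s
}

#' Render ground-truth journeys as noisy forum posts
#'
#' Every truth line is described by at least one post whose affirmative
#' receipt sentence resolves (via [resolve_time()]) to the line's start
#' month; combination regimens are always mentioned in a single sentence so
#' their drugs share one date. Post dates lag events by 0-90 days. Noise is
#' added at configured rates: negated decoy mentions, future-intent decoys,
#' off-topic chatter, adjuvant interferon decoys, brand names and one-edit
#' typos. A sentence-level truth table (receipt vs non-receipt) is returned
#' alongside, keyed by (username, forum, post_date, cleaned sentence).
#'
#' @param truth Output of [generate_truth()].
#' @param config The same [sim_config()].
#' @param lexicon Lexicon used for surface realization.
#' @return List: `posts` (tibble `username`, `forum`, `post_date`, `text`)
#'   and `labels` (tibble `username`, `forum`, `post_date`, `sentence`,
#'   `label`).
#' @export
render_posts <- function(truth, config, lexicon = default_lexicon()) {
  stopifnot(nrow(truth) > 0L)
  validate_sim_config(config)
  decoys <- attr(truth, "decoys") %||%
    tibble(patient_id = character(), drug = character(), event_date = as.Date(character()))
  all_drugs <- sort(lexicon$entries$canonical[!lexicon$entries$adjuvant_flag])

  withr::with_seed(derive_seed(config$seed, "posts"), {
    posts <- list()
    labels <- list()
    emit <- function(username, forum, post_date, sentences, sent_labels) {
      text <- paste(sentences, collapse = " ")
      posts[[length(posts) + 1L]] <<- tibble(
        username = username, forum = forum, post_date = post_date, text = text
      )
      labels[[length(labels) + 1L]] <<- tibble(
        username = username, forum = forum, post_date = post_date,
        sentence = clean_text(sentences), label = sent_labels
      )
    }

    receipt_post <- function(username, forum, line) {
      event <- line$start_date
      post_date <- event + sample(0:90, 1L)
      when <- when_phrase(event, post_date, config)
      drug_text <- regimen_surface(line$regimen, config, lexicon)
      sentence <- maybe_clause(compose_receipt(drug_text, when))
      sentences <- sentence
      labs <- "receipt"
      if (stats::runif(1) < config$p_filler) {
        sentences <- c(sentences, maybe_clause(sample(.templates$filler, 1L)))
        labs <- c(labs, "non_receipt")
      }
      emit(username, forum, post_date, sentences, labs)
    }

    patients <- truth |> distinct(.data$patient_id, .data$username, .data$forum)
    truth_by_patient <- split(truth, truth$patient_id)
    decoys_by_patient <- split(decoys, decoys$patient_id)

    for (r in seq_len(nrow(patients))) {
      pid <- patients$patient_id[r]
      uname <- patients$username[r]
      forum <- patients$forum[r]
      jl <- truth_by_patient[[pid]]
      span_start <- min(jl$start_date)
      span_end <- max(jl$start_date) + 120L
      span_days <- as.integer(span_end - span_start)
      own_drugs <- unique(unlist(lapply(jl$regimen, regimen_drugs)))

      for (li in seq_len(nrow(jl))) {
        line <- jl[li, ]
        receipt_post(uname, forum, line)
        if (stats::runif(1) < config$p_remention) {
          receipt_post(uname, forum, line)
        }
      }

      dd <- decoys_by_patient[[pid]]
      if (!is.null(dd) && nrow(dd) > 0L) {
        for (di in seq_len(nrow(dd))) {
          post_date <- dd$event_date[di] + sample(0:90, 1L)
          sentence <- maybe_clause(fill_template(sample(.templates$adjuvant, 1L), dd$drug[di]))
          emit(uname, forum, post_date, sentence, "receipt")
        }
      }
      if (stats::runif(1) < config$negation_rate) {
        decoy_drug <- sample(setdiff(all_drugs, own_drugs), 1L)
        post_date <- span_start + sample.int(max(span_days, 1L), 1L)
        when <- when_phrase(post_date - sample(0:180, 1L), post_date, config)
        sentence <- maybe_clause(fill_template(
          sample(.templates$negation, 1L),
          drug_surface(decoy_drug, config, lexicon),
          when = if (is.na(when)) "back then" else when
        ))
        emit(uname, forum, post_date, sentence, "non_receipt")
      }
      if (stats::runif(1) < config$intent_rate) {
        decoy_drug <- sample(setdiff(all_drugs, own_drugs), 1L)
        post_date <- span_start + sample.int(max(span_days, 1L), 1L)
        sentence <- maybe_clause(fill_template(
          sample(.templates$intent, 1L),
          drug_surface(decoy_drug, config, lexicon)
        ))
        emit(uname, forum, post_date, sentence, "non_receipt")
      }
      if (stats::runif(1) < config$hearsay_rate) {
        decoy_drug <- sample(setdiff(all_drugs, own_drugs), 1L)
        post_date <- span_start + sample.int(max(span_days, 1L), 1L)
        when <- when_phrase(post_date - sample(0:180, 1L), post_date, config)
        sentence <- maybe_clause(compose_hearsay(
          drug_surface(decoy_drug, config, lexicon), when
        ))
        emit(uname, forum, post_date, sentence, "non_receipt")
      }
      if (stats::runif(1) < config$offtopic_rate) {
        for (k in seq_len(sample(1:2, 1L))) {
          post_date <- span_start + sample.int(max(span_days, 1L), 1L)
          tpl <- sample(.templates$offtopic, 1L)
          mo <- sample.int(12L, 1L)
          sentence <- sub("{month}", .month_titles[mo], tpl, fixed = TRUE)
          sentence <- maybe_clause(sub("{year}",
            as.character(config$years[sample.int(length(config$years), 1L)]), sentence,
            fixed = TRUE
          ))
          emit(uname, forum, post_date, sentence, "non_receipt")
        }
      }
    }

    posts <- bind_rows(posts)
    labels <- bind_rows(labels) |> distinct()
    ord <- order(posts$username, posts$post_date, posts$text)
    list(posts = posts[ord, , drop = FALSE], labels = labels)
  })
}

#' Render comparator cohort tables
#'
#' For each database and year, exactly the configured number of patients is
#' generated, each with a first line starting that year and optional later
#' lines drawn from the same regimen distribution as the social-media
#' truth.
#'
#' @param config A [sim_config()].
#' @return Tibble: `patient_id`, `database`, `first_line_year`,
#'   `line_number`, `regimen`, `start_date`.
#' @export
render_comparators <- function(config) {
  validate_sim_config(config)
  out <- list()
  for (db in names(config$comparator_pools)) {
    pool <- config$comparator_pools[[db]]
    out[[db]] <- withr::with_seed(derive_seed(config$seed, paste0("comparators:", db)), {
      first_years <- rep(as.integer(names(pool)), times = as.integer(pool))
      if (length(first_years) == 0L) {
        NULL
      } else {
        sample_journeys(first_years, config) |>
          mutate(
            patient_id = sprintf("%s%06d", db, .data$idx),
            database = db,
            first_line_year = first_years[.data$idx]
          )
      }
    })
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble(
      patient_id = character(), database = character(),
      first_line_year = integer(), line_number = integer(),
      regimen = character(), start_date = as.Date(character())
    ))
  }
  select(res, "patient_id", "database", "first_line_year", "line_number", "regimen", "start_date")
}
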