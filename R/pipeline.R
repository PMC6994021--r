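# Orchestration: the in-memory end-to-end pipeline, and disk-backed stages
# with manifests for reproducible reruns.

#' Run the full pipeline in memory
#'
#' Posts -> sentence table -> user filter -> mention detection -> sentence
#' classification -> negation + temporal resolution -> timelines -> lines.
#' When `labels` is supplied (sentence-level receipt / non-receipt truth,
#' keyed by username, forum, post_date and cleaned sentence text) a
#' classifier is trained on them and applied to every mention-bearing
#' sentence; with `labels = NULL` (or single-class labels) every
#' mention-bearing sentence is treated as stating receipt and filtering
#' relies on the negation and temporal rules alone.
#'
#' @param posts Post tibble (`username`, `forum`, `post_date`, `text`).
#' @param lexicon Treatment lexicon.
#' @param labels Optional sentence-level label table.
#' @param model_name Classifier to train when labels are available.
#' @param combo_window_days Combination window for line assignment.
#' @param seed Integer seed (classifier balancing etc.).
#' @return List: `records`, `mentions`, `verdicts`, `resolved`, `lines`,
#'   `counts`, `classifier` (or `NULL`).
#' @export
run_pipeline <- function(posts, lexicon = default_lexicon(), labels = NULL,
                         model_name = "svm_linear", combo_window_days = 28L,
                         seed = 1L) {
  records <- tokenize_posts(posts)
  mentions <- mentions_table(records, lexicon)
  # user-level treatment filter, reusing the single mention scan
  records <- records[records$user_id %in% unique(mentions$user_id), , drop = FALSE]

  classifier <- NULL
  mention_keys <- mentions |> distinct(.data$user_id, .data$post_id, .data$sentence_index)
  if (!is.null(labels)) {
    labeled <- records |>
      inner_join(
        labels |> distinct(.data$username, .data$forum, .data$post_date,
          .data$sentence, .data$label
        ),
        by = c("username", "forum", "post_date", text = "sentence")
      )
    if (length(unique(labeled$label)) >= 2L) {
      vec <- tfidf_fit(labeled$text)
      x <- tfidf_transform(vec, labeled$text)
      classifier <- train_classifier(x, labeled$label, model_name, seed = seed)
      sent <- records |> semi_join(mention_keys, by = c("user_id", "post_id", "sentence_index"))
      verdicts <- sent |>
        select("user_id", "post_id", "sentence_index") |>
        mutate(label = as.character(predict(classifier, tfidf_transform(vec, sent$text))))
    } else {
      verdicts <- mention_keys |> mutate(label = "receipt")
    }
  } else {
    verdicts <- mention_keys |> mutate(label = "receipt")
  }

  resolved <- resolve_mentions(mentions, records, verdicts)
  lines <- derive_lines(resolved, combo_window_days, lexicon)
  list(
    records = records, mentions = mentions, verdicts = verdicts,
    resolved = resolved, lines = lines, counts = line_counts(lines),
    classifier = classifier
  )
}

.stages <- c("simulate", "preprocess", "classify", "extract", "lines", "match", "compare")

stage_inputs <- function(stage) {
  switch(stage,
    simulate = character(0),
    preprocess = "posts.jsonl",
    classify = c("sentences.csv", "labels.csv"),
    extract = c("sentences.csv", "verdicts.csv"),
    lines = "resolved.csv",
    match = c("lines.csv", "comparators.csv"),
    compare = c("lines.csv", "comparators.csv", "matched.csv")
  )
}

#' Pipeline configuration for disk-backed stages
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed recorded in every manifest.
#' @param n_patients,noise Passed to [sim_config()] for the simulate stage.
#' @param model_name Classifier trained in the classify stage.
#' @param combo_window_days Combination window for the lines stage.
#' @param ratio Frequency-matching ratio for the match stage.
#' @param top_k Regimens per line reported in the compare stage.
#' @return A named list understood by [run_stage()].
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_patients = 500L, noise = 0.1,
                            model_name = "svm_linear", combo_window_days = 28L,
                            ratio = 4L, top_k = 6L) {
  list(
    out_dir = out_dir, seed = as.integer(seed),
    n_patients = as.integer(n_patients), noise = noise,
    model_name = model_name, combo_window_days = as.integer(combo_window_days),
    ratio = as.integer(ratio), top_k = as.integer(top_k)
  )
}

write_manifest <- function(stage, config, inputs, outputs) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("forumlot")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    inputs = lapply(inputs, function(f) {
      list(file = f, checksum = checksum_file(file.path(config$out_dir, f)))
    }),
    outputs = outputs
  )
  path <- file.path(config$out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

require_inputs <- function(stage, config) {
  needed <- stage_inputs(stage)
  missing <- needed[!file.exists(file.path(config$out_dir, needed))]
  if (length(missing) > 0L) {
    producer <- vapply(missing, function(f) {
      names(which(vapply(.stages, function(s) {
        f %in% stage_outputs_names(s)
      }, logical(1))))[1]
    }, character(1))
    abort(paste0(
      "missing upstream artifact(s) ", paste(missing, collapse = ", "),
      "; run stage '", paste(unique(producer), collapse = "', '"), "' first"
    ))
  }
}

stage_outputs_names <- function(stage) {
  switch(stage,
    simulate = c("posts.jsonl", "truth.csv", "labels.csv", "comparators.csv", "config.yaml"),
    preprocess = "sentences.csv",
    classify = c("verdicts.csv", "classifier_metrics.json"),
    extract = "resolved.csv",
    lines = c("lines.csv", "line_counts.csv"),
    match = c("matched.csv", "match_summary.csv"),
    compare = c("estimates.csv", "concordance.json")
  )
}

#' Run one pipeline stage against an output directory
#'
#' Stages: `simulate`, `preprocess`, `classify`, `extract`, `lines`,
#' `match`, `compare`. Each stage reads its upstream artifacts from
#' `config$out_dir` (a missing artifact is an error naming the stage to run
#' first), writes its outputs there, and records a manifest (input
#' checksums, configuration, seed, package version). Reruns with unchanged
#' inputs and configuration produce identical artifacts and manifests.
#'
#' @param stage Stage name.
#' @param config A [pipeline_config()].
#' @return Invisibly, the output file names.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, .stages)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  require_inputs(stage, config)
  od <- function(f) file.path(config$out_dir, f)
  message("[", stage, "] running (seed ", config$seed, ")")

  if (stage == "simulate") {
    sc <- sim_config(
      n_patients = config$n_patients, noise = config$noise, seed = config$seed
    )
    truth <- generate_truth(sc)
    rendered <- render_posts(truth, sc)
    write_posts_jsonl(rendered$posts, od("posts.jsonl"))
    readr::write_csv(truth, od("truth.csv"))
    readr::write_csv(rendered$labels, od("labels.csv"))
    readr::write_csv(render_comparators(sc), od("comparators.csv"))
    yaml::write_yaml(
      config[c("seed", "n_patients", "noise")],
      od("config.yaml")
    )
  } else if (stage == "preprocess") {
    posts <- read_posts_jsonl(od("posts.jsonl"))
    records <- filter_treatment_users(tokenize_posts(posts))
    readr::write_csv(records, od("sentences.csv"))
  } else if (stage == "classify") {
    records <- readr::read_csv(od("sentences.csv"), col_types = "cccDiic")
    labels <- readr::read_csv(od("labels.csv"), col_types = "ccDcc")
    labeled <- records |>
      inner_join(
        labels |> distinct(.data$username, .data$forum, .data$post_date,
          .data$sentence, .data$label
        ),
        by = c("username", "forum", "post_date", text = "sentence")
      )
    study <- classifier_study(labeled$text, labeled$label, seed = config$seed)
    vec <- tfidf_fit(labeled$text)
    clf <- train_classifier(
      tfidf_transform(vec, labeled$text), labeled$label,
      config$model_name, seed = config$seed
    )
    verdicts <- records |>
      select("user_id", "post_id", "sentence_index") |>
      mutate(label = as.character(predict(clf, tfidf_transform(vec, records$text))))
    readr::write_csv(verdicts, od("verdicts.csv"))
    jsonlite::write_json(
      list(metrics = study$metrics, best = study$best),
      od("classifier_metrics.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  } else if (stage == "extract") {
    records <- readr::read_csv(od("sentences.csv"), col_types = "cccDiic")
    verdicts <- readr::read_csv(od("verdicts.csv"), col_types = "ciic")
    mentions <- mentions_table(records)
    resolved <- resolve_mentions(mentions, records, verdicts)
    readr::write_csv(resolved, od("resolved.csv"))
  } else if (stage == "lines") {
    resolved <- readr::read_csv(od("resolved.csv"), col_types = "ccDiiclDc")
    lines <- derive_lines(resolved, config$combo_window_days)
    readr::write_csv(lines, od("lines.csv"))
    readr::write_csv(line_counts(lines), od("line_counts.csv"))
  } else if (stage == "match") {
    lines <- readr::read_csv(od("lines.csv"), col_types = "cicD")
    comparators <- readr::read_csv(od("comparators.csv"), col_types = "cciicD")
    sm_years <- lines |>
      filter(.data$line_number == 1L) |>
      count(year = as.integer(format(.data$start_date, "%Y")), name = "n")
    pool <- comparators |> distinct(.data$patient_id, .data$database, .data$first_line_year)
    mc <- frequency_match(sm_years, pool, ratio = config$ratio, seed = config$seed)
    readr::write_csv(mc$matched, od("matched.csv"))
    readr::write_csv(mc$per_year, od("match_summary.csv"))
  } else if (stage == "compare") {
    lines <- readr::read_csv(od("lines.csv"), col_types = "cicD")
    comparators <- readr::read_csv(od("comparators.csv"), col_types = "cciicD")
    matched <- readr::read_csv(od("matched.csv"), col_types = "cci")
    matched_lines <- comparators |>
      semi_join(matched, by = c("database", "patient_id"))
    ests <- list()
    for (ln in 1:3) {
      sm_cnt <- length(unique(lines$patient_id[lines$line_number >= ln]))
      if (sm_cnt == 0L) next
      sm_est <- proportion_table(lines, ln, top_k = config$top_k, source = "social_media")
      ests[[length(ests) + 1L]] <- sm_est
      for (db in sort(unique(matched_lines$database))) {
        dbl <- matched_lines |> filter(.data$database == db)
        if (!any(dbl$line_number >= ln)) next
        ests[[length(ests) + 1L]] <- proportion_table(
          dbl, ln,
          regimens = sm_est$regimen, source = db
        )
      }
    }
    estimates <- bind_rows(ests)
    readr::write_csv(estimates, od("estimates.csv"))
    rep <- concordance_report(compare_sources(estimates))
    jsonlite::write_json(
      list(any_overlap = rep$any_overlap, by_line = rep$by_line),
      od("concordance.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  }

  outputs <- stage_outputs_names(stage)
  write_manifest(stage, config, stage_inputs(stage), as.list(outputs))
  invisible(outputs)
}

#' Run all pipeline stages in order
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the output directory.
#' @export
run_all <- function(config) {
  for (s in .stages) run_stage(s, config)
  invisible(config$out_dir)
}
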