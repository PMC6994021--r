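test_that("TF-IDF matches the closed-form idf and L2 normalization", {
  vec <- tfidf_fit(c("a b", "a c"))
  idf <- stats::setNames(vec$idf, vec$vocab)
  expect_equal(unname(idf["a"]), log(3 / 3) + 1)
  expect_equal(unname(idf["b"]), log(3 / 2) + 1)
  expect_equal(unname(idf["c"]), log(3 / 2) + 1)
  x <- tfidf_transform(vec, c("a b", "a c"))
  # hand-computed: row1 weights (1, 1.4054651) before normalization
  wb <- log(3 / 2) + 1
  nrm <- sqrt(1 + wb^2)
  expect_equal(unname(x[1, "a"]), 1 / nrm, tolerance = 1e-12)
  expect_equal(unname(x[1, "b"]), wb / nrm, tolerance = 1e-12)
  expect_equal(sqrt(rowSums(x^2)), c(1, 1))
  # single document: equal tf means equal weight after L2
  v1 <- tfidf_fit("x y z")
  x1 <- tfidf_transform(v1, "x y z")
  expect_true(all(abs(x1 - 1 / sqrt(3)) < 1e-12))
  # unseen token contributes nothing at transform time
  x2 <- tfidf_transform(vec, "q q q")
  expect_equal(sum(x2), 0)
  expect_error(tfidf_fit(character(0)), "empty")
})

test_that("precision/recall follow the stated definitions and NA conventions", {
  # TP=3 FP=1 FN=1
  truth <- c(rep("receipt", 4), rep("non_receipt", 2))
  pred <- c("receipt", "receipt", "receipt", "non_receipt", "receipt", "non_receipt")
  ev <- evaluate_classifier(truth, pred)
  expect_equal(ev$precision, 0.75)
  expect_equal(ev$recall, 0.75)
  ev2 <- evaluate_classifier(truth, truth)
  expect_equal(ev2$precision, 1)
  expect_equal(ev2$recall, 1)
  # zero predicted positives: precision absent, recall 0 when FN > 0
  ev3 <- evaluate_classifier(truth, rep("non_receipt", 6))
  expect_true(is.na(ev3$precision))
  expect_equal(ev3$recall, 0)
  expect_error(evaluate_classifier(truth, pred[-1]), "mismatch")
})

test_that("model selection maximizes precision+recall with the stated ties", {
  metrics <- tibble::tibble(
    model = c("svm_linear", "naive_bayes", "knn"),
    precision = c(0.84, 0.81, 0.68),
    recall = c(0.84, 0.81, 0.50)
  )
  expect_equal(select_model(metrics), "svm_linear")
  expect_equal(select_model(metrics[2, ]), "naive_bayes")
  tie <- tibble::tibble(
    model = c("knn", "naive_bayes"), precision = c(0.9, 0.9), recall = c(0.9, 0.9)
  )
  # exact tie on both -> first in the fixed model order
  expect_equal(select_model(tie), "naive_bayes")
  expect_error(select_model(metrics[0, ]), "candidate")
})

test_that("all three models fit a separable toy problem and predict deterministically", {
  sentences <- c(
    rep("i started the drug and it went fine", 10),
    rep("my friend started the drug recently", 10)
  )
  labels <- rep(c("receipt", "non_receipt"), each = 10)
  vec <- tfidf_fit(sentences)
  x <- tfidf_transform(vec, sentences)
  for (m in c("svm_linear", "naive_bayes", "knn")) {
    clf <- train_classifier(x, labels, m, seed = 1)
    p1 <- predict(clf, x)
    expect_equal(as.character(p1), labels, info = m)
    expect_identical(as.character(p1), as.character(predict(clf, x)), info = m)
  }
  expect_equal(train_classifier(x, labels, "knn")$fit$k, 5L)
  expect_error(train_classifier(x, rep("receipt", 20), "svm_linear"), "single class")
})

test_that("class balancing restores at most a 60/40 split before fitting", {
  sentences <- c(
    sprintf("i started drug number %d today", 1:90),
    sprintf("my friend tried drug number %d", 1:10)
  )
  labels <- rep(c("receipt", "non_receipt"), c(90, 10))
  vec <- tfidf_fit(sentences)
  x <- tfidf_transform(vec, sentences)
  clf <- train_classifier(x, labels, "knn", seed = 4)
  tab <- table(clf$fit$cl)
  expect_lte(max(tab) / sum(tab), 0.6)
  expect_equal(unname(tab[["non_receipt"]]), 10L)
})

test_that("classifier study metrics are stable across seeds on one corpus", {
  cfg <- sim_config(n_patients = 400, noise = 0.1, seed = 77)
  rendered <- render_posts(generate_truth(cfg), cfg)
  recs <- tokenize_posts(rendered$posts)
  labeled <- dplyr::inner_join(
    recs,
    dplyr::distinct(rendered$labels, username, forum, post_date, sentence, label),
    by = c("username", "forum", "post_date", text = "sentence")
  )
  scores <- vapply(1:3, function(sd) {
    st <- classifier_study(labeled$text, labeled$label, seed = sd,
      models = "svm_linear"
    )
    st$metrics$precision + st$metrics$recall
  }, numeric(1))
  expect_lt(max(scores) - min(scores), 0.06) # < 3 points on either metric
})
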