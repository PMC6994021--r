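# Sentence-level treatment-receipt classification: TF-IDF features and the
# three classical text classifiers (linear SVM, multinomial naive Bayes,
# KNN with K = 5).

tokenize_features <- function(x) {
  toks <- strsplit(tolower(x), "[^a-z0-9'-]+")
  lapply(toks, function(t) t[nzchar(t)])
}

#' Fit a TF-IDF vectorizer
#'
#' Lowercased unigram tokens; smoothed inverse document frequency
#' `idf(t) = ln((1 + N) / (1 + df(t))) + 1`; transformed rows are
#' L2-normalized. The vocabulary is whatever the training corpus contains:
#' tokens unseen at fit time contribute nothing at transform time.
#'
#' @param x Non-empty character vector of training sentences.
#' @return A `tfidf_model` with fields `vocab`, `idf`, `n_docs`.
#' @export
tfidf_fit <- function(x) {
  if (length(x) == 0L) abort("empty training corpus")
  toks <- tokenize_features(x)
  vocab <- sort(unique(unlist(toks)))
  if (length(vocab) == 0L) abort("training corpus has no tokens")
  df <- integer(length(vocab))
  for (t in toks) {
    idx <- unique(match(t, vocab))
    idx <- idx[!is.na(idx)]
    df[idx] <- df[idx] + 1L
  }
  idf <- log((1 + length(x)) / (1 + df)) + 1
  structure(
    list(vocab = vocab, idf = idf, n_docs = length(x)),
    class = "tfidf_model"
  )
}

#' Transform sentences into a TF-IDF weight matrix
#'
#' @param model A `tfidf_model` from [tfidf_fit()].
#' @param x Character vector of sentences.
#' @return Dense numeric matrix, one row per sentence, columns = fitted
#'   vocabulary, rows L2-normalized (all-zero rows stay zero).
#' @export
tfidf_transform <- function(model, x) {
  stopifnot(inherits(model, "tfidf_model"))
  toks <- tokenize_features(x)
  V <- length(model$vocab)
  out <- matrix(0, nrow = length(x), ncol = V, dimnames = list(NULL, model$vocab))
  for (i in seq_along(toks)) {
    idx <- match(toks[[i]], model$vocab)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) next
    tf <- tabulate(idx, nbins = V)
    w <- tf * model$idf
    nrm <- sqrt(sum(w^2))
    if (nrm > 0) w <- w / nrm
    out[i, ] <- w
  }
  out
}

.model_order <- c("svm_linear", "naive_bayes", "knn")

#' Train a treatment-receipt sentence classifier
#'
#' `svm_linear` is a linear-kernel support vector machine (via
#' \pkg{e1071}), `naive_bayes` a multinomial naive Bayes with Laplace
#' smoothing fitted on the TF-IDF weights, and `knn` a K-nearest-neighbour
#' classifier with `K = 5` (via \pkg{class}). When class imbalance exceeds
#' 60/40 the majority class is downsampled (seeded) before fitting.
#'
#' @param x Feature matrix from [tfidf_transform()].
#' @param y Labels, coercible to a factor with levels `receipt` /
#'   `non_receipt`; both classes must be present.
#' @param model_name One of `"svm_linear"`, `"naive_bayes"`, `"knn"`.
#' @param seed Integer seed controlling balancing (and any tie-breaking).
#' @param k Neighbourhood size for KNN.
#' @return A `treatment_classifier`.
#' @export
train_classifier <- function(x, y, model_name = c("svm_linear", "naive_bayes", "knn"),
                             seed = 1L, k = 5L) {
  model_name <- match.arg(model_name)
  y <- factor(as.character(y))
  if (nlevels(y) < 2L) abort("training labels contain a single class")
  if (nrow(x) != length(y)) abort("feature/label length mismatch")

  shares <- table(y) / length(y)
  if (max(shares) > 0.6) {
    maj <- names(shares)[which.max(shares)]
    min_n <- min(table(y))
    target <- ceiling(1.5 * min_n) # restore to at most 60/40
    keep_maj <- withr::with_seed(
      derive_seed(seed, "balance"),
      sample(which(y == maj), min(target, sum(y == maj)))
    )
    idx <- sort(c(which(y != maj), keep_maj))
    x <- x[idx, , drop = FALSE]
    y <- droplevels(y[idx])
  }

  fit <- switch(model_name,
    svm_linear = e1071::svm(
      x = x, y = y, kernel = "linear", scale = FALSE, cost = 1
    ),
    naive_bayes = {
      cs <- rowsum(x, y) # class-wise summed term weights
      alpha <- 1
      logp <- log(cs + alpha) - log(rowSums(cs) + alpha * ncol(x))
      list(logp = logp, prior = log(as.numeric(table(y)) / length(y)),
           classes = levels(y))
    },
    knn = list(train = x, cl = y, k = as.integer(k))
  )
  structure(
    list(model_name = model_name, fit = fit, levels = levels(y), seed = seed),
    class = "treatment_classifier"
  )
}

#' @export
print.treatment_classifier <- function(x, ...) {
  cat("<treatment_classifier>", x$model_name, "\n")
  invisible(x)
}

#' Predict treatment-receipt labels
#'
#' @param object A `treatment_classifier`.
#' @param newdata Feature matrix with the same columns as at training time.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.treatment_classifier <- function(object, newdata, ...) {
  switch(object$model_name,
    svm_linear = predict(object$fit, newdata),
    naive_bayes = {
      scores <- newdata %*% t(object$fit$logp)
      scores <- sweep(scores, 2L, object$fit$prior, `+`)
      factor(object$fit$classes[max.col(scores, ties.method = "first")],
        levels = object$fit$classes
      )
    },
    knn = withr::with_seed(
      derive_seed(object$seed, "knn_predict"),
      class::knn(object$fit$train, newdata, object$fit$cl, k = object$fit$k)
    )
  )
}

#' Precision and recall of receipt predictions
#'
#' Precision is the fraction of sentences predicted `receipt` that truly
#' are; recall the fraction of true `receipt` sentences that were found.
#' An undefined ratio (zero denominator) is reported as `NA`, not zero.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param positive Label counted as positive.
#' @return List with `precision` and `recall`.
#' @export
evaluate_classifier <- function(truth, predicted, positive = "receipt") {
  if (length(truth) != length(predicted)) abort("length mismatch")
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  tp <- sum(truth == positive & predicted == positive)
  fp <- sum(truth != positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  list(
    precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  )
}

#' Select the best classifier from evaluated candidates
#'
#' Argmax of precision + recall; ties broken by precision, then by the fixed
#' model order svm_linear, naive_bayes, knn.
#'
#' @param metrics Tibble/data.frame with columns `model`, `precision`,
#'   `recall` (one row per candidate).
#' @return The winning model name (character).
#' @export
select_model <- function(metrics) {
  if (is.null(metrics) || nrow(metrics) == 0L) abort("no candidate models")
  score <- metrics$precision + metrics$recall
  ord <- order(-score, -metrics$precision, match(metrics$model, .model_order))
  metrics$model[ord[1L]]
}

#' Train/test comparison of the three candidate classifiers
#'
#' Stratified seeded split (default 80/20), TF-IDF fitted on the training
#' fold only, all three models trained and evaluated on the held-out fold.
#'
#' @param sentences Character vector of labeled sentences.
#' @param labels `receipt` / `non_receipt` labels.
#' @param train_frac Training fraction.
#' @param seed Integer seed for the split and balancing.
#' @param models Candidate model names.
#' @return List: `metrics` (tibble model/precision/recall), `best` (model
#'   name), `n_train`, `n_test`.
#' @export
classifier_study <- function(sentences, labels, train_frac = 0.8, seed = 1L,
                             models = .model_order) {
  labels <- factor(as.character(labels))
  stopifnot(length(sentences) == length(labels))
  idx_train <- withr::with_seed(derive_seed(seed, "split"), {
    unlist(lapply(levels(labels), function(l) {
      i <- which(labels == l)
      sample(i, floor(train_frac * length(i)))
    }))
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_along(sentences), idx_train)
  vec <- tfidf_fit(sentences[idx_train])
  xtr <- tfidf_transform(vec, sentences[idx_train])
  xte <- tfidf_transform(vec, sentences[idx_test])
  rows <- lapply(models, function(m) {
    clf <- train_classifier(xtr, labels[idx_train], m, seed = seed)
    ev <- evaluate_classifier(labels[idx_test], predict(clf, xte))
    tibble(model = m, precision = ev$precision, recall = ev$recall)
  })
  metrics <- bind_rows(rows)
  list(
    metrics = metrics, best = select_model(metrics),
    n_train = length(idx_train), n_test = length(idx_test)
  )
}
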