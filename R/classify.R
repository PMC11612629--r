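# Classification and evaluation harness: the four classifier
# configurations, confusion-matrix metrics (including the
# accuracy/sensitivity F1 variant), stratified k-fold cross-validation,
# and fold-based confidence intervals.

#' Classifier specification
#'
#' Four supported kinds with their standard configurations:
#' * `"svm"`: polynomial kernel of degree 5, `gamma = 0.1`, `cost = 1`;
#' * `"ann"`: single hidden layer of 19 units, softmax output with
#'   cross-entropy fit;
#' * `"rf"`: seeded random forest;
#' * `"xgboost"`: gradient-boosted trees (softmax objective).
#'
#' Features are standardised (zero mean, unit variance, fitted on the
#' training rows only) before SVM and ANN; tree models consume raw
#' features.
#'
#' @param kind One of `"svm"`, `"ann"`, `"rf"`, `"xgboost"`.
#' @param ... Overrides of the kind's default parameters.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(kind = c("rf", "svm", "ann", "xgboost"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    svm = list(degree = 5, gamma = 0.1, cost = 1),
    ann = list(hidden = 19, maxit = 300, decay = 1e-4, seed = 7L),
    rf = list(num_trees = 300, seed = 7L),
    xgboost = list(nrounds = 60, max_depth = 4, eta = 0.3, seed = 7L))
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad) > 0) stop("unknown parameter(s) for ", kind, ": ",
                            paste(bad, collapse = ", "))
  defaults[names(override)] <- override
  structure(list(kind = kind, params = defaults), class = "model_spec")
}

standardizer <- function(x_train) {
  mu <- colMeans(x_train)
  sg <- apply(x_train, 2, sd)
  sg[sg == 0] <- 1
  function(x) sweep(sweep(x, 2, mu), 2, sg, "/")
}

#' Train a classifier and predict evaluation rows
#'
#' Standardisation (for SVM and ANN) is fitted on the training rows only
#' and applied to the evaluation rows; predictions are deterministic
#' given the spec's seeds.
#'
#' @param spec A [model_spec].
#' @param x_train,x_eval Numeric matrices with identical columns.
#' @param y_train Training labels (>= 2 classes).
#' @return Character vector of predicted labels, one per eval row.
#' @export
train_and_predict <- function(spec, x_train, y_train, x_eval) {
  stopifnot(inherits(spec, "model_spec"))
  if (!identical(colnames(x_train), colnames(x_eval))) {
    stop("train and eval feature columns differ")
  }
  lev <- sort(unique(as.character(y_train)))
  if (length(lev) < 2) stop("training labels contain a single class")
  y <- factor(as.character(y_train), levels = lev)
  p <- spec$params
  switch(spec$kind,
    svm = {
      sc <- standardizer(x_train)
      fit <- e1071::svm(x = sc(x_train), y = y, kernel = "polynomial",
                        degree = p$degree, gamma = p$gamma, cost = p$cost)
      as.character(predict(fit, sc(x_eval)))
    },
    ann = {
      sc <- standardizer(x_train)
      fit <- with_seed(p$seed,
        nnet::nnet(x = sc(x_train), y = nnet::class.ind(y),
                   size = p$hidden, softmax = TRUE, maxit = p$maxit,
                   decay = p$decay, trace = FALSE, MaxNWts = 100000))
      pr <- predict(fit, sc(x_eval))
      lev[max.col(pr, ties.method = "first")]
    },
    rf = rf_fit_predict(x_train, y, x_eval, p$num_trees, p$seed),
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(data = x_train,
                                     label = as.integer(y) - 1L)
      fit <- with_seed(p$seed,
        xgboost::xgb.train(params = list(objective = "multi:softmax",
                                         num_class = length(lev),
                                         max_depth = p$max_depth,
                                         eta = p$eta, nthread = 1),
                           data = dtrain, nrounds = p$nrounds,
                           verbose = 0))
      lev[predict(fit, xgboost::xgb.DMatrix(data = x_eval)) + 1L]
    })
}

#' Confusion matrix
#'
#' Entry (i, j) counts samples of true class i predicted as class j.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param levels Class levels fixing row/column order; defaults to the
#'   sorted union of observed labels.
#' @return K x K integer matrix with dimnames `truth` x `predicted`.
#' @export
confusion_matrix <- function(y_true, y_pred, levels = NULL) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (is.null(levels)) levels <- sort(unique(c(as.character(y_true),
                                               as.character(y_pred))))
  bad <- setdiff(unique(c(as.character(y_true), as.character(y_pred))), levels)
  if (length(bad) > 0) stop("label(s) outside 'levels': ",
                            paste(bad, collapse = ", "))
  tab <- table(factor(as.character(y_true), levels = levels),
               factor(as.character(y_pred), levels = levels))
  m <- matrix(as.integer(tab), nrow = length(levels),
              dimnames = list(truth = levels, predicted = levels))
  m
}

one_vs_rest_counts <- function(confusion, k) {
  tp <- confusion[k, k]
  fn <- sum(confusion[k, ]) - tp
  fp <- sum(confusion[, k]) - tp
  tn <- sum(confusion) - tp - fn - fp
  list(tp = tp, fn = fn, fp = fp, tn = tn)
}

metric_block <- function(tp, fn, tn, fp) {
  se <- if (tp + fn > 0) tp / (tp + fn) * 100 else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) * 100 else NA_real_
  ac <- (tp + tn) / (tp + fn + tn + fp) * 100
  # F1 as the harmonic mean of accuracy and sensitivity (the variant
  # reported by this pipeline); the precision/recall form is separate.
  f1p <- if (!is.na(se) && (ac + se) > 0) 2 * ac * se / (ac + se) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) * 100 else NA_real_
  f1c <- if (!is.na(prec) && !is.na(se) && (prec + se) > 0) {
    2 * prec * se / (prec + se)
  } else NA_real_
  c(SE = se, SP = sp, AC = ac, F1_paper = f1p,
    precision = prec, F1_conventional = f1c)
}

#' Evaluation metrics from a confusion matrix
#'
#' One-vs-rest per class: sensitivity `SE = TP/(TP+FN)`, specificity
#' `SP = TN/(TN+FP)`, accuracy `AC = (TP+TN)/(TP+FN+TN+FP)`, and two F1
#' variants — `F1_paper = 2*AC*SE/(AC+SE)` (the harmonic mean of accuracy
#' and sensitivity, the form this pipeline reports) and
#' `F1_conventional = 2*precision*SE/(precision+SE)`. All in percent.
#' Metrics with degenerate denominators are `NA` and excluded from the
#' macro average with a warning.
#'
#' @param confusion K x K confusion matrix (rows = truth).
#' @param averaging `"macro"` (unweighted mean over classes, default),
#'   `"per_class"`, or `"micro"` (pooled one-vs-rest counts).
#' @return For `"per_class"` a matrix (classes x metrics); otherwise a
#'   named numeric vector.
#' @export
metrics_from_confusion <- function(confusion,
                                   averaging = c("macro", "per_class", "micro")) {
  averaging <- match.arg(averaging)
  K <- nrow(confusion)
  per <- t(vapply(seq_len(K), function(k) {
    cts <- one_vs_rest_counts(confusion, k)
    metric_block(cts$tp, cts$fn, cts$tn, cts$fp)
  }, numeric(6)))
  rownames(per) <- rownames(confusion)
  if (averaging == "per_class") return(per)
  if (averaging == "micro") {
    agg <- Reduce(function(a, b) Map(`+`, a, b),
                  lapply(seq_len(K), function(k) one_vs_rest_counts(confusion, k)))
    return(metric_block(agg$tp, agg$fn, agg$tn, agg$fp))
  }
  if (anyNA(per)) warning("undefined per-class metric(s) excluded from macro average")
  colMeans(per, na.rm = TRUE)
}

#' Student-t confidence interval of fold accuracies
#'
#' Mean of the fold scores (proportions in `[0, 1]`) with a two-sided
#' Student-t interval, reported in percent and clipped to `[0, 100]`.
#'
#' @param fold_scores Numeric vector of per-fold accuracies (length >= 2).
#' @param level Confidence level.
#' @return Named vector `(low, high)` in percent.
#' @export
confidence_interval <- function(fold_scores, level = 0.95) {
  k <- length(fold_scores)
  if (k < 2) stop("need at least 2 fold scores")
  m <- mean(fold_scores) * 100
  s <- sd(fold_scores) * 100
  half <- qt(1 - (1 - level) / 2, df = k - 1) * s / sqrt(k)
  c(low = max(0, m - half), high = min(100, m + half))
}

#' Stratified k-fold cross-validated evaluation
#'
#' Folds are stratified by class and fixed by the seed. Each fold trains
#' on the remainder (standardisation refit per fold inside
#' [train_and_predict]) and predicts the held-out rows; the confusion
#' matrix is pooled across folds.
#'
#' @param features A `feature_matrix`, or numeric matrix with `labels`.
#' @param labels Class labels (ignored for a `feature_matrix`).
#' @param spec A [model_spec].
#' @param k Number of folds (the standard protocol uses 10).
#' @param seed Seed fixing the fold assignment.
#' @return Object of class `eval_report`: `confusion`, `metrics_macro`,
#'   `metrics_micro`, `per_class`, `fold_scores`, `ci95`, `accuracy`
#'   (pooled, percent).
#' @export
kfold_cv <- function(features, labels = NULL, spec = model_spec("rf"),
                     k = 10, seed = 0L) {
  if (inherits(features, "feature_matrix")) {
    labels <- features$labels
    x <- features$x
  } else {
    x <- as.matrix(features)
  }
  labels <- as.character(labels)
  folds <- stratified_folds(labels, k, seed)
  lev <- sort(unique(labels))
  pooled <- matrix(0L, length(lev), length(lev),
                   dimnames = list(truth = lev, predicted = lev))
  fold_scores <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    pred <- train_and_predict(spec, x[tr, , drop = FALSE], labels[tr],
                              x[!tr, , drop = FALSE])
    cm <- confusion_matrix(labels[!tr], pred, levels = lev)
    pooled <- pooled + cm
    fold_scores[f] <- sum(diag(cm)) / sum(cm)
  }
  structure(list(confusion = pooled,
                 metrics_macro = metrics_from_confusion(pooled, "macro"),
                 metrics_micro = metrics_from_confusion(pooled, "micro"),
                 per_class = metrics_from_confusion(pooled, "per_class"),
                 fold_scores = fold_scores,
                 ci95 = confidence_interval(fold_scores),
                 accuracy = sum(diag(pooled)) / sum(pooled) * 100,
                 spec = spec, k = k, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, %d-fold CV: accuracy %.2f%% (95%% CI %.2f-%.2f)\n",
              x$spec$kind, x$k, x$accuracy, x$ci95["low"], x$ci95["high"]))
  m <- x$metrics_macro
  cat(sprintf("  macro: SE %.2f  SP %.2f  AC %.2f  F1 %.2f\n",
              m["SE"], m["SP"], m["AC"], m["F1_paper"]))
  invisible(x)
}

#' Serialise an evaluation report
#'
#' Metrics and fold scores to JSON (percent, full precision); the pooled
#' confusion matrix additionally to `<path>_confusion.csv`.
#'
#' @param report An `eval_report`.
#' @param path JSON path.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(
    list(classifier = report$spec$kind,
         k = report$k,
         accuracy = report$accuracy,
         ci95 = as.list(report$ci95),
         metrics_macro = as.list(round(report$metrics_macro, 2)),
         metrics_micro = as.list(round(report$metrics_micro, 2)),
         fold_scores = report$fold_scores),
    path, auto_unbox = TRUE, digits = NA)
  write.csv(report$confusion, sub("\\.json$", "_confusion.csv", path))
  invisible(path)
}
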