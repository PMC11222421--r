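#' Confusion-matrix classification metrics
#'
#' Builds the true-by-predicted confusion matrix over `class_names` and
#' derives per-class precision, sensitivity (recall) and specificity,
#' overall accuracy, the non-error rate (mean of per-class sensitivities —
#' robust to class imbalance) and the Matthews correlation coefficient
#' (2x2 formula for binary problems; the generalised multi-category form
#' otherwise). Undefined ratios (e.g. precision of a never-predicted class,
#' sensitivity of a class absent from the truth) are reported as `NA`, never
#' silently as 0; the non-error rate averages over the defined
#' sensitivities.
#'
#' @param truth,predicted character vectors of equal length with values
#'   from `class_names`.
#' @param class_names ordered class set.
#' @return A `confusion_metrics` list: `confusion`, `precision`,
#'   `sensitivity`, `specificity` (named per class), `accuracy`,
#'   `non_error_rate`, `mcc`, `n`.
#' @export
confusion_metrics <- function(truth, predicted, class_names) {
  if (!length(truth)) stop("empty input")
  stopifnot(length(truth) == length(predicted))
  if (!all(c(truth, predicted) %in% class_names))
    stop("labels outside `class_names`")
  tf <- factor(truth, levels = class_names)
  pf <- factor(predicted, levels = class_names)
  cm <- table(truth = tf, predicted = pf)
  n <- sum(cm)
  tp <- diag(cm)
  row_tot <- rowSums(cm)   # per true class
  col_tot <- colSums(cm)   # per predicted class
  sens <- ifelse(row_tot > 0, tp / row_tot, NA_real_)
  prec <- ifelse(col_tot > 0, tp / col_tot, NA_real_)
  tn <- n - row_tot - col_tot + tp
  spec <- ifelse(n - row_tot > 0, tn / (n - row_tot), NA_real_)
  acc <- sum(tp) / n
  ner <- mean(sens, na.rm = TRUE)
  # generalised (multi-category) MCC; reduces to the 2x2 formula for K = 2
  s <- n; c_ <- sum(tp)
  num <- c_ * s - sum(row_tot * col_tot)
  den <- sqrt(s^2 - sum(col_tot^2)) * sqrt(s^2 - sum(row_tot^2))
  mcc <- if (den == 0) NA_real_ else num / den
  structure(
    list(confusion = unclass(cm), precision = prec, sensitivity = sens,
         specificity = spec, accuracy = acc, non_error_rate = ner,
         mcc = mcc, n = n),
    class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat("<confusion_metrics> n = ", x$n,
      ", accuracy ", format(x$accuracy, digits = 4),
      ", NER ", format(x$non_error_rate, digits = 4),
      ", MCC ", format(x$mcc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Receiver operating characteristic curve
#'
#' Threshold sweep over the unique scores, descending; tied scores enter
#' simultaneously. The curve runs from (0, 0) to (1, 1) and the AUC is its
#' trapezoidal area, which equals the Mann-Whitney U statistic divided by
#' `n_pos * n_neg` (with midrank tie handling).
#'
#' @param truth vector of class labels containing exactly two classes among
#'   scored molecules.
#' @param scores numeric scores, higher meaning more likely positive.
#' @param positive_class label counted as positive.
#' @return A `roc_curve` list: `thresholds`, `fpr`, `tpr`, `auc`.
#' @export
roc_curve <- function(truth, scores, positive_class) {
  pos <- truth == positive_class
  if (!any(pos) || all(pos))
    stop("ROC needs at least one positive and one negative")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  # group tied scores
  grp <- cumsum(!duplicated(s))
  tp <- tapply(p, grp, sum)
  fp <- tapply(!p, grp, sum)
  tpr <- c(0, cumsum(tp)) / sum(pos)
  fpr <- c(0, cumsum(fp)) / sum(!pos)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(thresholds = c(Inf, unique(s)), fpr = as.numeric(fpr),
         tpr = as.numeric(tpr), auc = auc),
    class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> AUC ", format(x$auc, digits = 4), " (",
      length(x$thresholds), " thresholds)\n", sep = "")
  invisible(x)
}

#' Venetian-blinds fold assignment
#'
#' Interleaved folds: the molecule at position `i` of the (stored) table
#' order lands in fold `((i - 1) mod k) + 1`. Fold sizes differ by at most
#' one.
#'
#' @param n number of molecules.
#' @param k number of folds, `2 <= k <= n`.
#' @return integer vector of fold labels in `1..k`.
#' @export
venetian_blinds_folds <- function(n, k) {
  if (k > n) stop("more folds than molecules")
  if (k < 2) stop("need at least 2 folds")
  ((seq_len(n) - 1L) %% as.integer(k)) + 1L
}

#' Venetian-blinds cross-validation
#'
#' Interleaved k-fold CV: the training table is (by default) pre-shuffled
#' with the given seed to decouple the interleaving from the stored row
#' order, folds are assigned by position modulo `k`, and a fresh classifier
#' is trained on each fold complement and evaluated on the held-out fold.
#' Per-fold and pooled confusion metrics are reported (the pooled confusion
#' is the sum of the fold confusions).
#'
#' @param train labelled, scaled [descriptor_table()].
#' @param trainer a [classifier_spec()].
#' @param k number of folds (default 10).
#' @param seed integer seed (pre-shuffle and per-fold training).
#' @param pre_shuffle shuffle rows before interleaving (default `TRUE`).
#' @return A `cv_result`: list with `n_folds`, `fold_assignment` (in the
#'   input table's row order), `per_fold` (list of `confusion_metrics`),
#'   `pooled` (`confusion_metrics`), `truth`, `predicted`, `scores`.
#' @export
cross_validate <- function(train, trainer, k = 10, seed = 1,
                           pre_shuffle = TRUE) {
  n <- n_molecules(train)
  perm <- if (pre_shuffle)
    withr::with_seed(seed, sample.int(n)) else seq_len(n)
  folds_perm <- venetian_blinds_folds(n, k)
  folds <- integer(n)
  folds[perm] <- folds_perm
  classes <- train$class_names
  predicted <- character(n)
  scores <- matrix(NA_real_, n, length(classes),
                   dimnames = list(NULL, classes))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    va <- which(folds == f)
    tr <- subset_molecules(train, which(folds != f))
    model <- fit_classifier(trainer, tr, seed = (seed %% 1000003L) * 100L + f)
    pr <- stats::predict(model, subset_molecules(train, va))
    predicted[va] <- pr$predicted_class
    scores[va, ] <- pr$scores
    per_fold[[f]] <- confusion_metrics(train$labels[va], pr$predicted_class,
                                       classes)
  }
  structure(
    list(n_folds = k, fold_assignment = folds, per_fold = per_fold,
         pooled = confusion_metrics(train$labels, predicted, classes),
         truth = train$labels, predicted = predicted, scores = scores),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$n_folds, "-fold; pooled accuracy ",
      format(x$pooled$accuracy, digits = 4), ", NER ",
      format(x$pooled$non_error_rate, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Map-size / epoch selection by cross-validation
#'
#' Exhaustive evaluation of a (side, epochs) grid by venetian-blinds CV
#' non-error rate; ties prefer the smaller side, then fewer epochs.
#'
#' @param train labelled, scaled [descriptor_table()].
#' @param trainer a [classifier_spec()] whose `side`/`epochs` are overridden
#'   by the grid.
#' @param sides,epochs candidate values (defaults `5:12` and
#'   `c(50, 100, 200)`).
#' @param k CV folds.
#' @param seed integer seed.
#' @return list with `side`, `epochs`, `cv` (the winning `cv_result`) and
#'   `grid` (data frame of all candidates with their NER).
#' @export
select_hyperparameters <- function(train, trainer, sides = 5:12,
                                   epochs = c(50, 100, 200), k = 10,
                                   seed = 1) {
  if (!length(sides) || !length(epochs)) stop("empty hyperparameter grid")
  grid <- expand.grid(side = sides, epochs = epochs)
  results <- vector("list", nrow(grid))
  ner <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tr <- trainer
    tr$side <- grid$side[i]; tr$epochs <- grid$epochs[i]
    results[[i]] <- cross_validate(train, tr, k = k, seed = seed)
    ner[i] <- results[[i]]$pooled$non_error_rate
  }
  best <- order(-ner, grid$side, grid$epochs)[1]
  list(side = grid$side[best], epochs = grid$epochs[best],
       cv = results[[best]],
       grid = cbind(grid, non_error_rate = ner))
}

#' y-randomization (label permutation) test
#'
#' Re-runs the modelling protocol on label-permuted copies of the data:
#' each iteration shuffles the class labels, re-splits into
#' training and test sets, trains a classifier with the same
#' hyperparameters as the real model, and records training, cross-validated
#' and test error rates (and test AUC for binary problems). A sound model
#' should collapse to chance under permutation.
#'
#' @param table labelled, scaled [descriptor_table()] (the full dataset).
#' @param trainer a [classifier_spec()].
#' @param n_iterations number of permutations (the reference protocol uses
#'   100).
#' @param seed master seed; iteration i uses an independent derived stream.
#' @param train_fraction passed to [split_train_test()].
#' @param k CV folds within each iteration; `0` skips the CV column.
#' @return A `yrand_result`: list with `n_iterations`, `train_error`,
#'   `cv_error`, `test_error`, `auc` (per-iteration vectors),
#'   `mean_error_rates` (named triple), `mean_auc`.
#' @export
y_randomization <- function(table, trainer, n_iterations = 100, seed = 1,
                            train_fraction = 0.7, k = 10) {
  stopifnot(n_iterations >= 1)
  classes <- table$class_names
  binary <- length(classes) == 2
  train_err <- cv_err <- test_err <- auc <- rep(NA_real_, n_iterations)
  for (i in seq_len(n_iterations)) {
    it_seed <- (seed %% 1000003L) * 1000L + i
    shuffled <- descriptor_table(
      table$values, table$molecule_ids, table$descriptor_names,
      labels = withr::with_seed(it_seed, sample(table$labels)),
      class_names = classes)
    sp <- split_train_test(shuffled, train_fraction, seed = it_seed + 1L)
    model <- fit_classifier(trainer, sp$train, seed = it_seed + 2L)
    pr_tr <- stats::predict(model, sp$train)
    pr_te <- stats::predict(model, sp$test)
    train_err[i] <- 1 - confusion_metrics(sp$train$labels,
                                          pr_tr$predicted_class,
                                          classes)$accuracy
    test_err[i] <- 1 - confusion_metrics(sp$test$labels,
                                         pr_te$predicted_class,
                                         classes)$accuracy
    if (k >= 2) {
      cv <- cross_validate(sp$train, trainer, k = k, seed = it_seed + 3L)
      cv_err[i] <- 1 - cv$pooled$accuracy
    }
    if (binary && length(unique(sp$test$labels)) == 2) {
      auc[i] <- roc_curve(sp$test$labels, pr_te$scores[, classes[2]],
                          classes[2])$auc
    }
  }
  structure(
    list(n_iterations = n_iterations, train_error = train_err,
         cv_error = cv_err, test_error = test_err, auc = auc,
         mean_error_rates = c(training = mean(train_err),
                              cv = mean(cv_err),
                              test = mean(test_err)),
         mean_auc = mean(auc, na.rm = TRUE)),
    class = "yrand_result")
}

#' @export
print.yrand_result <- function(x, ...) {
  cat("<yrand_result> ", x$n_iterations, " iterations; mean error rates: ",
      paste(sprintf("%s %.3f", names(x$mean_error_rates),
                    x$mean_error_rates), collapse = ", "),
      "; mean AUC ", format(x$mean_auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write classification metrics as a CSV row set
#' @param metrics a `confusion_metrics`.
#' @param path output path.
#' @param stage label for the rows (e.g. "training", "cv", "test").
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path, stage = "test") {
  classes <- rownames(metrics$confusion)
  df <- data.frame(stage = stage, class = classes,
                   precision = metrics$precision,
                   sensitivity = metrics$sensitivity,
                   specificity = metrics$specificity,
                   accuracy = metrics$accuracy,
                   non_error_rate = metrics$non_error_rate,
                   mcc = metrics$mcc)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
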