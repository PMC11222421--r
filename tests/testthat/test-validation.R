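test_that("confusion metrics reproduce hand-computed values", {
  # TP=50, FN=5, TN=40, FP=10 with "pos" as the second class
  truth <- c(rep("pos", 55), rep("neg", 50))
  pred <- c(rep("pos", 50), rep("neg", 5), rep("neg", 40), rep("pos", 10))
  cm <- confusion_metrics(truth, pred, c("neg", "pos"))
  expect_equal(unname(cm$sensitivity["pos"]), 50 / 55)
  expect_equal(unname(cm$specificity["pos"]), 40 / 50)
  expect_equal(cm$mcc, (50 * 40 - 10 * 5) / sqrt(60 * 55 * 50 * 45))

  perfect <- confusion_metrics(truth, truth, c("neg", "pos"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)

  # constant predictor on balanced classes: NER = 0.5, undefined cells NA
  bal <- rep(c("a", "b"), 10)
  const <- confusion_metrics(bal, rep("a", 20), c("a", "b"))
  expect_equal(const$non_error_rate, 0.5)
  expect_true(is.na(const$precision["b"]))
  expect_error(confusion_metrics(character(0), character(0), "a"), "empty")
})

test_that("MCC equals the Pearson correlation of indicator vectors", {
  withr::with_seed(10, {
    for (i in 1:50) {
      n <- sample(4:200, 1)
      truth <- sample(c("x", "y"), n, replace = TRUE)
      pred <- sample(c("x", "y"), n, replace = TRUE)
      if (length(unique(truth)) < 2 || length(unique(pred)) < 2) next
      cm <- confusion_metrics(truth, pred, c("x", "y"))
      r <- suppressWarnings(cor(as.numeric(truth == "y"),
                                as.numeric(pred == "y")))
      expect_equal(cm$mcc, r, tolerance = 1e-12)
    }
  })
})

test_that("ROC handles perfect, flat and tied scores; AUC = U/(n1 n2)", {
  perfect <- roc_curve(c("n", "n", "p", "p"), c(1, 2, 3, 4), "p")
  expect_equal(perfect$auc, 1)
  flat <- roc_curve(c("n", "p", "n", "p"), rep(2, 4), "p")
  expect_equal(flat$auc, 0.5)
  expect_error(roc_curve(rep("p", 3), 1:3, "p"), "positive and")

  withr::with_seed(21, {
    for (i in 1:40) {
      n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
      scores <- c(sample(1:8, n1, TRUE) + rnorm(n1, sd = 0.01) * (i %% 2),
                  sample(1:8, n2, TRUE) + rnorm(n2, sd = 0.01) * (i %% 2))
      truth <- c(rep("pos", n1), rep("neg", n2))
      auc <- roc_curve(truth, scores, "pos")$auc
      w <- suppressWarnings(wilcox.test(scores[1:n1],
                                        scores[-(1:n1)]))$statistic
      expect_equal(auc, unname(w) / (n1 * n2), tolerance = 1e-10)
    }
  })
})

test_that("AUC matches an independent ROC implementation", {
  withr::with_seed(77, {
    for (i in 1:10) {
      n <- 60
      truth <- sample(c("p", "n"), n, replace = TRUE)
      if (length(unique(truth)) < 2) next
      scores <- round(rnorm(n), i %% 3)  # provoke ties at low precision
      mine <- roc_curve(truth, scores, "p")$auc
      ref <- suppressMessages(
        pROC::auc(pROC::roc(truth, scores, levels = c("n", "p"),
                            direction = "<")))
      expect_equal(mine, as.numeric(ref), tolerance = 1e-12)
    }
  })
})

test_that("ROC curve monotonicity and endpoints hold for random scores", {
  withr::with_seed(31, {
    for (i in 1:10) {
      n <- 50
      truth <- sample(c("p", "n"), n, replace = TRUE, prob = c(0.3, 0.7))
      if (length(unique(truth)) < 2) next
      rc <- roc_curve(truth, rnorm(n), "p")
      expect_true(all(diff(rc$fpr) >= 0))
      expect_true(all(diff(rc$tpr) >= 0))
      expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
      expect_equal(c(rev(rc$fpr)[1], rev(rc$tpr)[1]), c(1, 1))
    }
  })
})

test_that("venetian blinds interleave with near-equal fold sizes", {
  expect_equal(venetian_blinds_folds(5, 2), c(1L, 2L, 1L, 2L, 1L))
  expect_equal(venetian_blinds_folds(10, 10), 1:10)
  expect_error(venetian_blinds_folds(3, 5), "more folds")
  for (n in c(7, 23, 100)) {
    for (k in c(2, 3, min(10, n))) {
      sizes <- table(venetian_blinds_folds(n, k))
      expect_lte(max(sizes) - min(sizes), 1)
      expect_length(sizes, k)
    }
  }
})

test_that("cross-validation is deterministic and accurate on separable data", {
  tab <- scaled_copy(separable_table(n_per_class = 60, seed = 3))
  cv <- cross_validate(tab, classifier_spec("skn", side = 5, epochs = 40),
                       k = 10, seed = 4)
  expect_gte(cv$pooled$accuracy, 0.9)
  expect_equal(sum(sapply(cv$per_fold, function(m) m$n)), n_molecules(tab))
  pooled_sum <- Reduce(`+`, lapply(cv$per_fold, function(m) m$confusion))
  expect_equal(unclass(cv$pooled$confusion), unclass(pooled_sum))
  cv2 <- cross_validate(tab, classifier_spec("skn", side = 5, epochs = 40),
                        k = 10, seed = 4)
  expect_identical(cv$predicted, cv2$predicted)
})

test_that("shuffled labels drive CV accuracy to chance", {
  accs <- vapply(1:10, function(s) {
    tab <- scaled_copy(separable_table(n_per_class = 40, seed = s))
    tab$labels <- withr::with_seed(s + 500, sample(tab$labels))
    cross_validate(tab, classifier_spec("pls"), k = 5,
                   seed = s)$pooled$accuracy
  }, numeric(1))
  expect_true(all(accs > 0.3 & accs < 0.7))
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
})

test_that("hyperparameter selection prefers adequate maps, breaks ties", {
  tab <- scaled_copy(separable_table(n_per_class = 40, seed = 8))
  pick <- select_hyperparameters(tab, classifier_spec("skn"),
                                 sides = c(2, 6), epochs = 30, k = 5,
                                 seed = 2)
  expect_equal(pick$side, 6)
  single <- select_hyperparameters(tab, classifier_spec("skn"),
                                   sides = 5, epochs = 40, k = 5, seed = 2)
  expect_equal(single$side, 5)
  expect_equal(single$epochs, 40)
  pick2 <- select_hyperparameters(tab, classifier_spec("skn"),
                                  sides = c(2, 6), epochs = 30, k = 5,
                                  seed = 2)
  expect_equal(pick$side, pick2$side)
  expect_error(select_hyperparameters(tab, classifier_spec("skn"),
                                      sides = integer(0), epochs = 30),
               "empty")
})

test_that("y-randomization collapses performance to chance levels", {
  tab <- scaled_copy(separable_table(n_per_class = 50, seed = 12))
  yr <- y_randomization(tab, classifier_spec("pls"), n_iterations = 10,
                        seed = 3, k = 5)
  expect_length(yr$test_error, 10)
  expect_true(all(yr$test_error >= 0 & yr$test_error <= 1))
  expect_gte(yr$mean_error_rates[["test"]], 0.3)
  # the real model beats every randomized AUC comfortably
  sp <- split_train_test(tab, 0.7, seed = 5)
  real <- somsar:::fit_classifier(classifier_spec("pls"), sp$train, seed = 1)
  pr <- predict(real, sp$test)
  real_auc <- roc_curve(sp$test$labels, pr$scores[, "inactive"],
                        "inactive")$auc
  expect_gt(real_auc, yr$mean_auc)
  yr2 <- y_randomization(tab, classifier_spec("pls"), n_iterations = 2,
                         seed = 3, k = 0)
  yr3 <- y_randomization(tab, classifier_spec("pls"), n_iterations = 2,
                         seed = 3, k = 0)
  expect_identical(yr2$test_error, yr3$test_error)
})
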