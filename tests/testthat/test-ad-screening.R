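test_that("leverage reproduces hand values and the trace identity", {
  # training X = column (1, -1): each training h = 0.5, sum = p = 1
  X <- matrix(c(1, -1), 2, 1, dimnames = list(NULL, "d1"))
  rep_ <- leverage(X)
  expect_equal(rep_$h_values, c(0.5, 0.5))
  expect_equal(sum(rep_$h_values), 1)
  # p = 1, n = 6 -> h* = 1
  X6 <- matrix(rnorm(6), 6, 1, dimnames = list(NULL, "d1"))
  expect_equal(leverage(X6)$h_star, 1)
  # query at the centroid of centred data has leverage 0
  Xc <- scale(matrix(rnorm(20), 10, 2), scale = FALSE)
  colnames(Xc) <- c("a", "b")
  q <- matrix(0, 1, 2, dimnames = list(NULL, c("a", "b")))
  lr <- leverage(Xc, q)
  expect_lt(lr$h_values, 1e-20)
  expect_true(lr$inside_domain)

  expect_error(leverage(matrix(numeric(0), 0, 1)), "empty")
  expect_error(leverage(Xc, matrix(0, 1, 3)), "differ")
})

test_that("training leverages sum to the rank of X", {
  withr::with_seed(13, {
    for (i in 1:20) {
      n <- sample(20:200, 1); p <- sample(2:30, 1)
      X <- matrix(rnorm(n * p), n, p)
      rep_ <- leverage(X)
      expect_equal(sum(rep_$h_values), qr(X)$rank, tolerance = 1e-8)
      # oracle: explicit hat-matrix diagonal
      H <- diag(X %*% solve(crossprod(X)) %*% t(X))
      expect_equal(rep_$h_values, unname(H), tolerance = 1e-8)
    }
  })
})

test_that("rank-deficient training matrices fall back to a pseudo-inverse", {
  X <- withr::with_seed(2, matrix(rnorm(20), 10, 2))
  X <- cbind(X, X[, 1])  # exact collinearity
  expect_warning(rep_ <- leverage(X), "pseudo-inverse")
  expect_equal(sum(rep_$h_values), qr(X)$rank, tolerance = 1e-6)
})

test_that("enrichment factors count the top bin per the definition", {
  # top 10% of 100 molecules holds all 5 actives -> EF = 10
  ranked <- c(rep(TRUE, 5), rep(FALSE, 95))
  expect_equal(enrichment_factor(ranked, 0.10), 10)
  expect_equal(enrichment_factor(ranked, 1.0), 1)
  none_on_top <- c(rep(FALSE, 95), rep(TRUE, 5))
  expect_equal(enrichment_factor(none_on_top, 0.10), 0)
  expect_error(enrichment_factor(rep(FALSE, 10), 0.1), "no actives")

  # antitone in the fraction for a perfect ranking until exhaustion
  perf <- c(rep(TRUE, 5), rep(FALSE, 995))
  fr <- c(0.005, 0.01, 0.05, 0.2, 1)
  efs <- sapply(fr, function(f) enrichment_factor(perf, f))
  expect_true(all(diff(efs) <= 1e-12))
})

test_that("EF under random ranking concentrates at 1", {
  efs <- vapply(1:200, function(s) {
    ranked <- withr::with_seed(s, sample(c(rep(TRUE, 30), rep(FALSE, 470))))
    enrichment_factor(ranked, 0.10)
  }, numeric(1))
  se <- sd(efs) / sqrt(length(efs))
  expect_lt(abs(mean(efs) - 1), 3 * se + 0.05)
})

test_that("spike-in screening ranks actives first for a separable model", {
  tab <- separable_table(n_per_class = 100, seed = 30)
  scaler <- fit_scaler(tab)
  scaled <- apply_scaler(tab, scaler)
  model <- train_skn(scaled, side = 6,
                     schedule = training_schedule(epochs = 60, seed = 1))
  # background from the inactive side, actives from the active side
  bg_raw <- separable_table(n_per_class = 300, seed = 31)
  bg <- apply_scaler(somsar:::subset_molecules(
    bg_raw, which(bg_raw$labels == "inactive")), scaler)
  bg <- descriptor_table(bg$values, paste0("BG", seq_len(nrow(bg$values))),
                         bg$descriptor_names)
  act_raw <- separable_table(n_per_class = 20, seed = 32)
  act <- apply_scaler(somsar:::subset_molecules(
    act_raw, which(act_raw$labels == "active")), scaler)
  act <- descriptor_table(act$values, paste0("ACT", seq_len(nrow(act$values))),
                          act$descriptor_names)
  res <- spike_in_screen(bg, act, model, "active")
  expect_gt(res$ef_10pct, 4)
  expect_gt(res$roc$auc, 0.95)
  expect_equal(res$n_spiked, 20)
  expect_error(spike_in_screen(bg, act[0], model, "active"))
})

test_that("screening tie-breaks put background ahead of spiked actives", {
  flat_model <- structure(
    list(kohonen = structure(list(side = 2, weights = matrix(0, 4, 1),
                                  feature_names = "d1"),
                             class = "som_grid"),
         grossberg = matrix(c(rep(0.7, 4), rep(0.3, 4)), 4, 2),
         class_names = c("active", "inactive"),
         schedule = training_schedule(seed = 1),
         descriptor_names = "d1", scaler_ref = NULL),
    class = c("cpann_model", "som_classifier"))
  bg <- descriptor_table(matrix(0, 100, 1),
                         sprintf("BG%03d", 1:100), "d1")
  act <- descriptor_table(matrix(0, 5, 1), sprintf("ACT%d", 1:5), "d1")
  res <- spike_in_screen(bg, act, flat_model, "active")
  # every score ties; all background must precede all actives
  expect_true(all(which(res$is_active) > 100))
  expect_equal(res$ef_1pct, 0)
})
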