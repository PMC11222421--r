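test_that("generated tables honour their generator specification and determinism", {
  spec <- synthetic_spec(c("a", "b", "c"), c(30, 20, 10),
                         n_informative = 6, n_noise = 4,
                         n_collinear_blocks = 2, block_size = 3, seed = 77)
  tab <- generate_descriptor_table(spec)
  expect_s3_class(tab, "descriptor_table")
  expect_equal(n_molecules(tab), 60)
  expect_equal(n_descriptors(tab), 6 + 4 + 2 * 3)
  expect_equal(unname(table(tab$labels)[c("a", "b", "c")]),
               c(30L, 20L, 10L), ignore_attr = TRUE)
  tab2 <- generate_descriptor_table(spec)
  expect_identical(tab$values, tab2$values)
  spec2 <- spec; spec2$seed <- 78L
  expect_false(identical(generate_descriptor_table(spec2)$values,
                         tab$values))
})

test_that("class-conditional means recover the requested separation", {
  spec <- synthetic_spec(c("a", "b"), c(400, 400), n_informative = 5,
                         n_noise = 0, n_collinear_blocks = 0,
                         class_mean_shift = 3, seed = 5)
  tab <- generate_descriptor_table(spec)
  mu_a <- colMeans(tab$values[tab$labels == "a", 1:5])
  mu_b <- colMeans(tab$values[tab$labels == "b", 1:5])
  # pairwise separation: ||mu_a - mu_b|| ~ 3 within sampling error
  expect_equal(sqrt(sum((mu_a - mu_b)^2)), 3, tolerance = 0.15)
  # each class mean sits at distance shift/sqrt(2) from the origin
  expect_equal(sqrt(sum(mu_a^2)), 3 / sqrt(2), tolerance = 0.15)
  expect_equal(sqrt(sum(mu_b^2)), 3 / sqrt(2), tolerance = 0.15)

  pd <- synthetic_spec(c("a", "b"), c(400, 400), n_informative = 4,
                       n_noise = 0, n_collinear_blocks = 0,
                       class_mean_shift = 1.5,
                       shift_mode = "per-descriptor", seed = 6)
  tpd <- generate_descriptor_table(pd)
  dmu <- colMeans(tpd$values[tpd$labels == "b", ]) -
    colMeans(tpd$values[tpd$labels == "a", ])
  expect_true(all(abs(dmu - 1.5) < 3 / sqrt(400) * 3))
})

test_that("collinear blocks exceed the filter threshold and are pruned", {
  spec <- synthetic_spec(c("a", "b"), c(100, 100), n_informative = 4,
                         n_noise = 4, n_collinear_blocks = 2,
                         block_size = 3, block_correlation = 0.95,
                         seed = 21)
  tab <- generate_descriptor_table(spec)
  for (b in 1:2) {
    block <- tab$values[, sprintf("cor%d_%d", b, 1:3)]
    C <- cor(block)
    expect_true(all(C[upper.tri(C)] >= 0.93))
  }
  res <- correlation_filter(drop_zero_variance(tab)$table, 0.9)
  expect_length(res$report$removed_correlated, 2 * (3 - 1))
})

test_that("zero shift yields chance-level classification", {
  spec <- synthetic_spec(c("a", "b"), c(60, 60), class_mean_shift = 0,
                         n_collinear_blocks = 0, seed = 31)
  tab <- scaled_copy(generate_descriptor_table(spec))
  cv <- cross_validate(tab, classifier_spec("pls"), k = 5, seed = 1)
  expect_gt(cv$pooled$accuracy, 0.3)
  expect_lt(cv$pooled$accuracy, 0.7)
})

test_that("accuracy increases with class separation", {
  med_acc <- vapply(c(0, 1, 2, 4), function(shift) {
    accs <- vapply(1:5, function(s) {
      spec <- synthetic_spec(c("a", "b"), c(50, 50),
                             class_mean_shift = shift,
                             n_collinear_blocks = 0, seed = s)
      tab <- scaled_copy(generate_descriptor_table(spec))
      cv <- cross_validate(tab,
                           classifier_spec("skn", side = 5, epochs = 40),
                           k = 5, seed = s)
      cv$pooled$accuracy
    }, numeric(1))
    median(accs)
  }, numeric(1))
  expect_true(all(diff(med_acc) >= -0.02))  # monotone up to noise
  expect_gt(med_acc[4], med_acc[1] + 0.2)
})

test_that("screening pairs share the training distribution geometry", {
  spec <- synthetic_preset("two-class", seed = 3)
  pair <- generate_screening_pair(spec, n_background = 200, n_actives = 30)
  expect_equal(n_molecules(pair$background), 200)
  expect_equal(n_molecules(pair$actives), 30)
  expect_identical(pair$background$descriptor_names,
                   pair$actives$descriptor_names)
  expect_length(intersect(pair$background$molecule_ids,
                          pair$actives$molecule_ids), 0)
  pair2 <- generate_screening_pair(spec, n_background = 200, n_actives = 30)
  expect_identical(pair$background$values, pair2$background$values)

  # actives sit near the training active-class centroid, background does not
  train <- generate_descriptor_table(spec)
  mu_act <- colMeans(train$values[train$labels == "active", ])
  mu_bg <- colMeans(train$values[train$labels == "inactive", ])
  d_act <- sqrt(sum((colMeans(pair$actives$values) - mu_act)^2))
  d_x <- sqrt(sum((colMeans(pair$background$values) - mu_act)^2))
  expect_lt(d_act, d_x)
  # fully active-like background is centred like the actives
  pair_null <- generate_screening_pair(spec, n_background = 200,
                                       n_actives = 30,
                                       active_like_fraction = 1)
  d_null <- sqrt(sum((colMeans(pair_null$background$values) - mu_act)^2))
  expect_lt(d_null, 1)
})
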