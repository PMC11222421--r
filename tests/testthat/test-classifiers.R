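sep_scaled <- scaled_copy(separable_table(n_per_class = 100, seed = 42))
sched60 <- function(seed) training_schedule(epochs = 60, seed = seed)

test_that("CPANN learns separable classes and is seed-deterministic", {
  m <- train_cpann(sep_scaled, side = 8,
                   schedule = training_schedule(epochs = 100, seed = 1))
  acc <- mean(predict(m, sep_scaled)$predicted_class == sep_scaled$labels)
  expect_gte(acc, 0.95)
  m2 <- train_cpann(sep_scaled, side = 8,
                    schedule = training_schedule(epochs = 100, seed = 1))
  expect_identical(m$kohonen$weights, m2$kohonen$weights)
  expect_identical(m$grossberg, m2$grossberg)
  m3 <- train_cpann(sep_scaled, side = 8,
                    schedule = training_schedule(epochs = 100, seed = 2))
  expect_false(identical(m$kohonen$weights, m3$kohonen$weights))

  single <- descriptor_table(matrix(rnorm(10), 5, 2), paste0("m", 1:5),
                             c("a", "b"), labels = rep("only", 5))
  expect_error(train_cpann(single, 4, sched60(1)), "single class")
})

test_that("Grossberg weights stay within [0, 1] under one-hot training", {
  m <- train_cpann(sep_scaled, side = 5,
                   schedule = training_schedule(epochs = 40, seed = 9))
  expect_gte(min(m$grossberg), 0)
  expect_lte(max(m$grossberg), 1)
  # per-neuron memberships track the two-class split: rows sum near 1
  # wherever the neuron has been pulled towards data
  expect_true(all(rowSums(m$grossberg) <= 2))
})

test_that("SKN learns separable classes; zero class weight is unsupervised", {
  m <- train_skn(sep_scaled, side = 6, schedule = sched60(1))
  acc <- mean(predict(m, sep_scaled)$predicted_class == sep_scaled$labels)
  expect_gte(acc, 0.95)
  m2 <- train_skn(sep_scaled, side = 6, schedule = sched60(1))
  expect_identical(m$xy_grid$weights, m2$xy_grid$weights)

  # class_weight 0: the X-part of the fused map must match a map trained
  # with an uninformative constant class block (BMU ignores the Y block)
  m0 <- train_skn(sep_scaled, side = 4, schedule = sched60(3),
                  class_weight = 0)
  flat <- sep_scaled
  flat$labels <- rep(c("active", "inactive"),
                     length.out = n_molecules(flat))
  m0b <- train_skn(flat, side = 4, schedule = sched60(3), class_weight = 0)
  p <- n_descriptors(sep_scaled)
  expect_equal(m0$xy_grid$weights[, 1:p], m0b$xy_grid$weights[, 1:p],
               tolerance = 1e-12)
})

test_that("prediction follows the argmax contract and ignores row order", {
  m <- train_skn(sep_scaled, side = 6, schedule = sched60(4))
  pr <- predict(m, sep_scaled)
  expect_identical(pr$predicted_class,
                   m$class_names[apply(pr$scores, 1, which.max)])
  expect_true(all(pr$scores >= 0 & pr$scores <= 1))
  # permutation invariance
  perm <- withr::with_seed(5, sample(n_molecules(sep_scaled)))
  shuffled <- somsar:::subset_molecules(sep_scaled, perm)
  pr2 <- predict(m, shuffled)
  expect_identical(pr2$predicted_class, pr$predicted_class[perm])
  expect_identical(pr2$scores, pr$scores[perm, ])
})

test_that("ties in membership resolve to the earlier class", {
  model <- structure(
    list(kohonen = structure(list(side = 2,
                                  weights = matrix(0, 4, 1),
                                  feature_names = "d1"),
                             class = "som_grid"),
         grossberg = matrix(0.5, 4, 2),
         class_names = c("first", "second"),
         schedule = training_schedule(seed = 1),
         descriptor_names = "d1", scaler_ref = NULL),
    class = c("cpann_model", "som_classifier"))
  tab <- descriptor_table(matrix(0, 1, 1), "m1", "d1")
  expect_identical(predict(model, tab)$predicted_class, "first")
})

test_that("top maps group same-class molecules into coherent regions", {
  m <- train_skn(sep_scaled, side = 6, schedule = sched60(6))
  tm <- top_map(m, sep_scaled)
  expect_equal(sum(tm$counts), n_molecules(sep_scaled))
  occupied <- which(tm$counts > 0)
  # majority-class regions: most occupied neurons have a same-class
  # toroidal neighbour (contiguity on the torus)
  side <- tm$side
  coherent <- vapply(occupied, function(k) {
    pos <- somsar:::neuron_coords(k, side)
    neigh <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r <- (pos[1, "row"] + dr) %% side; c_ <- (pos[1, "col"] + dc) %% side
      neigh <- c(neigh, tm$majority_class[somsar:::coords_neuron(r, c_, side)])
    }
    tm$majority_class[k] %in% neigh
  }, logical(1))
  expect_gte(mean(coherent), 0.9)

  # single molecule occupies exactly one neuron
  one <- somsar:::subset_molecules(sep_scaled, 1)
  expect_equal(sum(top_map(m, one)$counts > 0), 1)
})

test_that("model serialisation round-trips to bit-identical predictions", {
  for (maker in list(
    function() train_cpann(sep_scaled, 5,
                           training_schedule(epochs = 30, seed = 8)),
    function() train_skn(sep_scaled, 5,
                         training_schedule(epochs = 30, seed = 8)))) {
    m <- maker()
    path <- withr::local_tempfile(fileext = ".json")
    save_model(m, path)
    m2 <- load_model(path)
    p1 <- predict(m, sep_scaled); p2 <- predict(m2, sep_scaled)
    expect_identical(p1$scores, p2$scores)
    expect_identical(p1$predicted_class, p2$predicted_class)
  }
})

test_that("both SOM classifiers clearly beat the majority-class baseline", {
  ok <- vapply(1:10, function(s) {
    tab <- scaled_copy(separable_table(n_per_class = 50, seed = s))
    base <- max(table(tab$labels)) / n_molecules(tab)
    sch <- training_schedule(epochs = 40, seed = s)
    acc_c <- mean(predict(train_cpann(tab, 5, sch), tab)$predicted_class ==
                    tab$labels)
    acc_s <- mean(predict(train_skn(tab, 5, sch), tab)$predicted_class ==
                    tab$labels)
    (acc_c - base >= 0.3) && (acc_s - base >= 0.3)
  }, logical(1))
  expect_true(all(ok))
})
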