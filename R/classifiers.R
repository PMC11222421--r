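#' Train a counter-propagation neural network (CPANN)
#'
#' Two coupled square toroidal layers: a competitive Kohonen layer holding
#' descriptor weights and a Grossberg output layer holding one class-
#' membership weight per class. Each presented molecule selects its best
#' matching unit on the Kohonen layer only; both layers are then updated with
#' the same `eta * a` factor — the Kohonen weights towards the descriptor
#' vector and the Grossberg weights towards the one-hot class vector. With
#' one-hot targets and `eta * a` in `[0, 1]` the Grossberg weights remain in
#' `[0, 1]` throughout training.
#'
#' @param train scaled, labelled [descriptor_table()].
#' @param side map side length (the map has `side^2` neurons).
#' @param schedule a [training_schedule()]; its seed makes training
#'   deterministic.
#' @param scaler optional `scaling_model` stored for later query projection.
#' @return A `cpann_model`.
#' @export
train_cpann <- function(train, side = 8, schedule = training_schedule(),
                        scaler = NULL) {
  check_trainable(train)
  classes <- train$class_names
  X <- train$values
  Y <- one_hot(train$labels, classes)
  p <- ncol(X); K <- length(classes)
  grid <- withr::with_seed(schedule$seed,
    som_grid(side, p + K, data = cbind(X, Y),
             feature_names = c(train$descriptor_names, classes)))
  W <- run_som_training(grid$weights, X, cbind(X, Y), schedule, side,
                        bmu_feature_weights = rep(1, p))
  structure(
    list(kohonen = structure(list(side = grid$side,
                                  weights = W[, 1:p, drop = FALSE],
                                  feature_names = train$descriptor_names),
                             class = "som_grid"),
         grossberg = W[, p + seq_len(K), drop = FALSE],
         class_names = classes, schedule = schedule,
         descriptor_names = train$descriptor_names, scaler_ref = scaler),
    class = c("cpann_model", "som_classifier"))
}

#' Train a supervised Kohonen network (SKN)
#'
#' A single toroidal map whose neurons carry fused weight vectors over the
#' concatenated descriptor block and class block (the XY map). During
#' training the best matching unit is sought on the concatenation
#' `[x, class_weight * y]`; the whole fused vector is then updated by the
#' Kohonen rule. Prediction uses the descriptor block only and reads class
#' memberships off the class block.
#'
#' @inheritParams train_cpann
#' @param class_weight multiplier on the class block inside the training
#'   BMU distance; `0` reduces training to an unsupervised map on the
#'   descriptors alone. Default 1 (equal weighting).
#' @return An `skn_model`.
#' @export
train_skn <- function(train, side = 8, schedule = training_schedule(),
                      class_weight = 1, scaler = NULL) {
  check_trainable(train)
  stopifnot(class_weight >= 0)
  classes <- train$class_names
  X <- train$values
  Y <- one_hot(train$labels, classes)
  p <- ncol(X); K <- length(classes)
  grid <- withr::with_seed(schedule$seed,
    som_grid(side, p + K, data = cbind(X, Y),
             feature_names = c(train$descriptor_names, classes)))
  W <- run_som_training(grid$weights, cbind(X, Y), cbind(X, Y), schedule,
                        side,
                        bmu_feature_weights = c(rep(1, p),
                                                rep(class_weight, K)))
  structure(
    list(xy_grid = structure(list(side = grid$side, weights = W,
                                  feature_names = grid$feature_names),
                             class = "som_grid"),
         n_descriptors = p, class_names = classes, schedule = schedule,
         class_weight = class_weight,
         descriptor_names = train$descriptor_names, scaler_ref = scaler),
    class = c("skn_model", "som_classifier"))
}

check_trainable <- function(train) {
  if (is.null(train$labels)) stop("training table must be labelled")
  if (length(unique(train$labels)) < 2)
    stop("training data contain a single class")
}

one_hot <- function(labels, classes) {
  Y <- vapply(classes, function(cl) as.numeric(labels == cl),
              numeric(length(labels)))
  matrix(Y, ncol = length(classes), dimnames = list(NULL, classes))
}

# Internal: the map searched at prediction time and the class-membership
# weights per neuron.
prediction_layers <- function(model) {
  if (inherits(model, "cpann_model")) {
    list(weights = model$kohonen$weights, side = model$kohonen$side,
         memberships = model$grossberg)
  } else {
    p <- model$n_descriptors
    list(weights = model$xy_grid$weights[, seq_len(p), drop = FALSE],
         side = model$xy_grid$side,
         memberships = model$xy_grid$weights[, p + seq_along(model$class_names),
                                             drop = FALSE])
  }
}

#' Predict classes and membership scores
#'
#' Each query molecule is assigned the best matching unit on the descriptor
#' space (Kohonen layer for CPANN, descriptor block of the XY map for SKN);
#' its continuous class scores are that neuron's membership weights clipped
#' to `[0, 1]` and its class the argmax (ties towards the earlier class in
#' `class_names`).
#'
#' @param object a `cpann_model` or `skn_model`.
#' @param table a [descriptor_table()] already scaled like the training data
#'   and containing the model's descriptors.
#' @param neighborhood_scores if `TRUE`, scores average the 3x3 BMU
#'   neighbourhood's memberships with triangular distance weights, giving
#'   smoother rankings for screening.
#' @param ... unused.
#' @return A `som_prediction`: list with `molecule_ids`, `predicted_class`,
#'   `scores` (molecules x classes), `bmu_coordinates` (0-based, rows
#'   `(row, col)`).
#' @export
predict.som_classifier <- function(object, table,
                                   neighborhood_scores = FALSE, ...) {
  lay <- prediction_layers(object)
  if (!identical(table$descriptor_names, object$descriptor_names)) {
    table <- subset_descriptors(table, object$descriptor_names)
  }
  X <- table$values
  d2 <- outer(rowSums(X^2), rep(1, nrow(lay$weights))) +
    outer(rep(1, nrow(X)), rowSums(lay$weights^2)) -
    2 * tcrossprod(X, lay$weights)
  bmu <- apply(d2, 1, which.min)
  scores <- lay$memberships[bmu, , drop = FALSE]
  if (neighborhood_scores) {
    side <- lay$side
    ks <- seq_len(side^2)
    pos <- neuron_coords(ks, side)
    for (i in seq_along(bmu)) {
      b <- neuron_coords(bmu[i], side)
      dr <- abs(pos[, "row"] - b[1, "row"]); dc <- abs(pos[, "col"] - b[1, "col"])
      d <- pmax(pmin(dr, side - dr), pmin(dc, side - dc))
      w <- neighborhood(d, 1)  # support = the 3x3 ring around the BMU
      scores[i, ] <- colSums(lay$memberships * w) / sum(w)
    }
  }
  scores <- pmin(pmax(scores, 0), 1)
  dim(scores) <- c(length(bmu), length(object$class_names))
  colnames(scores) <- object$class_names
  pred <- object$class_names[apply(scores, 1, which.max)]
  structure(
    list(molecule_ids = table$molecule_ids, predicted_class = pred,
         scores = scores, bmu_coordinates = neuron_coords(bmu, lay$side)),
    class = "som_prediction")
}

#' @export
print.som_prediction <- function(x, ...) {
  cat("<som_prediction> ", length(x$molecule_ids), " molecules; classes: ",
      paste(utils::head(unique(x$predicted_class), 6), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Top map: per-neuron training-set assignment
#'
#' Assigns every training molecule to its best matching unit and summarises
#' each neuron by its occupants and majority class (ties towards the earlier
#' class; empty neurons flagged with `NA`). On a converged model trained on
#' separable classes the majority-class regions form contiguous patches on
#' the torus.
#'
#' @param model a trained `cpann_model` or `skn_model`.
#' @param train the (scaled) training [descriptor_table()].
#' @return A `top_map`: list with `side`, `assignments` (list of molecule-id
#'   vectors per neuron, row-major), `majority_class` (character vector,
#'   `NA` for empty neurons), `counts`.
#' @export
top_map <- function(model, train) {
  if (is.null(model$class_names)) stop("untrained model")
  pred <- stats::predict(model, train)
  lay <- prediction_layers(model)
  m <- lay$side^2
  idx <- coords_neuron(pred$bmu_coordinates[, "row"],
                       pred$bmu_coordinates[, "col"], lay$side)
  assignments <- vector("list", m)
  majority <- rep(NA_character_, m)
  counts <- integer(m)
  for (k in seq_len(m)) {
    members <- which(idx == k)
    assignments[[k]] <- train$molecule_ids[members]
    counts[k] <- length(members)
    if (length(members) && !is.null(train$labels)) {
      tab <- table(factor(train$labels[members],
                          levels = model$class_names))
      majority[k] <- names(tab)[which.max(tab)]
    }
  }
  structure(list(side = lay$side, assignments = assignments,
                 majority_class = majority, counts = counts),
            class = "top_map")
}

#' @export
print.top_map <- function(x, ...) {
  cat("<top_map> ", x$side, "x", x$side, " map, ",
      sum(x$counts > 0), " occupied neurons\n", sep = "")
  invisible(x)
}

#' Export a top map as a CSV grid
#' @param map a [top_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_top_map <- function(map, path) {
  pos <- neuron_coords(seq_len(map$side^2), map$side)
  utils::write.csv(
    data.frame(row = pos[, "row"], col = pos[, "col"],
               n_molecules = map$counts,
               majority_class = map$majority_class,
               molecule_ids = vapply(map$assignments, paste,
                                     character(1), collapse = ";")),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a trained classifier as portable JSON
#'
#' All weight arrays are written as full-precision JSON arrays; a round trip
#' reproduces predictions bit-for-bit.
#'
#' @param model a `cpann_model` or `skn_model`.
#' @param path file path.
#' @return `save_model`: `path` invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  kind <- if (inherits(model, "cpann_model")) "cpann" else "skn"
  payload <- list(kind = kind, class_names = model$class_names,
                  descriptor_names = model$descriptor_names,
                  schedule = unclass(model$schedule),
                  scaler = if (!is.null(model$scaler_ref))
                    unclass(model$scaler_ref))
  if (kind == "cpann") {
    payload$side <- model$kohonen$side
    payload$kohonen_weights <- model$kohonen$weights
    payload$grossberg <- model$grossberg
  } else {
    payload$side <- model$xy_grid$side
    payload$xy_weights <- model$xy_grid$weights
    payload$n_descriptors <- model$n_descriptors
    payload$class_weight <- model$class_weight
  }
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  schedule <- structure(pl$schedule, class = "training_schedule")
  scaler <- if (!is.null(pl$scaler))
    structure(pl$scaler, class = "scaling_model")
  classes <- pl$class_names
  if (pl$kind == "cpann") {
    W <- matrix(pl$kohonen_weights, ncol = length(pl$descriptor_names))
    colnames(W) <- pl$descriptor_names
    G <- matrix(pl$grossberg, ncol = length(classes))
    colnames(G) <- classes
    structure(
      list(kohonen = structure(list(side = pl$side, weights = W,
                                    feature_names = pl$descriptor_names),
                               class = "som_grid"),
           grossberg = G, class_names = classes, schedule = schedule,
           descriptor_names = pl$descriptor_names, scaler_ref = scaler),
      class = c("cpann_model", "som_classifier"))
  } else {
    nf <- length(pl$descriptor_names) + length(classes)
    W <- matrix(pl$xy_weights, ncol = nf)
    colnames(W) <- c(pl$descriptor_names, classes)
    structure(
      list(xy_grid = structure(list(side = pl$side, weights = W,
                                    feature_names = colnames(W)),
                               class = "som_grid"),
           n_descriptors = pl$n_descriptors, class_names = classes,
           schedule = schedule, class_weight = pl$class_weight,
           descriptor_names = pl$descriptor_names, scaler_ref = scaler),
      class = c("skn_model", "som_classifier"))
  }
}

#' Classifier specification for cross-validation and sweeps
#'
#' A lightweight description of which classifier to train and with what
#' hyperparameters, consumed by [cross_validate()], [sweep_model_size()],
#' [select_hyperparameters()] and [y_randomization()].
#'
#' @param kind `"skn"`, `"cpann"` or `"pls"` (PLS discriminant analysis on
#'   the one-hot response; fast, used mainly inside sweeps).
#' @param side,epochs map size and training epochs for the SOM kinds.
#' @param class_weight SKN class-block weighting.
#' @param n_components PLS component count (`NULL`: CV-selected).
#' @param eta_start,eta_end learning-rate schedule endpoints.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("skn", "cpann", "pls"), side = 6,
                            epochs = 60, class_weight = 1,
                            n_components = NULL,
                            eta_start = 0.5, eta_end = 0.01) {
  kind <- match.arg(kind)
  structure(list(kind = kind, side = side, epochs = epochs,
                 class_weight = class_weight, n_components = n_components,
                 eta_start = eta_start, eta_end = eta_end),
            class = "classifier_spec")
}

# Internal: train any classifier_spec on a labelled scaled table.
fit_classifier <- function(spec, train, seed) {
  sched <- training_schedule(epochs = spec$epochs, eta_start = spec$eta_start,
                             eta_end = spec$eta_end, seed = seed)
  switch(spec$kind,
    skn = train_skn(train, side = spec$side, schedule = sched,
                    class_weight = spec$class_weight),
    cpann = train_cpann(train, side = spec$side, schedule = sched),
    pls = {
      Y <- encode_response(train$labels, train$class_names)
      nc <- spec$n_components %||%
        min(5, ncol(train$values), nrow(train$values) - 1)
      fit <- fit_pls(train$values, Y, nc)
      structure(list(fit = fit, class_names = train$class_names,
                     descriptor_names = train$descriptor_names),
                class = "plsda_model")
    })
}

#' @export
predict.plsda_model <- function(object, table, ...) {
  tab <- if (identical(table$descriptor_names, object$descriptor_names))
    table else subset_descriptors(table, object$descriptor_names)
  raw <- stats::predict(object$fit, tab$values)
  classes <- object$class_names
  if (length(classes) == 2) {
    # single centred column predicts membership of the second class
    scores <- cbind(1 - raw[, 1], raw[, 1])
  } else {
    scores <- raw
  }
  colnames(scores) <- classes
  pred <- classes[apply(scores, 1, which.max)]
  structure(
    list(molecule_ids = tab$molecule_ids, predicted_class = pred,
         scores = pmin(pmax(scores, 0), 1), bmu_coordinates = NULL),
    class = "som_prediction")
}
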