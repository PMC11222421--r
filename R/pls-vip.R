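#' Fit a PLS2 model by NIPALS
#'
#' Nonlinear iterative partial least squares on a column-scaled descriptor
#' matrix `X` and a centred response matrix `Y` (a single centred \{0,1\}
#' column for binary classes, one-hot columns for multiclass). The
#' decomposition is fully deterministic for a fixed input.
#'
#' @param X numeric matrix, molecules x descriptors (column-scaled).
#' @param Y numeric matrix (or vector), molecules x responses; centred
#'   internally.
#' @param n_components number of latent components, at least 1 and at most
#'   `min(nrow(X) - 1, ncol(X))`.
#' @param tol,max_iter NIPALS inner-loop convergence controls.
#' @return A `pls_model`: list with `n_components`, `x_weights` (descriptors
#'   x components, unit-norm columns), `x_scores`, `x_loadings`,
#'   `y_loadings` (responses x components), `coefficients` (for response
#'   prediction), `explained_y_variance_per_component`, `y_means`,
#'   `descriptor_names`.
#' @export
fit_pls <- function(X, Y, n_components, tol = 1e-10, max_iter = 500) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  if (n_components < 1) stop("`n_components` must be at least 1")
  if (n_components > min(n - 1, p))
    stop("`n_components` exceeds the rank bound min(n - 1, p) = ",
         min(n - 1, p))
  y_means <- colMeans(Y)
  Yc <- sweep(Y, 2, y_means)
  Xd <- X; Yd <- Yc
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  Q <- matrix(0, m, n_components)
  ssy <- numeric(n_components)
  for (a in seq_len(n_components)) {
    u <- Yd[, which.max(apply(Yd, 2, stats::var))]
    if (sum(u^2) < tol) { n_components <- a - 1L; break }
    t_old <- rep(Inf, n)
    repeat {
      w <- crossprod(Xd, u)
      w <- w / sqrt(sum(w^2))
      t <- Xd %*% w
      q <- crossprod(Yd, t) / sum(t^2)
      u <- Yd %*% q / sum(q^2)
      if (sqrt(sum((t - t_old)^2)) < tol * sqrt(sum(t^2))) break
      t_old <- t
    }
    p_load <- crossprod(Xd, t) / sum(t^2)
    W[, a] <- w; P[, a] <- p_load; Tm[, a] <- t; Q[, a] <- q
    ssy[a] <- sum(t^2) * sum(q^2)  # Y variance captured by component a
    Xd <- Xd - tcrossprod(t, p_load)
    Yd <- Yd - tcrossprod(t, q)
  }
  if (n_components < 1) stop("response has zero variance; nothing to fit")
  W <- W[, seq_len(n_components), drop = FALSE]
  P <- P[, seq_len(n_components), drop = FALSE]
  Tm <- Tm[, seq_len(n_components), drop = FALSE]
  Q <- Q[, seq_len(n_components), drop = FALSE]
  ssy <- ssy[seq_len(n_components)]
  # regression coefficients B = W (P'W)^-1 Q'
  B <- W %*% solve(crossprod(P, W), t(Q))
  structure(
    list(n_components = n_components, x_weights = W, x_scores = Tm,
         x_loadings = P, y_loadings = Q, coefficients = B,
         explained_y_variance_per_component = ssy, y_means = y_means,
         descriptor_names = colnames(X)),
    class = "pls_model")
}

#' Predict responses from a fitted PLS model
#' @param object a `pls_model`.
#' @param newdata numeric matrix in the model's (scaled) descriptor space.
#' @param ... unused.
#' @return numeric matrix of predicted responses.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sweep(newdata %*% object$coefficients, 2, object$y_means, "+")
}

# Internal: response coding for PLS. Binary -> single centred {0,1} column;
# multiclass -> one-hot columns (centred inside fit_pls).
encode_response <- function(labels, class_names) {
  if (length(class_names) == 2) {
    matrix(as.numeric(labels == class_names[2]), ncol = 1,
           dimnames = list(NULL, class_names[2]))
  } else {
    Y <- vapply(class_names, function(cl) as.numeric(labels == cl),
                numeric(length(labels)))
    matrix(Y, ncol = length(class_names),
           dimnames = list(NULL, class_names))
  }
}

#' Variable importance in projection (VIP) scores
#'
#' Wold-style VIP: for descriptor j,
#' `VIP_j = sqrt( p * sum_a SSY_a * (w_ja / ||w_a||)^2 / sum_a SSY_a )`
#' with `p` the number of descriptors and `SSY_a` the response variance
#' captured by component `a`. By construction the mean squared VIP is 1.
#'
#' @param model a fitted `pls_model`.
#' @return A `vip_result`: list with `descriptor_names`, `vip_scores`,
#'   `n_components_used`.
#' @export
vip_scores <- function(model) {
  W <- model$x_weights
  ssy <- model$explained_y_variance_per_component
  if (sum(ssy) <= 0) stop("model explains zero response variance")
  p <- nrow(W)
  Wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  v <- sqrt(p * as.numeric(Wn2 %*% ssy) / sum(ssy))
  structure(
    list(descriptor_names = model$descriptor_names %||% rownames(W) %||%
           paste0("d", seq_len(p)),
         vip_scores = v, n_components_used = model$n_components),
    class = "vip_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the number of PLS components by venetian-blinds CV
#'
#' Evaluates 1..`max_components` latent components by interleaved k-fold
#' cross-validation, scoring each count by the predictive residual sum of
#' squares (PRESS) on the response; the count minimising PRESS is returned
#' (ties towards fewer components).
#'
#' @param X,Y as in [fit_pls()].
#' @param max_components upper cap; default 10.
#' @param k number of folds; default 10.
#' @return integer component count.
#' @export
select_pls_components <- function(X, Y, max_components = 10, k = 10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  k <- min(k, n)
  cap <- min(max_components, ncol(X), n - ceiling(n / k) - 1)
  cap <- max(cap, 1)
  folds <- venetian_blinds_folds(n, k)
  press <- numeric(cap)
  for (f in seq_len(k)) {
    tr <- folds != f; va <- !tr
    fit <- fit_pls(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                   min(cap, sum(tr) - 1, ncol(X)))
    fold_press <- numeric(cap)
    for (a in seq_len(min(cap, fit$n_components))) {
      Wa <- fit$x_weights[, 1:a, drop = FALSE]
      Pa <- fit$x_loadings[, 1:a, drop = FALSE]
      Qa <- fit$y_loadings[, 1:a, drop = FALSE]
      Ba <- Wa %*% solve(crossprod(Pa, Wa), t(Qa))
      pred <- sweep(X[va, , drop = FALSE] %*% Ba, 2, fit$y_means, "+")
      fold_press[a] <- sum((Y[va, , drop = FALSE] - pred)^2)
    }
    if (fit$n_components < cap)  # unreachable counts inherit the last fit
      fold_press[(fit$n_components + 1):cap] <- fold_press[fit$n_components]
    press <- press + fold_press
  }
  which.min(press)
}

#' Sweep the number of VIP-selected descriptors
#'
#' Ranks descriptors by VIP on the full (scaled, labelled) training table,
#' then for each candidate size k trains the designated classifier on the
#' top-k descriptors and scores it by k-fold venetian-blinds CV non-error
#' rate. The size attaining the maximal CV metric wins; ties go to the
#' smallest size.
#'
#' @param table scaled, labelled [descriptor_table()].
#' @param sizes integer vector of candidate descriptor counts
#'   (default `14:35`).
#' @param trainer classifier specification, see [classifier_spec()]; the
#'   `"pls"` kind is the fast default for sweeps.
#' @param cv_folds folds for the CV metric (default 10).
#' @param seed integer seed governing CV fold shuffling and SOM training.
#' @param n_components PLS component count for the VIP ranking; `NULL`
#'   (default) selects it by [select_pls_components()].
#' @return A `sweep_result`: list with `candidate_sizes`,
#'   `cv_metric_per_size`, `best_size`, `selected_descriptors`,
#'   `vip` (the underlying `vip_result`).
#' @export
sweep_model_size <- function(table, sizes = 14:35,
                             trainer = classifier_spec("pls"),
                             cv_folds = 10, seed = 1, n_components = NULL) {
  if (is.null(table$labels)) stop("sweep requires a labelled table")
  if (max(sizes) > n_descriptors(table))
    stop("candidate size ", max(sizes), " exceeds the ",
         n_descriptors(table), " available descriptors")
  Y <- encode_response(table$labels, table$class_names)
  if (is.null(n_components))
    n_components <- select_pls_components(table$values, Y)
  vip <- vip_scores(fit_pls(table$values, Y, n_components))
  ranked <- vip$descriptor_names[order(-vip$vip_scores)]
  metric <- vapply(sizes, function(k) {
    sub <- subset_descriptors(table, ranked[seq_len(k)])
    cv <- cross_validate(sub, trainer, k = cv_folds, seed = seed)
    cv$pooled$non_error_rate
  }, numeric(1))
  best <- sizes[order(-metric, sizes)[1]]
  structure(
    list(candidate_sizes = sizes, cv_metric_per_size = metric,
         best_size = best,
         selected_descriptors = ranked[seq_len(best)], vip = vip),
    class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> best size ", x$best_size, " (CV non-error rate ",
      format(x$cv_metric_per_size[match(x$best_size, x$candidate_sizes)],
             digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Write VIP scores as a two-column CSV
#' @param vip a `vip_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vip_scores <- function(vip, path) {
  utils::write.csv(
    data.frame(descriptor = vip$descriptor_names, vip = vip$vip_scores),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
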