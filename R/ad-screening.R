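#' Leverage-based applicability domain
#'
#' The leverage of a compound is `h_i = x_i' (X'X)^-1 x_i` with `X` the
#' (scaled, VIP-selected) training descriptor matrix and `x_i` the
#' compound's descriptor row, i.e. the diagonal of the hat matrix — its
#' distance from the training centroid in descriptor space. The critical
#' threshold is `h* = 3 (p + 1) / n` with `n` training compounds and `p`
#' selected descriptors; compounds with `h > h*` extrapolate and fall
#' outside the applicability domain. No intercept column is appended. For a
#' full-column-rank training matrix the training leverages sum to `p`.
#'
#' @param train_X numeric matrix (training molecules x descriptors) or a
#'   [descriptor_table()].
#' @param query_X matrix/table in the same descriptor space; defaults to the
#'   training matrix itself.
#' @return A `leverage_report`: list with `molecule_ids`, `h_values`,
#'   `h_star`, `inside_domain`, `n_train`, `n_descriptors`.
#' @export
leverage <- function(train_X, query_X = train_X) {
  ids <- NULL
  if (inherits(train_X, "descriptor_table")) train_X <- train_X$values
  if (inherits(query_X, "descriptor_table")) {
    ids <- query_X$molecule_ids
    query_X <- query_X$values
  }
  train_X <- as.matrix(train_X); query_X <- as.matrix(query_X)
  if (!nrow(train_X)) stop("empty training matrix")
  if (ncol(query_X) != ncol(train_X))
    stop("query and training matrices differ in descriptor count")
  if (!is.null(colnames(train_X)) && !is.null(colnames(query_X)) &&
      !identical(colnames(train_X), colnames(query_X)))
    stop("descriptor names of query and training matrices do not match")
  n <- nrow(train_X); p <- ncol(train_X)
  XtX <- crossprod(train_X)
  inv <- tryCatch(solve(XtX), error = function(e) NULL)
  if (is.null(inv) || rcond(XtX) < 1e-12) {
    warning("X'X is (near-)singular; using the Moore-Penrose pseudo-inverse")
    s <- svd(XtX)
    keep <- s$d > max(s$d) * 1e-12
    inv <- s$v[, keep, drop = FALSE] %*%
      (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  }
  h <- rowSums((query_X %*% inv) * query_X)
  h[h < 0] <- 0
  h_star <- 3 * (p + 1) / n
  structure(
    list(molecule_ids = ids %||% rownames(query_X) %||%
           as.character(seq_len(nrow(query_X))),
         h_values = as.numeric(h), h_star = h_star,
         inside_domain = h <= h_star, n_train = n, n_descriptors = p),
    class = "leverage_report")
}

#' @export
print.leverage_report <- function(x, ...) {
  cat("<leverage_report> h* = ", format(x$h_star, digits = 4), "; ",
      sum(x$inside_domain), "/", length(x$h_values),
      " compounds inside the domain\n", sep = "")
  invisible(x)
}

#' Write a leverage report as CSV
#' @param report a `leverage_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_leverage_report <- function(report, path) {
  utils::write.csv(
    data.frame(id = report$molecule_ids, h = report$h_values,
               h_star = report$h_star, inside = report$inside_domain),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Enrichment factor of a ranked screen
#'
#' Given the ranked (best-first) active/inactive flags of a screened
#' database, the enrichment factor at fraction `f` is the number of actives
#' in the top `ceiling(f * N)` ranks divided by `f` times the total actives:
#' random ranking concentrates at 1, a perfect ranking at up to `1 / f`.
#'
#' @param ranked_is_active logical vector, best rank first.
#' @param fraction top fraction of the database, in (0, 1].
#' @return the enrichment factor (non-negative real).
#' @export
enrichment_factor <- function(ranked_is_active, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  n_act <- sum(ranked_is_active)
  if (n_act == 0) stop("no actives in the ranked list")
  top <- ceiling(fraction * length(ranked_is_active))
  sum(ranked_is_active[seq_len(top)]) / (fraction * n_act)
}

#' Spike-in virtual screen
#'
#' Concatenates a background database with known actives, scores every
#' molecule with a trained classifier's continuous positive-class score,
#' ranks descending and reports enrichment factors at the requested top
#' fractions plus the ROC/AUC with the spiked actives as positives. Score
#' ties are resolved conservatively: background before spiked actives, then
#' molecule-id order.
#'
#' @param background [descriptor_table()] of database molecules (already
#'   scaled like the model's training data).
#' @param actives [descriptor_table()] of known actives, ids disjoint from
#'   the background.
#' @param model a trained `cpann_model`/`skn_model` (or any object with a
#'   `predict` method returning membership scores).
#' @param positive_class name of the class whose score ranks the database.
#' @param fractions top fractions for enrichment factors
#'   (default `c(0.01, 0.10)`).
#' @param neighborhood_scores passed to [predict.som_classifier()] for
#'   smoother score rankings.
#' @return A `screening_result`: list with `ranked_ids`, `is_active`,
#'   `scores`, `ef` (named per fraction), `ef_1pct`, `ef_10pct`, `roc`,
#'   `n_background`, `n_spiked`.
#' @export
spike_in_screen <- function(background, actives, model, positive_class,
                            fractions = c(0.01, 0.10),
                            neighborhood_scores = FALSE) {
  if (!nrow(actives$values)) stop("zero actives to spike in")
  if (nrow(background$values) < 100)
    stop("background must hold at least 100 molecules")
  if (length(intersect(background$molecule_ids, actives$molecule_ids)))
    stop("active ids overlap the background ids")
  score_of <- function(tab) {
    pr <- stats::predict(model, tab,
                         neighborhood_scores = neighborhood_scores)
    pr$scores[, positive_class]
  }
  sc <- c(score_of(background), score_of(actives))
  is_active <- c(rep(FALSE, nrow(background$values)),
                 rep(TRUE, nrow(actives$values)))
  ids <- c(background$molecule_ids, actives$molecule_ids)
  o <- order(-sc, is_active, ids)
  ranked_active <- is_active[o]
  ef <- vapply(fractions, function(f) enrichment_factor(ranked_active, f),
               numeric(1))
  names(ef) <- paste0("ef_", fractions)
  truth <- ifelse(is_active, "active", "background")
  roc <- roc_curve(truth, sc, "active")
  structure(
    list(ranked_ids = ids[o], is_active = ranked_active, scores = sc[o],
         ef = ef,
         ef_1pct = if (0.01 %in% fractions) ef[[which(fractions == 0.01)]]
                   else NA_real_,
         ef_10pct = if (0.10 %in% fractions) ef[[which(fractions == 0.10)]]
                    else NA_real_,
         roc = roc, n_background = nrow(background$values),
         n_spiked = nrow(actives$values)),
    class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("<screening_result> ", x$n_spiked, " actives spiked into ",
      x$n_background, " background molecules; EF1% ",
      format(x$ef_1pct, digits = 4), ", EF10% ",
      format(x$ef_10pct, digits = 4), ", AUC ",
      format(x$roc$auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write a screening result as CSV
#' @param result a `screening_result`.
#' @param path output path for the ranked list; a `*_summary.csv` sibling
#'   holds the EF/AUC block.
#' @return `path`, invisibly.
#' @export
write_screening_result <- function(result, path) {
  utils::write.csv(
    data.frame(rank = seq_along(result$ranked_ids), id = result$ranked_ids,
               score = result$scores, is_active = result$is_active),
    path, row.names = FALSE, quote = FALSE)
  summary_path <- sub("\\.csv$", "_summary.csv", path)
  utils::write.csv(
    data.frame(metric = c(names(result$ef), "auc", "n_background",
                          "n_spiked"),
               value = c(unname(result$ef), result$roc$auc,
                         result$n_background, result$n_spiked)),
    summary_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
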