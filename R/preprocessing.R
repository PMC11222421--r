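#' Remove (near-)constant descriptors
#'
#' Descriptors whose sample standard deviation does not exceed `eps` carry no
#' information and would break autoscaling; they are removed before any
#' correlation filtering.
#'
#' @param table a [descriptor_table()].
#' @param eps standard-deviation threshold below which a descriptor is
#'   considered constant; default `1e-8`.
#' @return A list with `table` (the filtered [descriptor_table()]) and
#'   `report` (a `filter_report`, see [correlation_filter()]).
#' @export
drop_zero_variance <- function(table, eps = 1e-8) {
  stds <- apply(table$values, 2, stats::sd)
  removed <- table$descriptor_names[stds <= eps]
  retained <- setdiff(table$descriptor_names, removed)
  if (!length(retained)) stop("all descriptors have (near-)zero variance")
  report <- structure(
    list(removed_zero_variance = removed, removed_correlated = character(0),
         retained = retained, threshold = NA_real_),
    class = "filter_report")
  list(table = subset_descriptors(table, retained), report = report)
}

#' Pairwise-correlation descriptor filter
#'
#' Removes multicollinear descriptors until no retained pair has Pearson
#' |r| above `threshold`. Elimination is greedy worst-pair-first: the pair
#' with the largest |r| above the threshold is found, and the member with the
#' higher mean absolute correlation to all other descriptors in the original
#' table is removed, so that within each correlated group the survivor is the
#' member with the lowest average correlation to the rest of the dataset.
#' Ties (e.g. identical columns) are broken by retaining the
#' lexicographically smaller descriptor name, which makes the retained set
#' invariant to column order.
#'
#' @param table a [descriptor_table()] with no zero-variance descriptors.
#' @param threshold Pearson |r| cutoff in (0, 1); default 0.90.
#' @return A list with `table` (filtered) and `report` (`filter_report` with
#'   fields `removed_zero_variance`, `removed_correlated`, `retained`,
#'   `threshold`).
#' @export
correlation_filter <- function(table, threshold = 0.90) {
  stopifnot(threshold > 0, threshold < 1)
  if (n_molecules(table) < 3)
    stop("correlation filter requires at least 3 molecules")
  C <- abs(stats::cor(table$values))
  if (anyNA(C))
    stop("undefined correlations; remove zero-variance descriptors first")
  p <- ncol(C)
  # mean |r| of each descriptor to all others, over the ORIGINAL set (fixed)
  mean_abs_r <- (rowSums(C) - 1) / (p - 1)
  names(mean_abs_r) <- colnames(C)
  alive <- rep(TRUE, p)
  nms <- colnames(C)
  repeat {
    Ca <- C[alive, alive, drop = FALSE]
    diag(Ca) <- 0
    mx <- max(Ca)
    if (mx <= threshold) break
    # candidate pairs within numerical tolerance of the worst correlation
    hits <- which(Ca >= mx - 1e-12, arr.ind = TRUE)
    pair_names <- t(apply(hits, 1, function(ij)
      sort(rownames(Ca)[ij])))
    pair_names <- unique(pair_names)
    key <- paste(pair_names[, 1], pair_names[, 2])
    pair <- pair_names[order(key)[1], ]
    victim <- if (mean_abs_r[pair[1]] > mean_abs_r[pair[2]] + 1e-12) {
      pair[1]
    } else if (mean_abs_r[pair[2]] > mean_abs_r[pair[1]] + 1e-12) {
      pair[2]
    } else {
      max(pair)  # tie: keep the lexicographically smaller name
    }
    alive[match(victim, nms)] <- FALSE
  }
  retained <- table$descriptor_names[table$descriptor_names %in% nms[alive]]
  removed <- setdiff(table$descriptor_names, retained)
  report <- structure(
    list(removed_zero_variance = character(0), removed_correlated = removed,
         retained = retained, threshold = threshold),
    class = "filter_report")
  list(table = subset_descriptors(table, retained), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> retained ", length(x$retained), " descriptors (",
      length(x$removed_zero_variance), " zero-variance, ",
      length(x$removed_correlated), " correlated removed",
      if (!is.na(x$threshold)) sprintf(", |r| > %.2f", x$threshold), ")\n",
      sep = "")
  invisible(x)
}

#' Fit an autoscaling model
#'
#' Records per-descriptor means and sample (ddof = 1) standard deviations so
#' that training, test and screening tables can be projected into the same
#' mean-centred, unit-variance space.
#'
#' @param table a [descriptor_table()] with no zero-variance descriptors.
#' @return A `scaling_model`: list with `descriptor_names`, `means`, `stds`.
#' @export
fit_scaler <- function(table) {
  means <- colMeans(table$values)
  stds <- apply(table$values, 2, stats::sd)
  if (any(stds == 0))
    stop("zero-variance descriptor encountered: ",
         paste(table$descriptor_names[stds == 0], collapse = ", "))
  structure(
    list(descriptor_names = table$descriptor_names,
         means = as.numeric(means), stds = as.numeric(stds)),
    class = "scaling_model")
}

#' Apply (or invert) an autoscaling model
#'
#' Projects a table onto the scaler's descriptors, in the scaler's order,
#' computing `(x - mean) / std` elementwise. Descriptors in the table but not
#' in the scaler are dropped with a warning; a scaler descriptor missing from
#' the table is an error.
#'
#' @param table a [descriptor_table()].
#' @param scaler a `scaling_model` from [fit_scaler()].
#' @param inverse if `TRUE`, undo the scaling (`x * std + mean`).
#' @return A [descriptor_table()] in the scaler's descriptor space.
#' @export
apply_scaler <- function(table, scaler, inverse = FALSE) {
  missing <- setdiff(scaler$descriptor_names, table$descriptor_names)
  if (length(missing))
    stop("scaler descriptors absent from table: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(table$descriptor_names, scaler$descriptor_names)
  if (length(extra))
    warning("dropping ", length(extra),
            " descriptors not covered by the scaler")
  tab <- subset_descriptors(table, scaler$descriptor_names)
  v <- tab$values
  if (inverse) {
    v <- sweep(sweep(v, 2, scaler$stds, "*"), 2, scaler$means, "+")
  } else {
    v <- sweep(sweep(v, 2, scaler$means, "-"), 2, scaler$stds, "/")
  }
  descriptor_table(v, tab$molecule_ids, tab$descriptor_names,
                   labels = tab$labels, class_names = tab$class_names)
}

#' @export
print.scaling_model <- function(x, ...) {
  cat("<scaling_model> ", length(x$descriptor_names), " descriptors\n",
      sep = "")
  invisible(x)
}
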