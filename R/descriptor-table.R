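#' Labelled molecular descriptor table
#'
#' The central data structure of the package: a numeric matrix of molecules
#' (rows) by molecular descriptors (columns), with unique molecule identifiers
#' and an optional categorical class label per molecule (e.g. active/inactive,
#' or the therapeutic target).
#'
#' @param values numeric matrix, molecules x descriptors; no missing values.
#' @param molecule_ids character vector of unique molecule identifiers, one
#'   per row of `values`.
#' @param descriptor_names character vector of unique descriptor names, one
#'   per column of `values`.
#' @param labels optional character (or factor) vector of class labels, one
#'   per molecule.
#' @param class_names optional character vector declaring the label set and
#'   its order; defaults to the sorted unique labels.
#' @return An object of class `descriptor_table`: a list with elements
#'   `values`, `molecule_ids`, `descriptor_names`, `labels`, `class_names`.
#' @export
descriptor_table <- function(values, molecule_ids, descriptor_names,
                             labels = NULL, class_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  molecule_ids <- as.character(molecule_ids)
  descriptor_names <- as.character(descriptor_names)
  if (nrow(values) != length(molecule_ids))
    stop("number of rows of `values` must equal length of `molecule_ids`")
  if (ncol(values) != length(descriptor_names))
    stop("number of columns of `values` must equal length of `descriptor_names`")
  if (anyDuplicated(molecule_ids))
    stop("duplicate molecule id: ",
         paste(unique(molecule_ids[duplicated(molecule_ids)]), collapse = ", "))
  if (anyDuplicated(descriptor_names))
    stop("duplicate descriptor name: ",
         paste(unique(descriptor_names[duplicated(descriptor_names)]), collapse = ", "))
  if (anyNA(values) || !all(is.finite(values)))
    stop("`values` must contain only finite numeric entries")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(values))
      stop("`labels` must have one entry per molecule")
    if (is.null(class_names)) class_names <- sort(unique(labels))
    if (!all(labels %in% class_names))
      stop("labels outside the declared class set: ",
           paste(setdiff(labels, class_names), collapse = ", "))
  } else {
    class_names <- NULL
  }
  dimnames(values) <- list(molecule_ids, descriptor_names)
  structure(
    list(values = values, molecule_ids = molecule_ids,
         descriptor_names = descriptor_names, labels = labels,
         class_names = class_names),
    class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("<descriptor_table> ", nrow(x$values), " molecules x ",
      ncol(x$values), " descriptors\n", sep = "")
  if (!is.null(x$labels)) {
    tab <- table(factor(x$labels, levels = x$class_names))
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  } else {
    cat("  unlabelled\n")
  }
  invisible(x)
}

#' Number of molecules / descriptors
#' @param table a [descriptor_table()].
#' @return integer count.
#' @export
n_molecules <- function(table) nrow(table$values)

#' @rdname n_molecules
#' @export
n_descriptors <- function(table) ncol(table$values)

#' Subset a descriptor table
#'
#' `subset_molecules` keeps the rows at `idx` (indices or a logical mask);
#' `subset_descriptors` keeps (and reorders to) the named descriptor
#' columns. Labels and ids stay consistent.
#'
#' @param table a [descriptor_table()].
#' @param idx integer or logical row selector.
#' @return A [descriptor_table()].
#' @export
subset_molecules <- function(table, idx) {
  descriptor_table(table$values[idx, , drop = FALSE],
                   table$molecule_ids[idx],
                   table$descriptor_names,
                   labels = if (!is.null(table$labels)) table$labels[idx],
                   class_names = table$class_names)
}

#' @rdname subset_molecules
#' @param names character vector of descriptor names to keep, in order.
#' @export
subset_descriptors <- function(table, names) {
  missing <- setdiff(names, table$descriptor_names)
  if (length(missing))
    stop("descriptors absent from table: ", paste(missing, collapse = ", "))
  descriptor_table(table$values[, names, drop = FALSE],
                   table$molecule_ids, names,
                   labels = table$labels, class_names = table$class_names)
}

#' Read a labelled descriptor table from CSV
#'
#' Expects a comma-separated file with a header row, a molecule-ID column and
#' numeric descriptor columns; an optional label column carries the class.
#'
#' @param path path to a CSV file.
#' @param id_column name of the molecule-ID column.
#' @param label_column optional name of the class-label column.
#' @param missing_policy what to do with empty or non-numeric descriptor
#'   cells: `"error"` (default), `"drop-molecule"` or `"drop-descriptor"`.
#' @return A [descriptor_table()].
#' @export
read_descriptor_table <- function(path, id_column = "id", label_column = NULL,
                                  missing_policy = c("error", "drop-molecule",
                                                     "drop-descriptor")) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!id_column %in% names(df)) stop("id column not found: ", id_column)
  if (!is.null(label_column) && !label_column %in% names(df))
    stop("label column not found: ", label_column)
  ids <- as.character(df[[id_column]])
  labels <- if (!is.null(label_column)) as.character(df[[label_column]])
  desc_cols <- setdiff(names(df), c(id_column, label_column))
  if (!length(desc_cols)) stop("no descriptor columns in ", path)
  vals <- suppressWarnings(
    vapply(df[desc_cols], function(col) as.numeric(col), numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(NULL, desc_cols))
  bad <- is.na(vals)
  if (any(bad)) {
    if (missing_policy == "error") {
      ij <- which(bad, arr.ind = TRUE)[1, ]
      stop("non-numeric or missing descriptor cell at molecule '",
           ids[ij[1]], "', descriptor '", desc_cols[ij[2]], "'")
    } else if (missing_policy == "drop-molecule") {
      keep <- !apply(bad, 1, any)
      vals <- vals[keep, , drop = FALSE]
      ids <- ids[keep]
      if (!is.null(labels)) labels <- labels[keep]
    } else {
      keep <- !apply(bad, 2, any)
      vals <- vals[, keep, drop = FALSE]
      desc_cols <- desc_cols[keep]
    }
  }
  descriptor_table(vals, ids, colnames(vals), labels = labels)
}

#' Write a descriptor table to CSV
#'
#' Inverse of [read_descriptor_table()]: id column first, then descriptors,
#' then (if present) the label column.
#'
#' @param table a [descriptor_table()].
#' @param path output CSV path.
#' @param id_column,label_column column names used in the file.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(table, path, id_column = "id",
                                   label_column = "label") {
  df <- data.frame(table$molecule_ids, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_column, table$descriptor_names)
  if (!is.null(table$labels)) df[[label_column]] <- table$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Random 70/30-style train/test split
#'
#' Randomly partitions a descriptor table into a training and a test set.
#' Stratified allocation (per-class proportions preserved to within one
#' molecule) is the default; set `stratified = FALSE` for a simple random
#' partition of the whole table.
#'
#' @param table a labelled [descriptor_table()] (labels required when
#'   `stratified = TRUE`).
#' @param train_fraction fraction of molecules assigned to training,
#'   in (0, 1); default 0.7.
#' @param seed integer seed; the split is deterministic given the seed.
#' @param stratified allocate per class (default) or over the pooled table.
#' @return A list of class `split_result` with elements `train`, `test`
#'   (descriptor tables), `seed` and `train_fraction`.
#' @export
split_train_test <- function(table, train_fraction = 0.7, seed,
                             stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- n_molecules(table)
  if (stratified) {
    if (is.null(table$labels))
      stop("stratified split requires a labelled table")
    sizes <- table(table$labels)
    if (any(sizes < 2))
      stop("class with fewer than 2 members under stratification: ",
           paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  train_idx <- withr::with_seed(seed, {
    if (stratified) {
      idx <- integer(0)
      for (cl in sort(unique(table$labels))) {
        members <- which(table$labels == cl)
        n_tr <- round(train_fraction * length(members))
        n_tr <- min(max(n_tr, 1L), length(members) - 1L)
        idx <- c(idx, sample(members, n_tr))
      }
      sort(idx)
    } else {
      sort(sample.int(n, round(train_fraction * n)))
    }
  })
  structure(
    list(train = subset_molecules(table, train_idx),
         test = subset_molecules(table, setdiff(seq_len(n), train_idx)),
         seed = seed, train_fraction = train_fraction),
    class = "split_result")
}

#' Test-versus-training nearest-neighbour similarity analysis
#'
#' For every test molecule, finds the most similar training molecule by
#' Euclidean distance in (scaled) descriptor space, reporting the minimum
#' distance and the achieving training id. Used to check that the external
#' test set is not trivially close to the training set.
#'
#' @param test,train descriptor tables with identical descriptor names in
#'   identical order, already scaled by the same scaler.
#' @return A list of class `similarity_report` with `test_ids`,
#'   `nearest_train_ids`, `nearest_distances`, `mean`, `std`. Ties are broken
#'   towards the lowest training row index.
#' @export
similarity_analysis <- function(test, train) {
  if (!identical(test$descriptor_names, train$descriptor_names))
    stop("descriptor names of test and training tables do not match")
  A <- test$values; B <- train$values
  # squared distances via the expansion ||a-b||^2 = ||a||^2 + ||b||^2 - 2ab'
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  nearest <- apply(d2, 1, which.min)
  dists <- sqrt(d2[cbind(seq_len(nrow(A)), nearest)])
  structure(
    list(test_ids = test$molecule_ids,
         nearest_train_ids = train$molecule_ids[nearest],
         nearest_distances = as.numeric(dists),
         mean = mean(dists),
         std = if (length(dists) > 1) stats::sd(dists) else 0),
    class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("<similarity_report> ", length(x$test_ids),
      " test molecules; nearest-training-distance mean ",
      format(x$mean, digits = 4), " (sd ", format(x$std, digits = 4), ")\n",
      sep = "")
  invisible(x)
}

#' Write a similarity report as CSV
#' @param report a `similarity_report` from [similarity_analysis()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity_report <- function(report, path) {
  utils::write.csv(
    data.frame(test_id = report$test_ids,
               nearest_train_id = report$nearest_train_ids,
               distance = report$nearest_distances),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
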