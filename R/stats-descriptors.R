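#' Hydrophilic factor (Hy) descriptor
#'
#' Computes the hydrophilic factor from the count of hydrophilic groups
#' (`-OH`, `-SH`, `-NH`), the carbon count and an atom count `A`:
#'
#' `Hy = [ (1 + N_Hy) log2(1 + N_Hy) + N_C (1/A log2 1/A) + sqrt(N_Hy / A^2) ]
#'        / log2(1 + A)`
#'
#' Hy grows with the number of hydrophilic groups and can be negative for
#' carbon-rich, hydrophilic-poor molecules (the middle term is negative).
#' The descriptor literature is not unanimous on what `A` counts; the
#' `atom_count_convention` argument records which convention the supplied
#' `n_atoms` follows (`"hydrogen"`: number of hydrogen atoms, the convention
#' used here by default; `"heavy_atoms"`: non-hydrogen atom count). The
#' arithmetic is identical either way — the flag only documents the input.
#'
#' @param n_hydrophilic non-negative integer count of -OH/-SH/-NH groups.
#' @param n_carbon non-negative integer carbon count.
#' @param n_atoms positive integer atom count `A` (see
#'   `atom_count_convention`).
#' @param atom_count_convention `"hydrogen"` (default) or `"heavy_atoms"`.
#' @return numeric Hy value(s); vectorised over the counts.
#' @export
hy_descriptor <- function(n_hydrophilic, n_carbon, n_atoms,
                          atom_count_convention = c("hydrogen",
                                                    "heavy_atoms")) {
  match.arg(atom_count_convention)
  stopifnot(all(n_hydrophilic >= 0), all(n_carbon >= 0))
  if (any(n_atoms < 1)) stop("atom count A must be at least 1")
  nhy <- n_hydrophilic; A <- n_atoms
  num <- (1 + nhy) * log2(1 + nhy) +
    n_carbon * (1 / A * log2(1 / A)) +
    sqrt(nhy / A^2)
  num / log2(1 + A)
}

#' Mann-Whitney U test with descriptor summaries
#'
#' Two-sided rank-sum comparison of a descriptor between two groups
#' (typically active vs inactive molecules). Uses exact enumeration when
#' `n1 + n2 <= 12` and the data are tie-free, and the normal approximation
#' with tie correction otherwise; also reports group means and standard
#' deviations for summary tables.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @return A `stat_test_result`: list with `statistic` (U for `group_a`),
#'   `p_value`, `group_sizes`, `method = "mann_whitney"`, `group_means`,
#'   `group_stds`, `exact`.
#' @export
mann_whitney <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("empty group")
  n1 <- length(group_a); n2 <- length(group_b)
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (n1 + n2 <= 12) && !has_ties
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = !exact))
  structure(
    list(statistic = unname(ht$statistic), p_value = min(ht$p.value, 1),
         group_sizes = c(n1, n2), method = "mann_whitney",
         group_means = c(mean(group_a), mean(group_b)),
         group_stds = c(stats::sd(group_a), stats::sd(group_b)),
         exact = exact),
    class = "stat_test_result")
}

#' Kruskal-Wallis test across descriptor groups
#'
#' Rank-based comparison of a descriptor across three or more groups (e.g.
#' the five active-inhibitor classes), with tie correction and a chi-square
#' p-value on `k - 1` degrees of freedom. Fully degenerate input (all
#' values identical) is flagged and reported as `H = 0`, `p = 1`.
#'
#' @param groups list of at least two non-empty numeric vectors.
#' @return A `stat_test_result` with `method = "kruskal_wallis"`; the
#'   `degenerate` flag marks the all-ties case.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(!lengths(groups))) stop("empty group")
  values <- unlist(groups, use.names = FALSE)
  degenerate <- length(unique(values)) == 1
  if (degenerate) {
    stat <- 0; p <- 1
  } else {
    g <- factor(rep(seq_along(groups), lengths(groups)))
    ht <- stats::kruskal.test(values, g)
    stat <- unname(ht$statistic); p <- ht$p.value
  }
  structure(
    list(statistic = stat, p_value = p, group_sizes = lengths(groups),
         method = "kruskal_wallis",
         group_means = vapply(groups, mean, numeric(1)),
         group_stds = vapply(groups, stats::sd, numeric(1)),
         degenerate = degenerate),
    class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat("<stat_test_result> ", x$method, ": statistic ",
      format(x$statistic, digits = 5), ", p = ",
      format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Per-class summary and group test for one descriptor
#'
#' Produces the summary-table row for a descriptor: per-class means and
#' standard deviations plus the appropriate nonparametric test — Mann-Whitney
#' for two classes, Kruskal-Wallis for three or more.
#'
#' @param table labelled [descriptor_table()].
#' @param descriptor descriptor name present in the table.
#' @return list with `descriptor`, `class_names`, `means`, `stds`, `test`
#'   (a `stat_test_result`).
#' @export
descriptor_group_summary <- function(table, descriptor) {
  if (is.null(table$labels)) stop("table must be labelled")
  if (!descriptor %in% table$descriptor_names)
    stop("descriptor not found: ", descriptor)
  x <- table$values[, descriptor]
  classes <- table$class_names
  groups <- lapply(classes, function(cl) x[table$labels == cl])
  test <- if (length(classes) == 2) {
    mann_whitney(groups[[1]], groups[[2]])
  } else {
    kruskal_wallis(groups)
  }
  list(descriptor = descriptor, class_names = classes,
       means = vapply(groups, mean, numeric(1)),
       stds = vapply(groups, stats::sd, numeric(1)),
       test = test)
}

#' Summary table over many descriptors
#'
#' Applies [descriptor_group_summary()] to each requested descriptor and
#' returns the rows as one data frame (per-class mean/sd columns plus the
#' test p-value). No multiple-testing correction is applied by default;
#' `adjust = "BH"` adds a Benjamini-Hochberg column.
#'
#' @param table labelled [descriptor_table()].
#' @param descriptors descriptor names (default: all).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data frame with one row per descriptor.
#' @export
descriptor_summary_table <- function(table, descriptors = NULL,
                                     adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  descriptors <- descriptors %||% table$descriptor_names
  rows <- lapply(descriptors, function(d) {
    s <- descriptor_group_summary(table, d)
    stats <- as.list(c(rbind(s$means, s$stds)))
    names(stats) <- as.vector(rbind(paste0("mean_", s$class_names),
                                    paste0("std_", s$class_names)))
    c(list(descriptor = d), stats,
      list(method = s$test$method, p_value = s$test$p_value))
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (adjust == "BH") df$p_adjusted <- stats::p.adjust(df$p_value, "BH")
  df
}
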