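#' Pearson chi-square test of independence on a contingency table
#'
#' Plain Pearson chi-square without continuity correction (also for 2x2
#' tables), with expected counts from the observed margins. A flag is raised
#' when the smallest expected count falls below 5; the test is never switched
#' silently.
#'
#' @param counts Non-negative integer matrix of observed counts (>= 2 rows
#'   and >= 2 columns, no all-zero row or column margin).
#' @return A list of class `chisq_result`: `statistic`, `df`
#'   (`(R-1)(C-1)`), `p_value`, `expected`, `min_expected`,
#'   `small_expected` (logical), `observed`.
#' @examples
#' pearson_chisq(matrix(c(10, 20, 30, 15), 2, 2))
#' @export
pearson_chisq <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop2("counts must be non-negative integers")
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop2("need at least a 2 x 2 table")
  if (sum(counts) <= 0) stop2("empty table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop2("degenerate table: a row or column margin is zero")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value),
                 expected = ct$expected,
                 min_expected = min(ct$expected),
                 small_expected = min(ct$expected) < 5,
                 observed = counts),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (x$small_expected)
    cat(sprintf("warning: min expected count %.2f < 5\n", x$min_expected))
  invisible(x)
}

#' Retained-vs-excluded attrition table
#'
#' Builds the 2-column contingency table comparing an analysis subset with
#' the participants excluded from it, category by category: the excluded
#' column is `full_counts - subset_counts`.
#'
#' @param full_counts,subset_counts Named non-negative integer vectors over
#'   the same categories; `subset_counts` must not exceed `full_counts`
#'   anywhere.
#' @return Integer matrix with columns `analysis` and `excluded`.
#' @export
attrition_table <- function(full_counts, subset_counts) {
  if (length(full_counts) != length(subset_counts))
    stop2("category vectors differ in length")
  if (!is.null(names(full_counts)) && !is.null(names(subset_counts)) &&
      !all(names(full_counts) == names(subset_counts)))
    stop2("category names differ between full and subset counts")
  excl <- full_counts - subset_counts
  if (any(excl < 0))
    stop2("subset counts exceed full counts")
  cbind(analysis = as.integer(subset_counts), excluded = as.integer(excl))
}

#' Cross-tabulate latent class assignments against subgroups
#'
#' Builds the engagement-class by demographic-subgroup count table, runs the
#' Pearson chi-square test of association, and computes within-subgroup
#' (column) proportions of each engagement class.
#'
#' @param assignments Per-participant class labels (factor or character).
#' @param subgroups Per-participant subgroup labels, same length and order.
#' @return A list of class `class_crosstab`: `counts`, `test` (a
#'   [pearson_chisq()] result), `col_props`.
#' @export
crosstab_classes <- function(assignments, subgroups) {
  if (length(assignments) != length(subgroups))
    stop2("assignments and subgroups must describe the same participants")
  counts <- table(class = assignments, subgroup = subgroups)
  counts <- unclass(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop2("degenerate table: need >= 2 classes and >= 2 subgroups")
  test <- pearson_chisq(counts)
  col_props <- sweep(counts, 2L, colSums(counts), `/`)
  structure(list(counts = counts, test = test, col_props = col_props),
            class = "class_crosstab")
}

#' @export
print.class_crosstab <- function(x, digits = 3, ...) {
  cat("Class x subgroup counts:\n")
  print(x$counts)
  cat("\nWithin-subgroup shares:\n")
  print(round(x$col_props, digits))
  cat("\n")
  print(x$test)
  invisible(x)
}
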