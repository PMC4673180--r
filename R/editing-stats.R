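#' Pool per-sample edited/unedited counts into a 2x2 proportion table
#'
#' Sums the edited and unedited counts of the target miRNA over the member
#' samples of each of two groups. Normalized counts are used by default
#' (rounded to the nearest integer for testing); raw counts on request.
#'
#' @param summaries an `editing_summary` data.frame from [editing_table()].
#' @param grouping named vector mapping sample id to group label; exactly
#'   two distinct groups are required.
#' @param use one of `"normalized"` (default) or `"raw"`.
#' @return a 2x2 matrix (rows = groups, columns = edited/unedited) of
#'   class `proportion_table`.
#' @export
pool_counts <- function(summaries, grouping, use = c("normalized", "raw")) {
  use <- match.arg(use)
  g <- grouping[summaries$sample]
  if (any(is.na(g)))
    stop_invalid("grouping does not cover samples: %s",
                 paste(summaries$sample[is.na(g)], collapse = ", "))
  lv <- unique(g)
  if (length(lv) != 2) stop_invalid("need exactly two groups, got %d", length(lv))
  ed <- if (use == "normalized") summaries$edited_norm else summaries$edited
  un <- if (use == "normalized") summaries$unedited_norm else summaries$unedited
  tab <- rbind(
    c(round(sum(ed[g == lv[1]])), round(sum(un[g == lv[1]]))),
    c(round(sum(ed[g == lv[2]])), round(sum(un[g == lv[2]]))))
  dimnames(tab) <- list(lv, c("edited", "unedited"))
  if (any(rowSums(tab) == 0))
    stop_invalid("group '%s' has zero total count; test refused",
                 lv[rowSums(tab) == 0][1])
  structure(tab, class = c("proportion_table", class(tab)))
}

#' Two-proportion chi-squared test with continuity correction
#'
#' The test for equality of two proportions on a 2x2 table:
#' `X^2 = sum over cells of (max(0, |O - E| - 0.5))^2 / E`, with expected
#' counts from the row/column marginals under independence; the 0.5
#' continuity term is clamped at zero so equal-proportion tables give
#' exactly `X^2 = 0`, and is dropped when `continuity = FALSE`. The
#' p-value is the upper tail of the chi-squared distribution with 1 degree
#' of freedom.
#'
#' @param tab 2x2 matrix: rows = groups, columns = edited/unedited.
#' @param continuity apply the continuity correction (default TRUE).
#' @return list of class `proportion_test_result`: `statistic`, `df`,
#'   `p_value`, `proportions` (per-group), `pooled`, `continuity`.
#' @export
two_proportion_test <- function(tab, continuity = TRUE) {
  tab <- unclass(as.matrix(tab))
  if (!all(dim(tab) == c(2, 2))) stop_invalid("need a 2x2 table")
  if (any(tab < 0) || any(!is.finite(tab))) stop_invalid("counts must be finite and non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_invalid("degenerate table: a marginal total is zero")
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  corr <- if (continuity) 0.5 else 0
  x2 <- sum(pmax(0, abs(tab - E) - corr)^2 / E)
  props <- tab[, 1] / rowSums(tab)
  structure(list(
    statistic = x2, df = 1L,
    p_value = stats::pchisq(x2, df = 1, lower.tail = FALSE),
    proportions = props,
    pooled = sum(tab[, 1]) / n,
    continuity = continuity), class = "proportion_test_result")
}

#' @export
print.proportion_test_result <- function(x, ...) {
  cat(sprintf(
    "Two-proportion test%s\nX-squared = %.4g, df = %d, p-value = %.4g\nproportions: %s (pooled %.4g)\n",
    if (x$continuity) " with continuity correction" else "",
    x$statistic, x$df, x$p_value,
    paste(sprintf("%s = %.4g", names(x$proportions), x$proportions),
          collapse = ", "),
    x$pooled))
  invisible(x)
}
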