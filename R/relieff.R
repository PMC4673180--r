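#' ReliefF feature weights for a binary classification problem
#'
#' Every instance is used in turn: its `k` nearest hits (same class) and
#' `k` nearest misses (other class) are found by Manhattan distance on
#' range-normalized features (the instance itself excluded, `k` clipped to
#' availability). The weight of feature `f` accumulates
#' `mean_miss diff(f) - mean_hit diff(f)` over instances, divided by the
#' number of instances, where `diff` is the absolute difference scaled by
#' the feature's range. A weight is therefore high when a feature differs
#' between classes but agrees within a class. Constant features get
#' weight 0. Neighbors are unweighted within `k`.
#'
#' @param x feature x sample numeric matrix.
#' @param labels binary class labels, one per sample (column).
#' @param k neighbors per class (default 10, clipped).
#' @param allow_singleton tolerate a one-sample class (used by the
#'   leave-one-out driver, where folds routinely leave one member): an
#'   instance with no same-class neighbor contributes only its miss term.
#' @return named numeric vector of feature weights.
#' @export
relieff_weights <- function(x, labels, k = 10L, allow_singleton = FALSE) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- ncol(x)
  if (length(labels) != n) stop_invalid("one label per sample required")
  if (length(unique(labels)) != 2)
    stop_invalid("exactly two classes required")
  if (min(table(labels)) < if (allow_singleton) 1 else 2)
    stop_invalid("each class needs at least 2 samples")
  k <- assert_scalar_int(k, "k", min = 1)
  rng <- apply(x, 1, function(v) diff(range(v)))
  keep <- rng > 0
  w <- stats::setNames(numeric(nrow(x)), rownames(x))
  if (!any(keep)) return(w)
  xn <- x[keep, , drop = FALSE] / rng[keep]   # range-normalized
  dmat <- as.matrix(stats::dist(t(xn), method = "manhattan"))
  acc <- numeric(sum(keep))
  for (r in seq_len(n)) {
    same <- which(labels == labels[r] & seq_len(n) != r)
    other <- which(labels != labels[r])
    misses <- other[order(dmat[r, other])][seq_len(min(k, length(other)))]
    diff_miss <- rowMeans(abs(xn[, misses, drop = FALSE] - xn[, r]))
    diff_hit <- if (length(same)) {
      hits <- same[order(dmat[r, same])][seq_len(min(k, length(same)))]
      rowMeans(abs(xn[, hits, drop = FALSE] - xn[, r]))
    } else 0
    acc <- acc + diff_miss - diff_hit
  }
  w[keep] <- acc / n
  w
}

#' Leave-one-out cross-validated average ReliefF merit
#'
#' For each of the `n` folds one sample is dropped and ReliefF weights are
#' computed on the remainder; the average merit of a feature is its mean
#' weight over folds, and features are ranked by decreasing average merit
#' with ties broken lexicographically by feature id. Folds whose removal
#' empties a class are skipped with a warning and the denominator
#' adjusted.
#'
#' @inheritParams relieff_weights
#' @return list of class `merit_ranking`: `fold_merits` (feature x fold
#'   matrix), `average_merit` (named vector), `rank` (named integer vector,
#'   1 = best), `n_folds_used`.
#' @export
loocv_average_merit <- function(x, labels, k = 10L) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (n < 4) stop_invalid("need at least 4 samples")
  labels <- as.character(labels)
  fold_merits <- matrix(NA_real_, nrow(x), n,
                        dimnames = list(rownames(x), colnames(x)))
  used <- logical(n)
  for (i in seq_len(n)) {
    lab_i <- labels[-i]
    if (length(unique(lab_i)) < 2) {
      warning(sprintf("fold %d skipped: dropping sample %s empties a class",
                      i, colnames(x)[i]))
      next
    }
    fold_merits[, i] <- relieff_weights(x[, -i, drop = FALSE], lab_i, k = k,
                                        allow_singleton = TRUE)
    used[i] <- TRUE
  }
  if (!any(used)) stop_invalid("no usable folds")
  avg <- rowMeans(fold_merits[, used, drop = FALSE])
  ord <- order(-avg, rownames(x))
  rk <- integer(nrow(x)); rk[ord] <- seq_len(nrow(x))
  names(rk) <- rownames(x)
  structure(list(fold_merits = fold_merits[, used, drop = FALSE],
                 average_merit = avg, rank = rk, n_folds_used = sum(used)),
            class = "merit_ranking")
}

#' Export the top-ranked features as paired log2-ratio heatmap matrices
#'
#' Rows are the `top_n` features by average merit; cells are per-pair
#' `log2((C + pseudocount) / (P + pseudocount))`. Three panels are
#' returned: all rows, rows with negative mean log2FC (underexpressed in C)
#' and rows with non-negative mean (overexpressed; zero-mean rows land
#' here), partitioning the `all` panel by sign.
#'
#' @param x feature x sample matrix (same features as the ranking).
#' @param ranking a `merit_ranking`.
#' @param pairs pairing as in [paired_log2fc()].
#' @param top_n number of top features (default 50, clipped with a warning).
#' @param pseudocount added inside the ratio (default 1).
#' @return list of class `heatmap_matrix`: `all`, `underexpressed`,
#'   `overexpressed` (matrices, rows annotated with rank), `ranks`.
#' @export
export_heatmap <- function(x, ranking, pairs, top_n = 50L, pseudocount = 1) {
  stopifnot(inherits(ranking, "merit_ranking"))
  if (top_n > length(ranking$rank)) {
    warning("top_n exceeds the number of features; clipped")
    top_n <- length(ranking$rank)
  }
  feats <- names(sort(ranking$rank))[seq_len(top_n)]
  fc <- paired_log2fc(x[feats, , drop = FALSE], pairs, pseudocount = pseudocount)
  m <- fc$per_pair
  under <- rowMeans(m) < 0
  structure(list(
    all = m,
    underexpressed = m[under, , drop = FALSE],
    overexpressed = m[!under, , drop = FALSE],
    ranks = ranking$rank[feats]), class = "heatmap_matrix")
}
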