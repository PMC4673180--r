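#' Per-pair log2 fold changes for a paired C/P design
#'
#' For every feature and every patient pair, computes
#' `log2((cpm_C + pseudocount) / (cpm_P + pseudocount))` and the mean over
#' pairs.
#'
#' @param nm feature x sample cpm (or normalized count) matrix.
#' @param pairs data.frame with columns `pair`, `C`, `P` (sample ids), or a
#'   metadata data.frame with `sample_id`, `patient`, `region` from which
#'   the pairing is derived.
#' @param pseudocount added to both members (default 1).
#' @return list of class `fold_change_table`: `per_pair` (feature x pair
#'   matrix of log2 ratios), `mean_log2fc` (named vector).
#' @export
paired_log2fc <- function(nm, pairs, pseudocount = 1) {
  nm <- as.matrix(nm)
  if (all(c("sample_id", "patient", "region") %in% colnames(pairs))) {
    wide <- split(pairs, pairs$patient)
    pairs <- do.call(rbind, lapply(wide, function(d) {
      if (!all(c("C", "P") %in% d$region))
        stop_invalid("patient %s lacks a C or P sample", d$patient[1])
      data.frame(pair = d$patient[1],
                 C = d$sample_id[d$region == "C"][1],
                 P = d$sample_id[d$region == "P"][1],
                 stringsAsFactors = FALSE)
    }))
  }
  missing <- setdiff(c(pairs$C, pairs$P), colnames(nm))
  if (length(missing))
    stop_invalid("samples absent from the matrix: %s",
                 paste(missing, collapse = ", "))
  per_pair <- log2((nm[, pairs$C, drop = FALSE] + pseudocount) /
                   (nm[, pairs$P, drop = FALSE] + pseudocount))
  colnames(per_pair) <- pairs$pair
  structure(list(per_pair = per_pair,
                 mean_log2fc = rowMeans(per_pair)),
            class = "fold_change_table")
}

#' Paired sign-flip permutation test
#'
#' The observed statistic per feature is the mean per-pair log2 fold
#' change. The null distribution is built by independently flipping the
#' sign of each pair's value (a common null for paired designs); the
#' two-sided p-value is `(1 + #permuted |stat| >= |observed|) / (n_perm + 1)`.
#' BH-adjusted FDRs are attached.
#'
#' @param fc a `fold_change_table` from [paired_log2fc()].
#' @param n_perm number of sign-flip permutations (default 10000, >= 100).
#' @param seed integer seed.
#' @return data.frame of class `diff_test_result`: feature, statistic,
#'   p_value, fdr.
#' @export
paired_permutation_test <- function(fc, n_perm = 10000L, seed) {
  stopifnot(inherits(fc, "fold_change_table"))
  n_perm <- assert_scalar_int(n_perm, "n_perm", min = 100)
  d <- fc$per_pair
  n_pairs <- ncol(d)
  if (n_pairs < 4) stop_invalid("need at least 4 pairs")
  obs <- rowMeans(d)
  with_seed(derive_seed(seed, "signflip"), {
    exceed <- integer(nrow(d))
    chunk <- 2000L
    done <- 0L
    while (done < n_perm) {
      nb <- min(chunk, n_perm - done)
      signs <- matrix(sample(c(-1, 1), n_pairs * nb, replace = TRUE),
                      n_pairs, nb)
      null_stats <- abs(d %*% signs) / n_pairs
      exceed <- exceed + rowSums(null_stats >= abs(obs) - 1e-12)
      done <- done + nb
    }
    p <- (1 + exceed) / (n_perm + 1)
  })
  out <- data.frame(feature = rownames(d), statistic = obs, p_value = p,
                    fdr = bh_fdr(p), stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("diff_test_result", "data.frame")
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard step-up adjustment (`q_(i) = min_{j >= i} p_(j) * m / j`,
#' capped at 1, input order preserved), delegated to
#' [stats::p.adjust()].
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_invalid("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Group-vs-control log2 fold changes
#'
#' Per group, `log2((mean group value + pseudocount) /
#' (control value + pseudocount))`. The groups are ratios of group means
#' (not means of per-sample ratios).
#'
#' @param nm feature x sample matrix (cpm or grouped counts).
#' @param groups named list: group name -> sample ids (columns of `nm`).
#' @param control column name (or index) of the control sample/profile.
#' @param pseudocount added to numerator and denominator (default 1).
#' @return feature x group matrix of log2 fold changes vs control.
#' @export
group_vs_control_fc <- function(nm, groups, control, pseudocount = 1) {
  nm <- as.matrix(nm)
  if (is.character(control) && !control %in% colnames(nm))
    stop_invalid("control column '%s' not found", control)
  ctrl <- nm[, control]
  out <- matrix(NA_real_, nrow(nm), length(groups),
                dimnames = list(rownames(nm), names(groups)))
  for (g in names(groups)) {
    cols <- groups[[g]]
    if (!length(cols)) stop_invalid("group '%s' is empty", g)
    gm <- rowMeans(nm[, cols, drop = FALSE])
    out[, g] <- log2((gm + pseudocount) / (ctrl + pseudocount))
  }
  out
}

#' Select features consistently modulated across all groups
#'
#' Overexpressed features reach `log2FC >= threshold` in every group;
#' underexpressed features reach `log2FC <= -threshold` in every group
#' (inclusive bounds). The two lists are disjoint by construction.
#'
#' @param fc feature x group matrix of log2 fold changes (e.g. from
#'   [group_vs_control_fc()]).
#' @param threshold positive log2 fold-change cutoff (default 1.5).
#' @return list with `overexpressed` and `underexpressed` feature ids.
#' @export
select_shared_modulated <- function(fc, threshold = 1.5) {
  if (threshold <= 0) stop_invalid("threshold must be positive")
  fc <- as.matrix(fc)
  if (ncol(fc) < 1) stop_invalid("need at least one group column")
  over <- rownames(fc)[apply(fc >= threshold, 1, all)]
  under <- rownames(fc)[apply(fc <= -threshold, 1, all)]
  list(overexpressed = over, underexpressed = under)
}
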