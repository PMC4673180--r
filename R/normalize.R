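#' Trimmed mean of M-values (TMM) normalization factors
#'
#' For each sample against a reference sample, per-feature log2 ratios of
#' proportions (M) and mean log2 abundances (A) are computed over features
#' with positive counts in both libraries. The most extreme
#' `logratio_trim` fraction of M values (per side, by rank) and
#' `abs_trim` fraction of A values are discarded, and the factor is
#' 2 to the precision-weighted mean of the retained M values. Precision
#' weights are the inverse relative (delta-method) variance computed from
#' the two proportions, `1 / ((1 - p_s) / p_s + (1 - p_r) / p_r)`; using
#' proportions rather than raw depths makes the factors exactly invariant
#' to rescaling any single library. Factors are rescaled so their
#' geometric mean is 1. The reference defaults to the sample whose
#' upper-quartile proportion is closest to the mean upper-quartile.
#'
#' @param m feature x sample matrix of non-negative counts.
#' @param logratio_trim fraction of M values trimmed per side (default 0.30).
#' @param abs_trim fraction of A values trimmed per side (default 0.05).
#' @param ref_sample optional column name or index of the reference sample.
#' @return named numeric vector of positive scaling factors, geometric
#'   mean 1.
#' @export
tmm_factors <- function(m, logratio_trim = 0.30, abs_trim = 0.05,
                        ref_sample = NULL) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop_invalid("TMM needs at least 2 samples")
  lib <- colSums(m)
  if (any(lib <= 0)) stop_invalid("every sample needs a positive total count")
  if (is.null(ref_sample)) {
    uq <- apply(m, 2, function(x) stats::quantile(x / sum(x), 0.75))
    ref_sample <- which.min(abs(uq - mean(uq)))
  } else if (is.character(ref_sample)) {
    ref_sample <- match(ref_sample, colnames(m))
  }
  yr <- m[, ref_sample]
  nr <- lib[ref_sample]
  f <- vapply(seq_len(ncol(m)), function(s) {
    if (s == ref_sample) return(1)
    ys <- m[, s]; ns <- lib[s]
    keep0 <- ys > 0 & yr > 0
    if (!any(keep0))
      stop_invalid("sample %d shares no positive features with the reference", s)
    ys0 <- ys[keep0]; yr0 <- yr[keep0]
    # M and A are defined canonically on log2 proportions so that trim
    # boundaries resolve identically across re-implementations; exact
    # ties are broken by feature order
    M <- log2(ys0 / ns) - log2(yr0 / nr)
    A <- (log2(ys0 / ns) + log2(yr0 / nr)) / 2
    # relative delta-method variance of M from the proportions; scale-free,
    # so rescaling one library leaves the weights (and factors) unchanged
    ps <- ys0 / ns; pr <- yr0 / nr
    v <- (1 - ps) / ps + (1 - pr) / pr
    if (max(abs(M)) < 1e-6) return(1)  # identical proportions
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first")
    rA <- rank(A, ties.method = "first")
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) return(1)
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(m))
}

#' Counts per million on effective library sizes
#'
#' `cpm[i, s] = (count[i, s] + pseudocount) /
#'  (library_size[s] * factor[s] + pseudocount * n_features) * 1e6`.
#' With `pseudocount = 0` and unit factors every column sums to 1e6.
#'
#' @param m feature x sample count matrix.
#' @param f named normalization factors covering all samples (default all 1).
#' @param pseudocount added to every count (default 0).
#' @return matrix of the same shape, counts per million.
#' @export
cpm_matrix <- function(m, f = NULL, pseudocount = 0) {
  m <- as.matrix(m)
  if (is.null(f)) f <- stats::setNames(rep(1, ncol(m)), colnames(m))
  if (!is.null(colnames(m))) {
    if (!all(colnames(m) %in% names(f)))
      stop_invalid("normalization factors must cover all samples")
    f <- f[colnames(m)]
  }
  eff <- colSums(m) * f + pseudocount * nrow(m)
  if (any(eff <= 0)) stop_invalid("zero effective library size")
  sweep(m + pseudocount, 2, eff, "/") * 1e6
}

#' Expression filter on counts per million
#'
#' With `pair_rule = TRUE` (the paired C/P filter), a pair passes for a
#' feature if the cpm reaches `min_cpm` in at least one of its two
#' samples, and the feature is retained iff strictly more than
#' `min_samples` pairs pass. With `pair_rule = FALSE`, a feature is
#' retained iff at least `min_samples` individual samples reach `min_cpm`.
#'
#' @param nm feature x sample cpm matrix.
#' @param min_cpm cpm threshold (default 10).
#' @param min_samples pair/sample count threshold (strict "more than" for
#'   pairs, "at least" for samples).
#' @param pair_rule logical; use the paired rule (needs `pairs`).
#' @param pairs named vector mapping sample id to pair/patient id.
#' @return character vector of retained feature ids.
#' @export
filter_by_cpm <- function(nm, min_cpm = 10, min_samples, pair_rule = FALSE,
                          pairs = NULL) {
  nm <- as.matrix(nm)
  pass <- nm >= min_cpm
  if (pair_rule) {
    if (is.null(pairs)) stop_invalid("pair_rule requires a sample-to-pair map")
    pairs <- pairs[colnames(nm)]
    n_pairs <- length(unique(pairs))
    if (min_samples >= n_pairs)
      stop_invalid("min_samples (%s) must be below the number of pairs (%d)",
                   min_samples, n_pairs)
    pair_pass <- t(apply(pass, 1, function(p) tapply(p, pairs, any)))
    keep <- rowSums(pair_pass) > min_samples
  } else {
    if (min_samples > ncol(nm))
      stop_invalid("min_samples exceeds the number of samples")
    keep <- rowSums(pass) >= min_samples
  }
  rownames(nm)[keep]
}
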