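toy_paired_matrix <- function(nf = 20, n_pairs = 6, seed = 1) {
  set.seed(seed)
  samples <- as.vector(rbind(sprintf("P%02d_C", 1:n_pairs),
                             sprintf("P%02d_P", 1:n_pairs)))
  m <- matrix(rnbinom(nf * 2 * n_pairs, mu = 100, size = 5),
              nf, 2 * n_pairs,
              dimnames = list(sprintf("f%02d", 1:nf), samples))
  meta <- data.frame(sample_id = samples,
                     patient = rep(sprintf("P%02d", 1:n_pairs), each = 2),
                     region = rep(c("C", "P"), n_pairs),
                     stringsAsFactors = FALSE)
  list(m = m, meta = meta)
}

test_that("paired log2 fold changes are computed per pair", {
  tp <- toy_paired_matrix()
  # identical C and P members: all zero
  m0 <- tp$m
  m0[, tp$meta$sample_id[tp$meta$region == "P"]] <-
    m0[, tp$meta$sample_id[tp$meta$region == "C"]]
  fc0 <- paired_log2fc(m0, tp$meta)
  expect_true(all(fc0$per_pair == 0))

  # worked value: C=30, P=7, pseudocount 1
  m1 <- matrix(c(30, 7), 1, 2, dimnames = list("f", c("P01_C", "P01_P")))
  meta1 <- data.frame(sample_id = c("P01_C", "P01_P"), patient = "P01",
                      region = c("C", "P"), stringsAsFactors = FALSE)
  expect_equal(unname(paired_log2fc(m1, meta1)$per_pair[1, 1]),
               log2(31 / 8), tolerance = 1e-12)

  # swapping labels negates every value
  fc <- paired_log2fc(tp$m, tp$meta)
  meta_sw <- tp$meta
  meta_sw$region <- ifelse(meta_sw$region == "C", "P", "C")
  fc_sw <- paired_log2fc(tp$m, meta_sw)
  expect_equal(fc_sw$per_pair, -fc$per_pair)

  bad <- tp$meta[-2, ]
  expect_error(paired_log2fc(tp$m, bad), "lacks")
})

test_that("sign-flip p-values match the exhaustive-flip oracle", {
  # n pairs, identical sign and magnitude: exact two-sided p = 2 / 2^n
  for (n_pairs in c(5, 8)) {
    d <- matrix(1, 1, n_pairs,
                dimnames = list("f", sprintf("P%02d", 1:n_pairs)))
    fc <- structure(list(per_pair = d, mean_log2fc = rowMeans(d)),
                    class = "fold_change_table")
    res <- paired_permutation_test(fc, n_perm = 20000, seed = 11)
    expect_equal(res$p_value, 2 / 2^n_pairs, tolerance = 0.35)
  }
  # all-zero differences: p = 1 exactly
  d0 <- matrix(0, 2, 6, dimnames = list(c("a", "b"), sprintf("P%d", 1:6)))
  fc0 <- structure(list(per_pair = d0, mean_log2fc = rowMeans(d0)),
                   class = "fold_change_table")
  res0 <- paired_permutation_test(fc0, n_perm = 500, seed = 2)
  expect_equal(res0$p_value, c(1, 1))
  # determinism
  tp <- toy_paired_matrix()
  fc <- paired_log2fc(tp$m, tp$meta)
  r1 <- paired_permutation_test(fc, n_perm = 500, seed = 7)
  r2 <- paired_permutation_test(fc, n_perm = 500, seed = 7)
  expect_identical(r1, r2)
  expect_error(paired_permutation_test(fc, n_perm = 50, seed = 1), "n_perm")
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(99)
  for (trial in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-14)
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("group-vs-control fold changes reproduce hand-computed values", {
  m <- rbind(`hsa-miR-99b-5p` = c(HC = 1186, LTC = 71),
             `hsa-miR-21-3p` = c(HC = 0, LTC = 10))
  fc <- group_vs_control_fc(m, groups = list(LTC = "LTC"), control = "HC")
  expect_equal(unname(fc["hsa-miR-99b-5p", "LTC"]), log2(72 / 1187),
               tolerance = 1e-12)
  expect_equal(unname(fc["hsa-miR-21-3p", "LTC"]), log2(11 / 1),
               tolerance = 1e-12)
  # group mean equal to control: zero
  m2 <- rbind(f = c(HC = 50, a = 40, b = 60))
  fc2 <- group_vs_control_fc(m2, groups = list(g = c("a", "b")), control = "HC")
  expect_equal(unname(fc2["f", "g"]), 0)
  expect_error(group_vs_control_fc(m2, groups = list(g = character(0)),
                                   control = "HC"), "empty")
  expect_error(group_vs_control_fc(m2, groups = list(g = "a"),
                                   control = "nope"), "control")
})

test_that("signature selection keeps the bundled count tables intact", {
  for (direction in c("overexpressed", "underexpressed")) {
    counts <- example_mirna_counts(direction)
    groups <- list(LTC = "LTC", LTP = "LTP", STC = "STC", STP = "STP")
    fc <- group_vs_control_fc(counts, groups, control = "HC", pseudocount = 1)
    sel <- select_shared_modulated(fc, threshold = 1.5)
    expect_setequal(sel[[direction]], rownames(counts))
    other <- setdiff(c("overexpressed", "underexpressed"), direction)
    expect_length(sel[[other]], 0)
  }
})

test_that("selection bounds are inclusive and the lists disjoint", {
  fc <- rbind(at_bound = c(1.5, 1.5), below = c(1.49, 2),
              neg = c(-1.5, -1.6), mixed = c(1.5, -1.5))
  colnames(fc) <- c("g1", "g2")
  sel <- select_shared_modulated(fc, threshold = 1.5)
  expect_identical(sel$overexpressed, "at_bound")
  expect_identical(sel$underexpressed, "neg")
  expect_length(intersect(sel$overexpressed, sel$underexpressed), 0)
  expect_error(select_shared_modulated(fc, threshold = 0), "positive")
})

test_that("null cohorts give uniform p-values and planted effects are found", {
  coh <- simulate_paired_cohort(8, effects = list(n_features = 300,
                                                  n_planted = 0), seed = 5)
  fc <- paired_log2fc(cpm_matrix(coh$counts), coh$metadata)
  res <- paired_permutation_test(fc, n_perm = 2000, seed = 6)
  ks <- suppressWarnings(stats::ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)

  # the sign-flip null has p-value resolution 2 / 2^n_pairs, so detecting
  # 5 of 300 features at FDR 0.05 needs p <= 8.3e-4, i.e. >= 13 pairs
  coh2 <- simulate_paired_cohort(14, effects = list(n_features = 300,
                                                    n_planted = 5,
                                                    log2_effect = 2), seed = 9)
  fc2 <- paired_log2fc(cpm_matrix(coh2$counts), coh2$metadata)
  res2 <- paired_permutation_test(fc2, n_perm = 5000, seed = 10)
  hits <- res2$feature[res2$fdr < 0.05]
  expect_gte(length(intersect(hits, coh2$truth$planted)), 4)
})
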