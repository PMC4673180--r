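summary_row <- function(sample, edited, unedited, norm = 1) {
  data.frame(sample = sample, edited = edited, unedited = unedited,
             edited_norm = edited * norm, unedited_norm = unedited * norm,
             fraction = edited / (edited + unedited),
             defined = edited + unedited > 0, stringsAsFactors = FALSE)
}

test_that("pooling sums member samples per group", {
  s <- rbind(summary_row("a", 10, 90), summary_row("b", 20, 80),
             summary_row("c", 5, 95))
  tab <- pool_counts(s, c(a = "G1", b = "G1", c = "G2"))
  expect_equal(unname(tab["G1", ]), c(30, 170))
  expect_equal(unname(tab["G2", ]), c(5, 95))
  # one sample per group: the table is that sample's counts
  tab1 <- pool_counts(s[1:2, ], c(a = "X", b = "Y"))
  expect_equal(unname(tab1["X", ]), c(10, 90))
  # different groupings of the same summaries give different tables
  tab2 <- pool_counts(s, c(a = "G1", b = "G2", c = "G2"))
  expect_false(identical(unname(tab2), unname(tab)))
  # normalized counts are the default; raw mode uses raw columns
  s2 <- rbind(summary_row("a", 10, 90, norm = 2), summary_row("b", 5, 5, norm = 2))
  expect_equal(unname(pool_counts(s2, c(a = "X", b = "Y"))["X", ]), c(20, 180))
  expect_equal(unname(pool_counts(s2, c(a = "X", b = "Y"), use = "raw")["X", ]),
               c(10, 90))
  # a group with zero total refuses the test
  s3 <- rbind(summary_row("a", 10, 90), summary_row("b", 0, 0))
  expect_error(pool_counts(s3, c(a = "X", b = "Y")), "zero total")
})

test_that("the two-proportion test reproduces hand-computed statistics", {
  # equal proportions: X2 = 0, p = 1
  t_eq <- rbind(c(10, 90), c(20, 180))
  r_eq <- two_proportion_test(t_eq)
  expect_equal(r_eq$statistic, 0)
  expect_equal(r_eq$p_value, 1)
  # hand-computed Yates and Pearson values for (10,90) vs (30,70)
  t1 <- rbind(c(10, 90), c(30, 70))
  expect_equal(two_proportion_test(t1)$statistic, 11.28125, tolerance = 1e-12)
  expect_equal(two_proportion_test(t1, continuity = FALSE)$statistic, 12.5,
               tolerance = 1e-12)
  # row swap leaves the statistic unchanged
  expect_equal(two_proportion_test(t1[2:1, ])$statistic,
               two_proportion_test(t1)$statistic)
  expect_error(two_proportion_test(rbind(c(0, 0), c(1, 1))), "degenerate")
})

test_that("the statistic equals the Yates shortcut and the squared z", {
  set.seed(123)
  for (trial in 1:1000) {
    tab <- matrix(rpois(4, lambda = sample(c(5, 50, 500), 1)) + 1, 2, 2)
    expect_equal(two_proportion_test(tab)$statistic,
                 oracle_yates_shortcut(tab), tolerance = 1e-9)
    expect_equal(two_proportion_test(tab, continuity = FALSE)$statistic,
                 oracle_z_squared(tab), tolerance = 1e-9)
  }
})

test_that("the test agrees with prop.test and is calibrated under the null", {
  tab <- rbind(c(120, 880), c(210, 790))
  mine <- two_proportion_test(tab)
  ref <- stats::prop.test(tab[, 1], rowSums(tab))
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)

  # Monte-Carlo: equal true proportions reject at most ~alpha
  set.seed(7)
  n_sim <- 10000
  rejections <- 0
  for (i in seq_len(n_sim)) {
    e1 <- rbinom(1, 200, 0.3); e2 <- rbinom(1, 300, 0.3)
    t2 <- rbind(c(e1, 200 - e1), c(e2, 300 - e2))
    if (any(colSums(t2) == 0)) next
    if (two_proportion_test(t2)$p_value < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections / n_sim, 0.06)
})

test_that("a planted fraction difference is detected with the right sign", {
  ref <- make_mirna_reference(4, seed = 3)
  idx <- build_mirna_index(ref)
  target <- ref$editable[1]
  w <- setNames(rep(1, 4), names(mature_sequences(ref)))
  tables <- list()
  grouping <- character(0)
  for (p in 1:3) {
    for (reg in c("C", "P")) {
      id <- sprintf("P%d_%s", p, reg)
      d <- sample_design(id, abundance = w,
                         editing_fraction = setNames(
                           if (reg == "C") 0.15 else 0.45, target),
                         n_reads = 4000, error_rate = 0.001, region = reg)
      sim <- simulate_small_rna_sample(ref, d, seed = 50 + p)
      tables[[id]] <- summarize_sample(sim$reads, idx, sample_id = id)
      grouping[id] <- reg
    }
  }
  et <- editing_table(tables, target)
  tab <- pool_counts(et, grouping)
  res <- two_proportion_test(tab)
  expect_lt(res$p_value, 1e-6)
  expect_lt(res$proportions[["C"]], res$proportions[["P"]])
})
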