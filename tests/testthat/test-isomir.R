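# A small hand-built reference used across the calling tests: one
# precursor whose mature occupies a known interval, so expected calls can
# be derived by eye.
toy_reference <- function() {
  pre <- paste0("GGGTT",                      # 5 nt upstream flank
                "TACATAGAGGAAATTCCATGAT",     # mature, 22 nt (pos 6..27)
                "GTCCC")                      # downstream flank starts G,T
  structure(list(
    precursors = c(`pre-1` = pre),
    matures = data.frame(mature_name = "mir-1", precursor_id = "pre-1",
                         start = 6L, end = 27L, arm = "3p",
                         stringsAsFactors = FALSE),
    editable = "mir-1"), class = "mirna_reference")
}

test_that("the index stores clipped precursor-templated extended regions", {
  ref <- toy_reference()
  idx <- build_mirna_index(ref, window = 3)
  en <- idx$entries[["mir-1"]]
  # [start-3, end+3] = precursor[3..30]
  expect_equal(en$ext, substr(ref$precursors[[1]], 3, 30))
  expect_equal(en$mature_at, 4L)

  # mature too close to the precursor start: region clipped at base 1
  ref2 <- ref
  ref2$matures$start <- 2L; ref2$matures$end <- 23L
  idx2 <- build_mirna_index(ref2, window = 3)
  expect_equal(idx2$entries[["mir-1"]]$mature_at, 2L)

  ref3 <- ref
  ref3$matures$end <- 99L
  expect_error(build_mirna_index(ref3), "outside")
})

test_that("canonical, edited and tailed reads are classified as expected", {
  ref <- toy_reference()
  idx <- build_mirna_index(ref)
  mat <- mature_sequences(ref)[["mir-1"]]

  cc <- call_read(mat, idx)
  expect_equal(cc$mature_name, "mir-1")
  expect_true(cc$is_canonical)
  expect_equal(cc$offset5, 0L)
  expect_equal(cc$offset3, 0L)
  expect_equal(nrow(cc$substitutions), 0)

  # G in place of the A at mature position 6: the configured edit
  edited <- mat; substr(edited, 6, 6) <- "G"
  ce <- call_read(edited, idx)
  expect_equal(ce$substitutions$mature_position, 6L)
  expect_equal(ce$substitutions$ref, "A")
  expect_equal(ce$substitutions$alt, "G")
  expect_true(gbmirnome:::call_is_edited(
    ce, list(position = 6L, ref = "A", alt = "G")))

  # mature + AA where the precursor continues GT: non-templated tail
  tailed <- paste0(mat, "AA")
  ct <- call_read(tailed, idx)
  expect_equal(ct$tail, "AA")
  expect_equal(ct$offset3, 0L)
  expect_equal(nrow(ct$substitutions), 0)

  # two substitutions exceed the budget
  bad <- mat
  substr(bad, 6, 6) <- "G"; substr(bad, 12, 12) <- "C"
  expect_s3_class(call_read(bad, idx), "unassigned")
  expect_s3_class(call_read("ACGTACGTACGTACG", idx), "unassigned")
})

test_that("templated shifts are offsets, not tails", {
  ref <- toy_reference()
  idx <- build_mirna_index(ref)
  pre <- ref$precursors[[1]]
  # one extra templated base on both sides
  shifted <- substr(pre, 5, 28)
  cs <- call_read(shifted, idx)
  expect_equal(cs$offset5, -1L)
  expect_equal(cs$offset3, 1L)
  expect_equal(cs$tail, "")
  expect_true(startsWith(cs$signature, "o5:-1;o3:1"))
})

test_that("call_read agrees with brute-force enumeration on random reads", {
  ref <- make_mirna_reference(8, seed = 31)
  idx <- build_mirna_index(ref)
  ms <- mature_sequences(ref)
  set.seed(77)
  for (trial in 1:120) {
    base <- ms[[sample(length(ms), 1)]]
    read <- base
    op <- sample(c("none", "sub", "tail", "both"), 1)
    if (op %in% c("sub", "both")) {
      p <- sample(nchar(read), 1)
      substr(read, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    if (op %in% c("tail", "both"))
      read <- paste0(read, paste(sample(c("A", "C", "G", "T"),
                                        sample(1:3, 1), replace = TRUE),
                                 collapse = ""))
    mine <- call_read(read, idx)
    orac <- oracle_call_read(read, ref)
    if (is.null(orac)) {
      expect_s3_class(mine, "unassigned")
    } else {
      expect_equal(mine$mature_name, orac$mature_name, info = read)
      expect_equal(mine$offset5, orac$offset5, info = read)
      expect_equal(mine$offset3, orac$offset3, info = read)
      expect_equal(mine$tail, orac$tail, info = read)
      expect_equal(mine$substitutions$mature_position,
                   orac$subs$mature_position, info = read)
    }
  }
})

test_that("sample summaries count, group and conserve reads", {
  ref <- toy_reference()
  idx <- build_mirna_index(ref)
  mat <- mature_sequences(ref)[["mir-1"]]
  edited <- mat; substr(edited, 6, 6) <- "G"
  reads <- c(rep(mat, 10), rep(edited, 5), "CCCCCCCCCCCCCCCC")
  tab <- summarize_sample(reads, idx, sample_id = "S1")
  expect_equal(unname(tab$grouped["mir-1"]), 15)
  expect_equal(nrow(tab$variants), 2)
  expect_equal(tab$unassigned, 1L)
  expect_equal(sum(tab$variants$count) + tab$unassigned, tab$total)
  # order invariance
  tab2 <- summarize_sample(rev(reads), idx, sample_id = "S1")
  expect_identical(tab$variants, tab2$variants)
  # no assignable reads: empty table, everything unassigned
  tab3 <- summarize_sample(c("GGGGGGGGGGGGGGGG"), idx)
  expect_equal(nrow(tab3$variants), 0)
  expect_equal(tab3$unassigned, 1L)
})

test_that("editing summaries separate edited variants and flag empties", {
  ref <- toy_reference()
  idx <- build_mirna_index(ref)
  mat <- mature_sequences(ref)[["mir-1"]]
  edited <- mat; substr(edited, 6, 6) <- "G"
  edited_tailed <- paste0(edited, "AA")   # edit plus tail still edited
  reads <- c(rep(edited, 20), rep(edited_tailed, 5), rep(mat, 75))
  tab <- summarize_sample(reads, idx, sample_id = "S1")
  et <- editing_table(list(S1 = tab), "mir-1")
  expect_equal(et$edited, 25)
  expect_equal(et$unedited, 75)
  expect_equal(et$fraction, 0.25)

  # per-sample normalizer scales the normalized columns only
  etn <- editing_table(list(S1 = tab), "mir-1", normalizer = c(S1 = 2))
  expect_equal(etn$edited_norm, 50)
  expect_equal(etn$edited, 25)

  # absent target: flagged undefined
  et0 <- editing_table(list(S1 = tab), "mir-1",
                       edit = list(position = 6L, ref = "A", alt = "G"),
                       known = "mir-1")
  expect_true(et0$defined)
  empty <- summarize_sample(character(0), idx, sample_id = "S2")
  et2 <- editing_table(list(S2 = empty), "mir-1")
  expect_false(et2$defined)
  expect_true(is.na(et2$fraction))
  expect_error(editing_table(list(S1 = tab), "nope", known = "mir-1"),
               "not in the reference")
})

test_that("edited fraction is recovered on simulated samples", {
  ref <- make_mirna_reference(5, seed = 2)
  idx <- build_mirna_index(ref)
  target <- ref$editable[1]
  w <- setNames(rep(1, 5), names(mature_sequences(ref)))
  # zero error: recovery is exact against the planted truth
  d <- sample_design("S", abundance = w,
                     editing_fraction = setNames(0.3, target),
                     n_reads = 5000, error_rate = 0)
  sim <- simulate_small_rna_sample(ref, d, seed = 5)
  tab <- summarize_sample(sim$reads, idx, sample_id = "S")
  et <- editing_table(list(S = tab), target)
  truth <- sim$truth[sim$truth$mature_name == target, ]
  expect_equal(et$edited, truth$n_edited)
  expect_equal(et$edited + et$unedited, truth$n_reads)

  # with sequencing error: within 3 binomial SDs plus an error-order bias
  d2 <- sample_design("S", abundance = w,
                      editing_fraction = setNames(0.3, target),
                      n_reads = 20000, error_rate = 0.002)
  sim2 <- simulate_small_rna_sample(ref, d2, seed = 6)
  tab2 <- summarize_sample(sim2$reads, idx, sample_id = "S")
  et2 <- editing_table(list(S = tab2), target)
  n_t <- sim2$truth$n_reads[sim2$truth$mature_name == target]
  tol <- 3 * sqrt(0.3 * 0.7 / n_t) + 25 * 0.002
  expect_lt(abs(et2$fraction - 0.3), tol)
})
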