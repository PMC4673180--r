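test_that("miRNA reference construction enforces its invariants", {
  ref <- make_mirna_reference(20, seed = 7, n_editable = 3)
  expect_length(ref$precursors, 20)
  expect_equal(nrow(ref$matures), 20)
  pre_len <- nchar(ref$precursors[ref$matures$precursor_id])
  expect_true(all(ref$matures$start >= 1 & ref$matures$end <= pre_len))
  lens <- ref$matures$end - ref$matures$start + 1
  expect_true(all(lens >= 18 & lens <= 25))
  expect_false(any(duplicated(ref$matures$mature_name)))
  ms <- mature_sequences(ref)
  expect_true(all(substr(ms[ref$editable], 6, 6) == "A"))
  expect_error(make_mirna_reference(0, seed = 1), "n_mirnas")
})

test_that("generators are pure functions of config and seed", {
  r1 <- make_mirna_reference(50, seed = 1)
  r2 <- make_mirna_reference(50, seed = 1)
  r3 <- make_mirna_reference(50, seed = 2)
  expect_identical(r1, r2)
  expect_false(identical(r1$precursors, r3$precursors))

  coh1 <- simulate_paired_cohort(4, seed = 11)
  coh2 <- simulate_paired_cohort(4, seed = 11)
  expect_identical(coh1$counts, coh2$counts)

  tx1 <- simulate_transcriptome(5, 100, seed = 3)
  tx2 <- simulate_transcriptome(5, 100, seed = 3)
  expect_identical(tx1$utrs, tx2$utrs)
})

test_that("reference round-trips through FASTA + TSV byte-identically", {
  ref <- make_mirna_reference(10, seed = 5)
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  write_mirna_reference(ref, fa, tsv)
  back <- read_mirna_reference(fa, tsv)
  expect_identical(back$precursors, ref$precursors)
  expect_identical(back$matures, ref$matures)
})

test_that("read simulator respects editing fraction and conservation", {
  ref <- make_mirna_reference(3, seed = 2)
  ms <- names(mature_sequences(ref))
  # fraction 1, zero error, all canonical: every read has G at position 6
  d1 <- sample_design("S", abundance = setNames(c(1, 0, 0), ms),
                      editing_fraction = setNames(1, ms[1]),
                      isomir_profile = c(canonical = 1, shift5 = 0,
                                         shift3 = 0, tail = 0),
                      n_reads = 100, error_rate = 0)
  sim1 <- simulate_small_rna_sample(ref, d1, seed = 9)
  expect_true(all(substr(sim1$reads, 6, 6) == "G"))
  expect_length(sim1$reads, 100)
  expect_equal(sum(sim1$truth$n_reads), 100)

  # all mass on canonical, no edit: reads equal the mature sequence
  d2 <- sample_design("S", abundance = setNames(c(1, 0, 0), ms),
                      isomir_profile = c(canonical = 1, shift5 = 0,
                                         shift3 = 0, tail = 0),
                      n_reads = 50, error_rate = 0)
  sim2 <- simulate_small_rna_sample(ref, d2, seed = 9)
  expect_true(all(sim2$reads == mature_sequences(ref)[[1]]))

  # fraction 0.4 at n = 10000: within 3 binomial SDs of 4000
  d3 <- sample_design("S", abundance = setNames(c(1, 0, 0), ms),
                      editing_fraction = setNames(0.4, ms[1]),
                      n_reads = 10000, error_rate = 0)
  sim3 <- simulate_small_rna_sample(ref, d3, seed = 4)
  sd3 <- sqrt(10000 * 0.4 * 0.6)
  expect_lt(abs(sim3$truth$n_edited[1] - 4000), 3 * sd3)

  # unknown mature in the design is a reference mismatch
  d4 <- sample_design("S", abundance = c(nope = 1))
  expect_error(simulate_small_rna_sample(ref, d4, seed = 1), "absent")
})

test_that("paired cohort plants the configured class effect", {
  # null design: per-feature mean log2(C/P) centered at 0
  coh0 <- simulate_paired_cohort(10, effects = list(n_planted = 0), seed = 21)
  fc0 <- paired_log2fc(coh0$counts, coh0$metadata)
  expect_lt(abs(mean(fc0$mean_log2fc)), 0.05)

  coh <- simulate_paired_cohort(10, effects = list(n_planted = 5,
                                                   log2_effect = 2), seed = 8)
  expect_length(coh$truth$planted, 5)
  fc <- paired_log2fc(coh$counts, coh$metadata)
  planted_fc <- fc$mean_log2fc[coh$truth$planted]
  expect_true(all(planted_fc >= 1 & planted_fc <= 3))
  expect_error(simulate_paired_cohort(10, effects = list(dispersion = 0),
                                      seed = 1), "dispersion")
})

test_that("every simulated transcript anchors a full tag at its 3'-most CATG", {
  tx <- simulate_transcriptome(10, 200, seed = 3)
  for (u in tx$utrs) {
    hits <- gregexpr("CATG", u, fixed = TRUE)[[1]]
    expect_true(any(hits > 0))
    expect_gte(nchar(u) - max(hits) + 1, 27)
  }
  expect_error(simulate_transcriptome(5, 39, seed = 1), "utr_length")
})

test_that("planted seed sites are recorded and present in the sequence", {
  ps <- data.frame(transcript = 1L, position = 10L, type = "8mer",
                   seed = "ACATAGA", stringsAsFactors = FALSE)
  tx <- simulate_transcriptome(3, 120, planted_sites = ps, seed = 6)
  expect_identical(tx$truth$planted_sites, ps)
  hits <- scan_utr(tx$utrs[[1]], "ACATAGA")
  expect_true(any(hits$type == "8mer" & hits$start == 10))
})

test_that("subtype gene sets are disjoint and GMT round-trips", {
  sets <- make_subtype_gene_sets(4, 50, seed = 1)
  expect_length(sets, 4)
  expect_true(all(lengths(sets) == 50))
  expect_equal(anyDuplicated(unlist(sets)), 0)
  gmt <- tempfile(fileext = ".gmt")
  write_gmt(sets, gmt)
  back <- read_gmt(gmt)
  expect_identical(back, stats::setNames(lapply(sets, identity), names(sets)))
  expect_error(make_subtype_gene_sets(4, 50, seed = 1, universe = letters),
               "too small")
})

test_that("subtype profile simulator shifts exactly the planted signature", {
  sets <- make_subtype_gene_sets(3, 30, seed = 2)
  prof <- simulate_subtype_profiles(sets, 10, shift = 5, seed = 4)
  expect_equal(dim(prof$expr), c(length(attr(sets, "universe")), 10))
  for (j in 1:10) {
    true_set <- sets[[prof$truth[j]]]
    in_mean <- mean(prof$expr[true_set, j])
    out_mean <- mean(prof$expr[setdiff(rownames(prof$expr), true_set), j])
    expect_gt(in_mean - out_mean, 3)
  }
})
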