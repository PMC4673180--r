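#' Default end-to-end pipeline configuration
#'
#' Every tunable parameter of every stage appears here explicitly with its
#' default, so a run's manifest records the full parameterization. The
#' defaults describe the simulated study: 10 paired tumor-center /
#' peritumor small-RNA samples at 50,000 reads each over 30 miRNAs, a
#' planted A-to-G edit at mature position 6 of the first miRNA with edited
#' fractions 0.15 (C) vs 0.45 (P), 5 planted C-vs-P differential miRNAs at
#' log2 effect 2, 3+3 miRNAs up-/down-modulated in every tumor sample vs
#' the healthy control (log2 effect 3, the shared-signature structure), an
#' expression cohort for subtype calling, and a SAGE transcript set.
#'
#' @param seed master seed for the whole run.
#' @param out_dir output directory.
#' @param ... overrides for any default listed below.
#' @return named list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L, out_dir = "pipeline_out", ...) {
  cfg <- list(
    seed = seed, out_dir = out_dir,
    # simulate
    n_mirnas = 30L, n_pairs = 10L, n_reads = 50000L, error_rate = 0.001,
    editing_fraction_c = 0.15, editing_fraction_p = 0.45,
    isomir_profile = c(canonical = 0.7, shift5 = 0.1, shift3 = 0.1, tail = 0.1),
    n_planted_mirnas = 5L, planted_log2_effect = 2,
    n_shared_up = 3L, n_shared_down = 3L, shared_log2_effect = 3,
    # isomir
    window = 3L, max_mismatch = 1L,
    edit = list(position = 6L, ref = "A", alt = "G"),
    # normalization / filters
    logratio_trim = 0.30, abs_trim = 0.05,
    min_cpm = 10, min_pairs = 4L, pseudocount = 1,
    # diffexp
    n_perm = 10000L, fdr_threshold = 0.05, fc_threshold = 1.5,
    # ranking
    relieff_k = 10L, top_n = 50L,
    # subtype
    n_subtypes = 4L, genes_per_set = 50L, n_profiles = 20L,
    subtype_shift = 2, ssgsea_alpha = 0.75,
    # sage
    n_transcripts = 50L, utr_length = 300L, tag_length = 27L,
    sage_reads_per_transcript = 40L)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown))
    stop_invalid("unknown config keys: %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, override)
  structure(cfg, class = c("pipeline_config", "list"))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes, in dependency order: simulate (miRNA reference, paired
#' small-RNA samples, a healthy-control sample, subtype profiles, SAGE
#' transcriptome and reads) -> isomiR calling -> TMM/cpm normalization and
#' the paired cpm filter -> paired sign-flip differential expression and
#' the vs-control +/-1.5 log2FC signature -> editing summary and pooled
#' two-proportion tests (C vs P, and ST vs LT on C samples) -> ReliefF
#' leave-one-out ranking with heatmap export -> ssGSEA subtype calls ->
#' SAGE tag counting -> seed target-shift analysis. A stage failure aborts
#' the downstream stages and is recorded as a typed error in the manifest.
#'
#' All result tables are written under `config$out_dir`; the manifest
#' (JSON) records the config, package version, per-stage output paths,
#' output checksums and wall times. Two runs from one config byte-match on
#' every table.
#'
#' @param config a `pipeline_config` from [default_config()].
#' @return the manifest, invisibly (list of class `run_manifest`).
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config[setdiff(names(config), "out_dir")],
                   package_version = as.character(utils::packageVersion("gbmirnome")),
                   stages = list())
  state <- new.env(parent = emptyenv())
  stages <- c("simulate", "isomir", "normalize", "diffexp", "editing",
              "rank", "subtype", "sage", "targets")
  failed <- NULL
  for (st in stages) {
    if (!is.null(failed)) {
      manifest$stages[[st]] <- list(status = "skipped",
                                    reason = sprintf("upstream stage '%s' failed", failed))
      next
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      do.call(paste0("stage_", st), list(config, state)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed <- st
      manifest$stages[[st]] <- list(status = "error",
                                    error = conditionMessage(res))
    } else {
      manifest$stages[[st]] <- c(
        list(status = "ok",
             wall_time_s = round(proc.time()[["elapsed"]] - t0, 3)), res)
    }
  }
  outputs <- unlist(lapply(manifest$stages, function(s) s$outputs))
  if (is.null(outputs)) outputs <- character(0)
  manifest$output_md5 <- as.list(tools::md5sum(outputs[file.exists(outputs)]))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(structure(manifest, class = "run_manifest"))
}

stage_simulate <- function(cfg, st) {
  st$ref <- make_mirna_reference(cfg$n_mirnas, seed = cfg$seed)
  mats <- st$ref$matures$mature_name
  st$target <- st$ref$editable[1]
  n_special <- 1L + cfg$n_planted_mirnas + cfg$n_shared_up + cfg$n_shared_down
  if (n_special > cfg$n_mirnas)
    stop_invalid(paste("n_mirnas (%d) too small for 1 editing target +",
                       "%d planted + %d shared miRNAs"),
                 cfg$n_mirnas, cfg$n_planted_mirnas,
                 cfg$n_shared_up + cfg$n_shared_down)
  with_seed(derive_seed(cfg$seed, "abundance"), {
    base_w <- stats::rlnorm(length(mats), 0, 1)
    planted <- sample(setdiff(seq_along(mats), 1), cfg$n_planted_mirnas)
    shared <- sample(setdiff(seq_along(mats), c(1, planted)),
                     cfg$n_shared_up + cfg$n_shared_down)
  })
  names(base_w) <- mats
  eff <- numeric(length(mats)); eff[planted] <- cfg$planted_log2_effect
  # miRNAs modulated in every tumor sample (C and P) vs the healthy
  # control, emulating the shared tumor/peritumor signature
  shared_eff <- numeric(length(mats))
  shared_eff[shared] <- rep(c(cfg$shared_log2_effect,
                              -cfg$shared_log2_effect),
                            c(cfg$n_shared_up, cfg$n_shared_down))
  st$planted_mirnas <- mats[planted]
  st$shared_up <- mats[shared[seq_len(cfg$n_shared_up)]]
  st$shared_down <- mats[shared[cfg$n_shared_up + seq_len(cfg$n_shared_down)]]
  designs <- list()
  for (p in seq_len(cfg$n_pairs)) {
    pid <- sprintf("P%02d", p)
    surv <- if (p <= ceiling(cfg$n_pairs * 0.7)) "ST" else "LT"
    for (reg in c("C", "P")) {
      w <- base_w * 2^(shared_eff + if (reg == "C") eff / 2 else -eff / 2)
      ef <- stats::setNames(
        if (reg == "C") cfg$editing_fraction_c else cfg$editing_fraction_p,
        st$target)
      designs[[paste0(pid, "_", reg)]] <- sample_design(
        sample_id = paste0(pid, "_", reg), abundance = w,
        editing_fraction = ef, isomir_profile = cfg$isomir_profile,
        n_reads = cfg$n_reads, error_rate = cfg$error_rate,
        patient_id = pid, region = reg, survival = surv)
    }
  }
  st$designs <- designs
  st$samples <- lapply(designs, function(d)
    simulate_small_rna_sample(st$ref, d, seed = cfg$seed, edit = cfg$edit))
  # one unpaired healthy-control small-RNA sample (baseline weights)
  hc_design <- sample_design(
    sample_id = "HC", abundance = base_w,
    editing_fraction = stats::setNames(cfg$editing_fraction_p, st$target),
    isomir_profile = cfg$isomir_profile, n_reads = cfg$n_reads,
    error_rate = cfg$error_rate, patient_id = "HC", region = "HC",
    survival = "HC")
  st$samples$HC <- simulate_small_rna_sample(st$ref, hc_design,
                                             seed = cfg$seed, edit = cfg$edit)
  st$metadata <- data.frame(
    sample_id = names(designs),
    patient = vapply(designs, function(d) d$patient_id, character(1)),
    region = vapply(designs, function(d) d$region, character(1)),
    survival = vapply(designs, function(d) d$survival, character(1)),
    stringsAsFactors = FALSE)
  st$gene_sets <- make_subtype_gene_sets(cfg$n_subtypes, cfg$genes_per_set,
                                         seed = cfg$seed)
  st$profiles <- simulate_subtype_profiles(st$gene_sets, cfg$n_profiles,
                                           shift = cfg$subtype_shift,
                                           seed = cfg$seed)
  st$transcriptome <- simulate_transcriptome(cfg$n_transcripts,
                                             cfg$utr_length, seed = cfg$seed)
  st$sage <- simulate_sage_reads(
    st$transcriptome$utrs,
    stats::setNames(rep(cfg$sage_reads_per_transcript, cfg$n_transcripts),
                    names(st$transcriptome$utrs)),
    tag_length = cfg$tag_length, seed = cfg$seed,
    error_rate = cfg$error_rate)
  ref_fa <- file.path(cfg$out_dir, "precursors.fasta")
  ref_tsv <- file.path(cfg$out_dir, "matures.tsv")
  write_mirna_reference(st$ref, ref_fa, ref_tsv)
  meta_tsv <- write_tsv(st$metadata, file.path(cfg$out_dir, "metadata.tsv"))
  list(outputs = c(ref_fa, ref_tsv, meta_tsv),
       n_samples = length(st$samples),
       planted_mirnas = st$planted_mirnas,
       shared_up = st$shared_up, shared_down = st$shared_down,
       editing_target = st$target)
}

stage_isomir <- function(cfg, st) {
  index <- build_mirna_index(st$ref, window = cfg$window)
  st$tables <- lapply(names(st$samples), function(s)
    summarize_sample(st$samples[[s]]$reads, index,
                     max_mismatch = cfg$max_mismatch, edit = cfg$edit,
                     sample_id = s))
  names(st$tables) <- names(st$samples)
  mats <- st$ref$matures$mature_name
  st$counts <- vapply(st$tables, function(t) {
    v <- stats::setNames(numeric(length(mats)), mats)
    v[names(t$grouped)] <- t$grouped
    v
  }, numeric(length(mats)))
  variants <- do.call(rbind, lapply(names(st$tables), function(s)
    cbind(sample = s, st$tables[[s]]$variants, stringsAsFactors = FALSE)))
  v_tsv <- write_tsv(variants, file.path(cfg$out_dir, "isomir_variants.tsv"))
  c_tsv <- write_count_matrix(st$counts,
                              file.path(cfg$out_dir, "grouped_counts.tsv"),
                              id_col = "mature_name")
  list(outputs = c(v_tsv, c_tsv),
       reads_assigned = sum(vapply(st$tables, function(t) t$total - t$unassigned,
                                   numeric(1))),
       reads_total = sum(vapply(st$tables, function(t) t$total, numeric(1))))
}

stage_normalize <- function(cfg, st) {
  st$factors <- tmm_factors(st$counts, logratio_trim = cfg$logratio_trim,
                            abs_trim = cfg$abs_trim)
  st$cpm <- cpm_matrix(st$counts, st$factors)
  paired_cols <- st$metadata$sample_id
  pair_of <- stats::setNames(st$metadata$patient, st$metadata$sample_id)
  st$kept <- filter_by_cpm(st$cpm[, paired_cols, drop = FALSE],
                           min_cpm = cfg$min_cpm, min_samples = cfg$min_pairs,
                           pair_rule = TRUE, pairs = pair_of)
  f_tsv <- write_tsv(data.frame(sample = names(st$factors),
                                factor = unname(st$factors)),
                     file.path(cfg$out_dir, "tmm_factors.tsv"))
  cpm_tsv <- write_count_matrix(round(st$cpm, 6),
                                file.path(cfg$out_dir, "cpm.tsv"),
                                id_col = "mature_name")
  kept_txt <- file.path(cfg$out_dir, "filtered_mirnas.txt")
  writeLines(st$kept, kept_txt)
  list(outputs = c(f_tsv, cpm_tsv, kept_txt), n_kept = length(st$kept))
}

stage_diffexp <- function(cfg, st) {
  cpm_pairs <- st$cpm[st$kept, st$metadata$sample_id, drop = FALSE]
  st$fc <- paired_log2fc(cpm_pairs, st$metadata, pseudocount = cfg$pseudocount)
  st$dt <- paired_permutation_test(st$fc, n_perm = cfg$n_perm, seed = cfg$seed)
  # vs healthy control, per survival x region group
  groups <- split(st$metadata$sample_id,
                  paste0(st$metadata$survival, st$metadata$region))
  st$vs_hc <- group_vs_control_fc(st$cpm, groups, control = "HC",
                                  pseudocount = cfg$pseudocount)
  st$signature <- select_shared_modulated(st$vs_hc, threshold = cfg$fc_threshold)
  de_tsv <- write_tsv(
    cbind(st$dt, mean_log2fc = st$fc$mean_log2fc[st$dt$feature]),
    file.path(cfg$out_dir, "diffexp_paired.tsv"))
  fc_tsv <- write_count_matrix(round(st$vs_hc, 6),
                               file.path(cfg$out_dir, "log2fc_vs_control.tsv"),
                               id_col = "mature_name")
  sig_over <- file.path(cfg$out_dir, "signature_overexpressed.txt")
  sig_under <- file.path(cfg$out_dir, "signature_underexpressed.txt")
  writeLines(st$signature$overexpressed, sig_over)
  writeLines(st$signature$underexpressed, sig_under)
  list(outputs = c(de_tsv, fc_tsv, sig_over, sig_under),
       n_significant = sum(st$dt$fdr < cfg$fdr_threshold),
       n_over = length(st$signature$overexpressed),
       n_under = length(st$signature$underexpressed))
}

stage_editing <- function(cfg, st) {
  st$editing <- editing_table(st$tables, st$target, edit = cfg$edit,
                              normalizer = st$factors,
                              known = st$ref$matures$mature_name)
  grouping_cp <- stats::setNames(st$metadata$region, st$metadata$sample_id)
  st$test_cp <- two_proportion_test(pool_counts(
    st$editing[st$editing$sample != "HC", ], grouping_cp))
  c_meta <- st$metadata[st$metadata$region == "C", ]
  grouping_st_lt <- stats::setNames(c_meta$survival, c_meta$sample_id)
  st$test_st_lt <- two_proportion_test(pool_counts(
    st$editing[st$editing$sample %in% c_meta$sample_id, ], grouping_st_lt))
  ed_df <- st$editing
  ed_df$percent_edited <- round(100 * ed_df$fraction, 3)
  ed_tsv <- write_tsv(ed_df, file.path(cfg$out_dir, "editing_summary.tsv"))
  test_json <- file.path(cfg$out_dir, "editing_tests.json")
  jsonlite::write_json(list(
    C_vs_P = unclass(st$test_cp)[c("statistic", "df", "p_value",
                                   "proportions", "pooled")],
    STC_vs_LTC = unclass(st$test_st_lt)[c("statistic", "df", "p_value",
                                          "proportions", "pooled")]),
    test_json, auto_unbox = TRUE, digits = NA)
  list(outputs = c(ed_tsv, test_json),
       chisq_c_vs_p = st$test_cp$statistic,
       chisq_stc_vs_ltc = st$test_st_lt$statistic)
}

stage_rank <- function(cfg, st) {
  x <- log2(st$cpm[st$kept, st$metadata$sample_id, drop = FALSE] + 1)
  st$ranking <- loocv_average_merit(x, st$metadata$region, k = cfg$relieff_k)
  st$heatmap <- export_heatmap(st$cpm[st$kept, , drop = FALSE], st$ranking,
                               st$metadata, top_n = min(cfg$top_n, length(st$kept)),
                               pseudocount = cfg$pseudocount)
  rk_tsv <- write_tsv(data.frame(
    mature_name = names(st$ranking$average_merit),
    average_merit = unname(st$ranking$average_merit),
    rank = unname(st$ranking$rank)),
    file.path(cfg$out_dir, "relieff_ranking.tsv"))
  hm_paths <- vapply(c("all", "underexpressed", "overexpressed"), function(p) {
    m <- st$heatmap[[p]]
    write_count_matrix(round(m, 6),
                       file.path(cfg$out_dir, sprintf("heatmap_%s.tsv", p)),
                       id_col = "mature_name")
  }, character(1))
  list(outputs = c(rk_tsv, unname(hm_paths)),
       top_feature = names(which.min(st$ranking$rank)))
}

stage_subtype <- function(cfg, st) {
  st$calls <- classify_samples(st$profiles$expr, st$gene_sets,
                               alpha = cfg$ssgsea_alpha)
  sc_tsv <- write_count_matrix(round(t(st$calls$scores), 6),
                               file.path(cfg$out_dir, "ssgsea_scores.tsv"),
                               id_col = "gene_set")
  calls_df <- st$calls$calls
  calls_df$truth <- st$profiles$truth[calls_df$sample]
  calls_tsv <- write_tsv(calls_df, file.path(cfg$out_dir, "subtype_calls.tsv"))
  list(outputs = c(sc_tsv, calls_tsv),
       accuracy = mean(calls_df$subtype == calls_df$truth))
}

stage_sage <- function(cfg, st) {
  idx <- extract_reference_tags(st$transcriptome$utrs, cfg$tag_length)
  st$tag_counts <- count_tags(st$sage$reads, idx,
                              max_mismatch = cfg$max_mismatch)
  counts_tsv <- file.path(cfg$out_dir, "sage_counts.tsv")
  summary_json <- file.path(cfg$out_dir, "sage_discards.json")
  write_tag_counts(st$tag_counts, counts_tsv, summary_json)
  list(outputs = c(counts_tsv, summary_json),
       reads_counted = sum(st$tag_counts$counts))
}

stage_targets <- function(cfg, st) {
  mature <- mature_sequences(st$ref)[[st$target]]
  seed_un <- make_seed(mature, mature_name = st$target)
  seed_ed <- make_seed(mature, edit = cfg$edit, mature_name = st$target)
  hits_un <- scan_transcripts(st$transcriptome$utrs, seed_un)
  hits_ed <- scan_transcripts(st$transcriptome$utrs, seed_ed)
  st$shift <- compare_target_sets(hits_un, hits_ed)
  out_json <- file.path(cfg$out_dir, "target_shift.json")
  jsonlite::write_json(unclass(st$shift), out_json, auto_unbox = TRUE,
                       digits = NA)
  list(outputs = out_json,
       n_lost = length(st$shift$lost), n_gained = length(st$shift$gained),
       n_both = length(st$shift$both), jaccard = st$shift$jaccard)
}
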