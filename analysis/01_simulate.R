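#!/usr/bin/env Rscript
# Simulate the study cohort: a miRNA reference with an editable position-6
# adenosine, 10 paired tumor-center (C) / peritumor (P) small-RNA samples
# plus one healthy-control sample, subtype expression profiles, and a
# CATG-anchored 3'UTR transcriptome with SAGE reads. Everything downstream
# (02-05) reads from results/run/.
#
# This driver is a thin wrapper over run_pipeline()'s simulate stage: it
# writes the reference, metadata and reads so that each later script can
# be re-run independently.

library(gbmirnome)

seed <- 1L
out <- "results/run"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- default_config(seed = seed, out_dir = out)
ref <- make_mirna_reference(cfg$n_mirnas, seed = seed)
write_mirna_reference(ref, file.path(out, "precursors.fasta"),
                      file.path(out, "matures.tsv"))

target <- ref$editable[1]
cat(sprintf("reference: %d miRNAs; editing target %s (A at mature position %d)\n",
            cfg$n_mirnas, target, cfg$edit$position))

# per-sample designs: shared baseline abundances, five planted C/P
# differential miRNAs, edited fractions 0.15 (C) vs 0.45 (P)
mats <- ref$matures$mature_name
set.seed(seed)
base_w <- stats::setNames(stats::rlnorm(length(mats), 0, 1), mats)
planted <- sample(setdiff(seq_along(mats), 1), cfg$n_planted_mirnas)
shared <- sample(setdiff(seq_along(mats), c(1, planted)),
                 cfg$n_shared_up + cfg$n_shared_down)
eff <- numeric(length(mats)); eff[planted] <- cfg$planted_log2_effect
shared_eff <- numeric(length(mats))
shared_eff[shared] <- rep(c(cfg$shared_log2_effect, -cfg$shared_log2_effect),
                          c(cfg$n_shared_up, cfg$n_shared_down))

meta <- NULL
for (p in seq_len(cfg$n_pairs)) {
  pid <- sprintf("P%02d", p)
  surv <- if (p <= ceiling(cfg$n_pairs * 0.7)) "ST" else "LT"
  for (reg in c("C", "P")) {
    id <- paste0(pid, "_", reg)
    d <- sample_design(
      id,
      abundance = base_w * 2^(shared_eff +
                                if (reg == "C") eff / 2 else -eff / 2),
      editing_fraction = stats::setNames(
        if (reg == "C") cfg$editing_fraction_c else cfg$editing_fraction_p,
        target),
      n_reads = cfg$n_reads, error_rate = cfg$error_rate,
      patient_id = pid, region = reg, survival = surv)
    sim <- simulate_small_rna_sample(ref, d, seed = seed, edit = cfg$edit)
    write_reads_fastq(sim$reads, file.path(out, paste0(id, ".fastq")))
    meta <- rbind(meta, data.frame(sample_id = id, patient = pid,
                                   region = reg, survival = surv))
  }
}
hc <- sample_design("HC", abundance = base_w,
                    editing_fraction = stats::setNames(
                      cfg$editing_fraction_p, target),
                    n_reads = cfg$n_reads, error_rate = cfg$error_rate,
                    patient_id = "HC", region = "HC", survival = "HC")
sim_hc <- simulate_small_rna_sample(ref, hc, seed = seed, edit = cfg$edit)
write_reads_fastq(sim_hc$reads, file.path(out, "HC.fastq"))
utils::write.table(meta, file.path(out, "metadata.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
writeLines(c(target, mats[planted]), file.path(out, "truth_planted.txt"))
writeLines(c(paste("up", mats[shared[seq_len(cfg$n_shared_up)]]),
             paste("down", mats[shared[cfg$n_shared_up +
                                         seq_len(cfg$n_shared_down)]])),
           file.path(out, "truth_shared.txt"))
cat(sprintf("simulated %d paired samples + HC at %d reads each; planted C/P miRNAs: %s\n",
            2 * cfg$n_pairs, cfg$n_reads,
            paste(mats[planted], collapse = ", ")))

# subtype profiles and SAGE substrate
sets <- make_subtype_gene_sets(cfg$n_subtypes, cfg$genes_per_set, seed = seed)
write_gmt(sets, file.path(out, "subtype_sets.gmt"))
prof <- simulate_subtype_profiles(sets, cfg$n_profiles,
                                  shift = cfg$subtype_shift, seed = seed)
write_count_matrix(round(prof$expr, 6), file.path(out, "expression.tsv"),
                   id_col = "gene")
utils::write.table(
  data.frame(sample = names(prof$truth), subtype = unname(prof$truth)),
  file.path(out, "subtype_truth.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

tx <- simulate_transcriptome(cfg$n_transcripts, cfg$utr_length, seed = seed)
write_fasta_seqs(tx$utrs, file.path(out, "utrs.fasta"))
sage <- simulate_sage_reads(
  tx$utrs,
  stats::setNames(rep(cfg$sage_reads_per_transcript, cfg$n_transcripts),
                  names(tx$utrs)),
  tag_length = cfg$tag_length, seed = seed, error_rate = cfg$error_rate)
write_reads_fastq(sage$reads, file.path(out, "sage_reads.fastq"))
cat("simulation inputs written to", out, "\n")
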