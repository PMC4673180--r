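#!/usr/bin/env Rscript
# Call isomiRs on every simulated sample, build the grouped miRNA count
# matrix, TMM-normalize it and apply the paired cpm filter (cpm >= 10 in
# at least one member of more than 4 of the 10 C/P pairs).

library(gbmirnome)

out <- "results/run"
ref <- read_mirna_reference(file.path(out, "precursors.fasta"),
                            file.path(out, "matures.tsv"))
meta <- utils::read.delim(file.path(out, "metadata.tsv"),
                          stringsAsFactors = FALSE)
cfg <- default_config()
idx <- build_mirna_index(ref, window = cfg$window)

samples <- c(meta$sample_id, "HC")
tables <- lapply(samples, function(s) {
  reads <- read_reads(file.path(out, paste0(s, ".fastq")))
  summarize_sample(reads, idx, max_mismatch = cfg$max_mismatch,
                   edit = cfg$edit, sample_id = s)
})
names(tables) <- samples
assigned <- vapply(tables, function(t) t$total - t$unassigned, numeric(1))
cat(sprintf("assigned %.2f%% of reads overall\n",
            100 * sum(assigned) / sum(vapply(tables, `[[`, numeric(1), "total"))))

mats <- ref$matures$mature_name
counts <- vapply(tables, function(t) {
  v <- stats::setNames(numeric(length(mats)), mats)
  v[names(t$grouped)] <- t$grouped
  v
}, numeric(length(mats)))
write_count_matrix(counts, file.path(out, "grouped_counts.tsv"),
                   id_col = "mature_name")
dir.create("scratch", showWarnings = FALSE)
saveRDS(tables, "scratch/isomir_tables.rds")  # large intermediate, not shipped

f <- tmm_factors(counts, logratio_trim = cfg$logratio_trim,
                 abs_trim = cfg$abs_trim)
cpm <- cpm_matrix(counts, f)
write_count_matrix(round(cpm, 6), file.path(out, "cpm.tsv"),
                   id_col = "mature_name")
utils::write.table(data.frame(sample = names(f), factor = unname(f)),
                   file.path(out, "tmm_factors.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

kept <- filter_by_cpm(cpm[, meta$sample_id], min_cpm = cfg$min_cpm,
                      min_samples = cfg$min_pairs, pair_rule = TRUE,
                      pairs = stats::setNames(meta$patient, meta$sample_id))
writeLines(kept, file.path(out, "filtered_mirnas.txt"))
cat(sprintf("TMM factors in [%.3f, %.3f]; %d of %d miRNAs pass the paired cpm filter\n",
            min(f), max(f), length(kept), nrow(counts)))
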