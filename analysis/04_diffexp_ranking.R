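#!/usr/bin/env Rscript
# Paired C/P differential expression (sign-flip permutation test with BH
# FDR), the vs-healthy-control +/-1.5 log2FC shared signature, ReliefF
# leave-one-out merit ranking and the top-feature heatmap matrices, and
# ssGSEA subtype calls for the expression cohort.

library(gbmirnome)

out <- "results/run"
meta <- utils::read.delim(file.path(out, "metadata.tsv"),
                          stringsAsFactors = FALSE)
cpm <- read_count_matrix(file.path(out, "cpm.tsv"))
kept <- readLines(file.path(out, "filtered_mirnas.txt"))
planted <- readLines(file.path(out, "truth_planted.txt"))[-1]
cfg <- default_config()

## paired differential expression on filtered, TMM-normalized cpm
fc <- paired_log2fc(cpm[kept, meta$sample_id], meta,
                    pseudocount = cfg$pseudocount)
dt <- paired_permutation_test(fc, n_perm = cfg$n_perm, seed = cfg$seed)
dt$mean_log2fc <- fc$mean_log2fc[dt$feature]
utils::write.table(dt, file.path(out, "diffexp_paired.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
sig <- dt$feature[dt$fdr < cfg$fdr_threshold]
cat(sprintf("paired test: %d/%d miRNAs at FDR < %.2f; planted recovered: %d/%d\n",
            length(sig), nrow(dt), cfg$fdr_threshold,
            sum(planted %in% sig), length(planted)))

## shared modulation vs the healthy control
groups <- split(meta$sample_id, paste0(meta$survival, meta$region))
vs_hc <- group_vs_control_fc(cpm, groups, control = "HC",
                             pseudocount = cfg$pseudocount)
sel <- select_shared_modulated(vs_hc, threshold = cfg$fc_threshold)
write_count_matrix(round(vs_hc, 6), file.path(out, "log2fc_vs_control.tsv"),
                   id_col = "mature_name")
writeLines(sel$overexpressed, file.path(out, "signature_overexpressed.txt"))
writeLines(sel$underexpressed, file.path(out, "signature_underexpressed.txt"))
cat(sprintf("shared signature vs control: %d over-, %d underexpressed\n",
            length(sel$overexpressed), length(sel$underexpressed)))

## ReliefF merit ranking with LOOCV and heatmap export
x <- log2(cpm[kept, meta$sample_id] + 1)
mr <- loocv_average_merit(x, meta$region, k = cfg$relieff_k)
utils::write.table(
  data.frame(mature_name = names(mr$average_merit),
             average_merit = unname(mr$average_merit),
             rank = unname(mr$rank)),
  file.path(out, "relieff_ranking.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
hm <- export_heatmap(cpm[kept, ], mr, meta,
                     top_n = min(cfg$top_n, length(kept)),
                     pseudocount = cfg$pseudocount)
for (p in c("all", "underexpressed", "overexpressed"))
  write_count_matrix(round(hm[[p]], 6),
                     file.path(out, sprintf("heatmap_%s.tsv", p)),
                     id_col = "mature_name")
cat(sprintf("ReliefF: planted miRNAs in top-10 average merit: %d/%d\n",
            sum(mr$rank[planted] <= 10), length(planted)))

## ssGSEA subtype calls for the simulated expression cohort
expr <- read_count_matrix(file.path(out, "expression.tsv"))
sets <- read_gmt(file.path(out, "subtype_sets.gmt"))
truth <- with(utils::read.delim(file.path(out, "subtype_truth.tsv")),
              stats::setNames(subtype, sample))
cls <- classify_samples(expr, sets, alpha = cfg$ssgsea_alpha)
calls <- cls$calls
calls$truth <- truth[calls$sample]
utils::write.table(calls, file.path(out, "subtype_calls.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_count_matrix(round(t(cls$scores), 6),
                   file.path(out, "ssgsea_scores.tsv"), id_col = "gene_set")
cat(sprintf("ssGSEA subtype accuracy: %.2f\n",
            mean(calls$subtype == calls$truth)))
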