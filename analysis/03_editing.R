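#!/usr/bin/env Rscript
# Quantify the A-to-G edited fraction of the target miRNA per sample and
# test equality of pooled edited proportions: tumor centers vs peritumor
# areas, and short-term vs long-term survivor centers.

library(gbmirnome)

out <- "results/run"
ref <- read_mirna_reference(file.path(out, "precursors.fasta"),
                            file.path(out, "matures.tsv"))
meta <- utils::read.delim(file.path(out, "metadata.tsv"),
                          stringsAsFactors = FALSE)
target <- readLines(file.path(out, "truth_planted.txt"))[1]
tables <- readRDS("scratch/isomir_tables.rds")
factors <- with(utils::read.delim(file.path(out, "tmm_factors.tsv")),
                stats::setNames(factor, sample))
cfg <- default_config()

et <- editing_table(tables, target, edit = cfg$edit, normalizer = factors,
                    known = ref$matures$mature_name)
et$percent_edited <- round(100 * et$fraction, 2)
utils::write.table(et, file.path(out, "editing_summary.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

cp <- stats::setNames(meta$region, meta$sample_id)
test_cp <- two_proportion_test(pool_counts(et[et$sample != "HC", ], cp))
cat("C vs P pooled edited proportions:\n")
print(test_cp)

c_meta <- meta[meta$region == "C", ]
st_lt <- stats::setNames(c_meta$survival, c_meta$sample_id)
test_st <- two_proportion_test(pool_counts(
  et[et$sample %in% c_meta$sample_id, ], st_lt))
cat("\nSTC vs LTC pooled edited proportions:\n")
print(test_st)

jsonlite::write_json(list(
  C_vs_P = unclass(test_cp)[c("statistic", "df", "p_value", "proportions")],
  STC_vs_LTC = unclass(test_st)[c("statistic", "df", "p_value", "proportions")]),
  file.path(out, "editing_tests.json"), auto_unbox = TRUE, digits = NA)
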