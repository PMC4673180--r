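#!/usr/bin/env Rscript
# SAGE tag counting against the simulated 3'UTR reference, and the
# seed-site target-shift analysis of the edited vs unedited target miRNA.

library(gbmirnome)

out <- "results/run"
cfg <- default_config()
utrs <- read_fasta_seqs(file.path(out, "utrs.fasta"))
reads <- read_reads(file.path(out, "sage_reads.fastq"))
idx <- extract_reference_tags(utrs, cfg$tag_length)
cnt <- count_tags(reads, idx, max_mismatch = cfg$max_mismatch)
write_tag_counts(cnt, file.path(out, "sage_counts.tsv"),
                 file.path(out, "sage_discards.json"))
cat(sprintf("SAGE: %d/%d reads counted; discards: %s\n",
            sum(cnt$counts), cnt$total,
            paste(sprintf("%s=%d", names(cnt$discarded), cnt$discarded),
                  collapse = ", ")))

ref <- read_mirna_reference(file.path(out, "precursors.fasta"),
                            file.path(out, "matures.tsv"))
target <- readLines(file.path(out, "truth_planted.txt"))[1]
mat <- mature_sequences(ref)[[target]]
seed_un <- make_seed(mat, mature_name = target)
seed_ed <- make_seed(mat, edit = cfg$edit, mature_name = target)
cat(sprintf("seed %s: unedited %s -> edited %s\n",
            target, seed_un$seed, seed_ed$seed))
shift <- compare_target_sets(scan_transcripts(utrs, seed_un),
                             scan_transcripts(utrs, seed_ed))
jsonlite::write_json(unclass(shift), file.path(out, "target_shift.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("target shift: %d lost, %d gained, %d shared (Jaccard %.3f)\n",
            length(shift$lost), length(shift$gained), length(shift$both),
            ifelse(is.na(shift$jaccard), NA, shift$jaccard)))
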