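#' Read and write the plain-text formats used across the pipeline
#'
#' Count matrices are TSV with the feature id in the first column and one
#' column per sample; gene sets are GMT (set name, description, then genes,
#' tab separated); mature-miRNA annotation is TSV with 1-based inclusive
#' coordinates on the precursor.
#'
#' @param path file path.
#' @name pipeline-io
NULL

#' @describeIn pipeline-io Read a feature-by-sample count matrix from TSV.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @describeIn pipeline-io Write a count matrix to TSV.
#' @param m matrix with feature rownames and sample colnames.
#' @param id_col name of the feature-id column.
#' @export
write_count_matrix <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn pipeline-io Read a GMT gene-set file into a named list.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop_invalid("malformed GMT line: %s", l)
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' @describeIn pipeline-io Write a named list of gene sets to GMT.
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @describeIn pipeline-io Read mature-miRNA annotation TSV
#'   (columns mature_name, precursor_id, start, end, arm).
#' @export
read_mature_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mature_name", "precursor_id", "start", "end", "arm")
  if (!all(need %in% colnames(df)))
    stop_invalid("mature annotation must have columns: %s", paste(need, collapse = ", "))
  df
}

#' @describeIn pipeline-io Read a FASTA file into a named character vector
#'   (U mapped to T).
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as_dna(as.character(x)), names(x))
}

#' @describeIn pipeline-io Write named sequences to FASTA.
#' @param seqs named character vector of sequences.
#' @export
write_fasta_seqs <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @describeIn pipeline-io Read reads from FASTQ or FASTA into a character
#'   vector.
#' @param format `"fastq"` or `"fasta"`.
#' @export
read_reads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  x <- Biostrings::readDNAStringSet(path, format = format)
  as.character(x)
}

#' @describeIn pipeline-io Write reads to FASTQ with constant quality.
#' @param reads character vector of read sequences.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("read_%d", seq_along(reads))
  qual <- Biostrings::PhredQuality(
    vapply(nchar(reads), function(n) strrep("I", n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}
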