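#' Extract CATG-anchored reference tags from 3'UTR sequences
#'
#' For each transcript, every window of `tag_length` nucleotides that
#' starts at a CATG tetramer and lies fully inside the sequence is indexed
#' as a reference tag. Anchors are ranked from the 3' end: the 3'-most
#' usable CATG has `anchor_rank` 1. Transcripts containing no usable CATG
#' are recorded but absent from the index.
#'
#' @param utrs named character vector of UTR sequences (DNA alphabet; U is
#'   mapped to T).
#' @param tag_length tag length in nt (default 27, >= 8).
#' @return an object of class `tag_index`: list with `tags` (data.frame:
#'   tag, transcript_id, offset \[0-based from transcript start\],
#'   anchor_rank), `by_transcript` (tag sequences per transcript),
#'   `tag_length`, and `no_anchor` (transcripts without a usable CATG).
#' @export
extract_reference_tags <- function(utrs, tag_length = 27L) {
  tag_length <- assert_scalar_int(tag_length, "tag_length", min = 8)
  utrs <- stats::setNames(as_dna(unname(utrs)), names(utrs))
  rows <- vector("list", length(utrs))
  for (i in seq_along(utrs)) {
    u <- utrs[[i]]
    hits <- gregexpr("CATG", u, fixed = TRUE)[[1]]
    hits <- hits[hits > 0 & hits + tag_length - 1L <= nchar(u)]
    if (!length(hits)) next
    hits <- sort(hits)
    rows[[i]] <- data.frame(
      tag = substring(u, hits, hits + tag_length - 1L),
      transcript_id = names(utrs)[i],
      offset = hits - 1L,
      anchor_rank = rev(seq_along(hits)),
      stringsAsFactors = FALSE)
  }
  tags <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tags))
    tags <- data.frame(tag = character(0), transcript_id = character(0),
                       offset = integer(0), anchor_rank = integer(0))
  structure(list(
    tags = tags,
    by_transcript = split(tags$tag, tags$transcript_id),
    tag_length = tag_length,
    no_anchor = setdiff(names(utrs), tags$transcript_id)),
    class = "tag_index")
}

# Candidate lookup for <=1-mismatch matching with an exact CATG prefix:
# split the post-CATG remainder into two halves; one substitution can spoil
# at most one half, so every true match is recovered from the exact half.
tag_lookup_env <- function(index) {
  L <- index$tag_length
  h1_end <- 4L + (L - 4L) %/% 2L
  env <- new.env(hash = TRUE, parent = emptyenv())
  add <- function(key, i) assign(key, c(env[[key]], i), envir = env)
  for (i in seq_len(nrow(index$tags))) {
    t <- index$tags$tag[i]
    add(paste0("A:", substr(t, 5L, h1_end)), i)
    add(paste0("B:", substr(t, h1_end + 1L, L)), i)
  }
  list(env = env, h1_end = h1_end)
}

hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

#' Count SAGE reads against a reference tag index
#'
#' A read is truncated to the tag length, then counted for a transcript iff
#' it starts with an exact CATG, matches at least one indexed tag with at
#' most `max_mismatch` substitutions outside the anchor, and its
#' best-scoring matches resolve to a single (transcript, offset) position.
#' Reads matching equally well at two positions -- even within one
#' transcript -- are discarded as multi-mapped. Every read lands in exactly
#' one bucket: a transcript count or one of the discard tallies.
#'
#' @param reads character vector of read sequences (>= tag length each).
#' @param index a `tag_index` from [extract_reference_tags()].
#' @param max_mismatch substitution budget outside the CATG anchor
#'   (default 1).
#' @return list of class `tag_counts`: `counts` (named integer per
#'   transcript, zero-filled over all indexed transcripts) and `discarded`
#'   (no_catg_prefix, too_many_mismatches, multi_mapped, unmapped, too_short).
#' @export
count_tags <- function(reads, index, max_mismatch = 1L) {
  stopifnot(inherits(index, "tag_index"))
  if (nrow(index$tags) == 0) stop_invalid("empty tag index")
  max_mismatch <- assert_scalar_int(max_mismatch, "max_mismatch", min = 0)
  L <- index$tag_length
  lk <- tag_lookup_env(index)
  counts <- stats::setNames(
    integer(length(unique(index$tags$transcript_id))),
    unique(index$tags$transcript_id))
  discarded <- c(no_catg_prefix = 0L, too_many_mismatches = 0L,
                 multi_mapped = 0L, unmapped = 0L, too_short = 0L)
  reads <- as_dna(reads)
  for (r in reads) {
    if (nchar(r) < L) { discarded["too_short"] <- discarded["too_short"] + 1L; next }
    r <- substr(r, 1L, L)
    if (substr(r, 1L, 4L) != "CATG") {
      discarded["no_catg_prefix"] <- discarded["no_catg_prefix"] + 1L; next
    }
    cand <- unique(c(lk$env[[paste0("A:", substr(r, 5L, lk$h1_end))]],
                     lk$env[[paste0("B:", substr(r, lk$h1_end + 1L, L))]]))
    best <- Inf
    if (length(cand)) {
      mm <- vapply(index$tags$tag[cand], hamming, integer(1), a = r, USE.NAMES = FALSE)
      best <- min(mm)
    }
    if (best > max_mismatch) {
      # the half lookup recovers every tag within the budget, so this read
      # truly has no acceptable match; a full scan decides whether it is a
      # near-miss (<= twice the budget) or matches nothing at all
      d_min <- min(vapply(index$tags$tag, hamming, integer(1), a = r,
                          USE.NAMES = FALSE))
      key <- if (d_min <= 2L * max_mismatch) "too_many_mismatches" else "unmapped"
      discarded[key] <- discarded[key] + 1L
      next
    }
    hits <- cand[mm == best]
    if (length(hits) > 1L) {
      discarded["multi_mapped"] <- discarded["multi_mapped"] + 1L; next
    }
    tx <- index$tags$transcript_id[hits]
    counts[tx] <- counts[tx] + 1L
  }
  structure(list(counts = counts, discarded = discarded,
                 total = length(reads)), class = "tag_counts")
}

#' Write SAGE tag counts and discard summary
#'
#' @param x a `tag_counts`.
#' @param counts_tsv,summary_json output paths.
#' @export
write_tag_counts <- function(x, counts_tsv, summary_json) {
  utils::write.table(
    data.frame(transcript_id = names(x$counts), count = unname(x$counts)),
    counts_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(x$discarded), summary_json, auto_unbox = TRUE)
  invisible(c(counts_tsv, summary_json))
}
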