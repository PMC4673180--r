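#' Build a seed specification for a mature miRNA, optionally edited
#'
#' The seed is mature positions 2-8 (7 nt, 1-based from the 5' end). When
#' an edit is supplied, the mature base at `position` must equal `ref`; the
#' edited seed carries `alt` at the mapped offset. An edit outside
#' positions 2-8 leaves the seed unchanged (with a warning), since only
#' seed-region edits can reshape canonical target sites.
#'
#' @param mature mature miRNA sequence (>= 8 nt; RNA alphabet accepted).
#' @param edit optional `list(position =, ref =, alt =)` in mature
#'   coordinates.
#' @param mature_name optional label.
#' @return list of class `seed_spec`: `mature_name`, `mature`, `seed`
#'   (7 nt), `edited` (logical), `edit`.
#' @export
make_seed <- function(mature, edit = NULL, mature_name = NA_character_) {
  mature <- as_dna(mature)
  if (nchar(mature) < 8) stop_invalid("mature sequence must be >= 8 nt")
  edited <- FALSE
  if (!is.null(edit)) {
    ref <- as_dna(edit$ref); alt <- as_dna(edit$alt)
    have <- substr(mature, edit$position, edit$position)
    if (have != ref)
      stop_invalid("mature position %d is %s, expected %s",
                   edit$position, have, ref)
    if (edit$position >= 2 && edit$position <= 8) {
      mature <- substitute_base(mature, edit$position, alt)
      edited <- TRUE
    } else {
      warning("edit lies outside the seed (positions 2-8); seed unchanged")
    }
  }
  structure(list(mature_name = mature_name, mature = mature,
                 seed = substr(mature, 2, 8), edited = edited,
                 edit = edit), class = "seed_spec")
}

# UTR-side sequence (5'->3') of a canonical site for a given seed:
# the site core is the reverse complement of seed positions 1-6
# (miRNA positions 2-7); m8 types prepend the complement of seed position 7
# (miRNA position 8); A1 types append an A opposite miRNA position 1.
seed_site_sequence <- function(seed, type) {
  seed <- as_dna(seed)
  if (nchar(seed) != 7) stop_invalid("seed must be 7 nt")
  core <- revcomp(substr(seed, 1, 6))
  m8 <- complement_base(substr(seed, 7, 7))
  switch(type,
         "6mer" = core,
         "7mer-m8" = paste0(m8, core),
         "7mer-A1" = paste0(core, "A"),
         "8mer" = paste0(m8, core, "A"),
         stop_invalid("unknown site type '%s'", type))
}

#' Scan a 3'UTR for canonical seed-match sites
#'
#' Finds Watson-Crick matches of the reverse complement of the seed on the
#' given UTR strand (no reverse-complement search; ambiguous bases never
#' match). Every occurrence of the 6-nt core (miRNA positions 2-7) is one
#' locus, reported once with its strongest type: 8mer (positions 2-8
#' matched plus an A opposite position 1), then 7mer-m8 (2-8), then
#' 7mer-A1 (2-7 plus A), then 6mer. Coordinates are 1-based inclusive
#' starts of the full site on the UTR.
#'
#' @param utr UTR sequence (DNA alphabet; U mapped to T).
#' @param seed a `seed_spec` from [make_seed()] (or a 7-nt seed string).
#' @return data.frame: `start`, `end`, `type`.
#' @export
scan_utr <- function(utr, seed) {
  utr <- as_dna(utr)
  sd <- if (inherits(seed, "seed_spec")) seed$seed else as_dna(seed)
  core <- revcomp(substr(sd, 1, 6))
  m8 <- complement_base(substr(sd, 7, 7))
  # zero-width lookahead so self-overlapping cores are all found
  hits <- gregexpr(paste0("(?=", core, ")"), utr, perl = TRUE)[[1]]
  hits <- hits[hits > 0]
  if (!length(hits))
    return(data.frame(start = integer(0), end = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  n <- nchar(utr)
  rows <- lapply(hits, function(i) {
    has_m8 <- i > 1 && substr(utr, i - 1, i - 1) == m8
    has_a1 <- i + 6 <= n && substr(utr, i + 6, i + 6) == "A"
    if (has_m8 && has_a1) data.frame(start = i - 1L, end = i + 6L, type = "8mer")
    else if (has_m8) data.frame(start = i - 1L, end = i + 5L, type = "7mer-m8")
    else if (has_a1) data.frame(start = i, end = i + 6L, type = "7mer-A1")
    else data.frame(start = i, end = i + 5L, type = "6mer")
  })
  out <- do.call(rbind, rows)
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  out
}

#' Scan a whole transcript set for seed sites
#'
#' @param utrs named character vector of UTR sequences.
#' @param seed a `seed_spec` (or 7-nt seed string).
#' @param min_type weakest site type that counts a transcript as targeted
#'   (default `"6mer"`, i.e. all canonical types).
#' @return data.frame: `transcript_id`, `start`, `end`, `type`.
#' @export
scan_transcripts <- function(utrs, seed,
                             min_type = c("6mer", "7mer-A1", "7mer-m8", "8mer")) {
  min_type <- match.arg(min_type)
  strength <- c("6mer" = 1, "7mer-A1" = 2, "7mer-m8" = 3, "8mer" = 4)
  rows <- lapply(names(utrs), function(tx) {
    h <- scan_utr(utrs[[tx]], seed)
    h <- h[strength[h$type] >= strength[min_type], , drop = FALSE]
    if (!nrow(h)) return(NULL)
    cbind(transcript_id = tx, h, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), type = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare the target sets of the unedited and edited seed
#'
#' Reduces the two hit lists to transcript-level sets and reports the
#' transcripts targeted by the unedited form only (lost upon editing), by
#' the edited form only (gained), and by both, plus the Jaccard index
#' `|both| / |union|`.
#'
#' @param hits_unedited,hits_edited hit data.frames from
#'   [scan_transcripts()] computed on the same transcript set.
#' @return list of class `target_shift_summary`: `lost`, `gained`, `both`
#'   (character vectors), `jaccard`.
#' @export
compare_target_sets <- function(hits_unedited, hits_edited) {
  u <- unique(hits_unedited$transcript_id)
  e <- unique(hits_edited$transcript_id)
  both <- intersect(u, e)
  un <- union(u, e)
  structure(list(
    lost = setdiff(u, e),
    gained = setdiff(e, u),
    both = both,
    jaccard = if (length(un)) length(both) / length(un) else NA_real_),
    class = "target_shift_summary")
}
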