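#' Build an isomiR search index from a miRNA reference
#'
#' For each annotated mature miRNA the index stores the precursor-templated
#' extended region `[start - window, end + window]` (clipped to precursor
#' bounds), against which reads are aligned ungapped at every 5' offset
#' within the window. Two matures on one precursor get independent regions.
#'
#' @param ref a `mirna_reference`.
#' @param window maximum 5'/3' templated shift considered (default 3).
#' @return object of class `mirna_index`.
#' @export
build_mirna_index <- function(ref, window = 3L) {
  stopifnot(inherits(ref, "mirna_reference"))
  window <- assert_scalar_int(window, "window", min = 0)
  mats <- ref$matures
  pre_len <- nchar(ref$precursors[mats$precursor_id])
  if (any(mats$start < 1 | mats$end > pre_len | mats$start > mats$end))
    stop_invalid("mature interval outside precursor bounds")
  entries <- lapply(seq_len(nrow(mats)), function(i) {
    pre <- ref$precursors[[mats$precursor_id[i]]]
    ext_start <- max(1L, mats$start[i] - window)
    ext_end <- min(nchar(pre), mats$end[i] + window)
    ext <- substr(pre, ext_start, ext_end)
    list(mature_name = mats$mature_name[i],
         ext = ext,
         ext_raw = charToRaw(ext),
         # 1-based position of the mature 5' end within the extended region
         mature_at = mats$start[i] - ext_start + 1L,
         mature_len = mats$end[i] - mats$start[i] + 1L,
         mature_seq = substr(pre, mats$start[i], mats$end[i]))
  })
  names(entries) <- mats$mature_name
  # anchor dictionary: for every (mature, offset5) the first 15 templated
  # bases are split into an 8-mer and a 7-mer; one substitution can spoil
  # at most one of them, so a read with <= 1 mismatch in its templated
  # prefix is always recovered through the exact half
  env <- new.env(hash = TRUE, parent = emptyenv())
  add <- function(key, val) assign(key, c(env[[key]], list(val)), envir = env)
  for (i in seq_along(entries)) {
    en <- entries[[i]]
    for (off in -window:window) {
      p <- en$mature_at + off
      if (p < 1L || p + 14L > nchar(en$ext)) next
      t15 <- substr(en$ext, p, p + 14L)
      add(paste0("A:", substr(t15, 1L, 8L)), c(i, off))
      add(paste0("B:", substr(t15, 9L, 15L)), c(i, off))
    }
  }
  structure(list(entries = entries, anchors = env, window = window,
                 min_templated = 15L),
            class = "mirna_index")
}

# Evaluate one (read, mature, offset5) candidate: find the best tail split.
# Returns NULL or a call record. read_raw: raw vector of the read.
evaluate_candidate <- function(read_raw, n, entry, off, max_mismatch,
                               min_templated) {
  p <- entry$mature_at + off              # read 5' position in ext region
  if (p < 1L) return(NULL)
  avail <- length(entry$ext_raw) - p + 1L # templated bases available
  if (avail < min_templated) return(NULL)
  ov <- min(n, avail)                     # maximal templated overlap
  forced_tail <- n - ov
  mm_pos <- which(read_raw[seq_len(ov)] != entry$ext_raw[p:(p + ov - 1L)])
  # dropping the k 3'-most mismatches into the tail shortens the templated
  # part to mm_pos[M - k + 1] - 1; only k >= M - max_mismatch can qualify
  M <- length(mm_pos)
  best <- NULL
  for (k in max(0L, M - max_mismatch):M) {
    tlen <- if (k == 0L) ov else mm_pos[M - k + 1L] - 1L
    if (tlen < min_templated) next
    subs_idx <- if (k == M) integer(0) else mm_pos[seq_len(M - k)]
    tail_len <- n - tlen
    cand <- list(templated_len = tlen, tail_len = tail_len,
                 n_subs = M - k, subs_idx = subs_idx, offset5 = off, p = p)
    if (is.null(best) ||
        cand$n_subs < best$n_subs ||
        (cand$n_subs == best$n_subs && cand$tail_len < best$tail_len))
      best <- cand
  }
  best
}

call_better <- function(a, b, name_a, name_b) {
  # TRUE if a beats b: fewest substitutions, shortest tail, smallest
  # |offset5|, lexicographic mature name; a 5' over 3' shift of equal size
  # breaks the final tie deterministically
  if (a$n_subs != b$n_subs) return(a$n_subs < b$n_subs)
  if (a$tail_len != b$tail_len) return(a$tail_len < b$tail_len)
  if (abs(a$offset5) != abs(b$offset5)) return(abs(a$offset5) < abs(b$offset5))
  if (name_a != name_b) return(name_a < name_b)
  a$offset5 < b$offset5
}

#' Assign one small-RNA read to a miRNA and classify its isomiR variant
#'
#' The read is aligned without gaps to each mature's precursor-templated
#' extended region at every 5' offset within the window. Trailing read
#' bases that cannot be templated become a non-templated 3' tail, provided
#' the templated prefix keeps at most `max_mismatch` substitutions and
#' length >= 15. Among valid decompositions the best call has the fewest
#' substitutions, then the shortest tail, then the smallest |offset5|, then
#' the lexicographically smallest mature name. Substitution coordinates are
#' 1-based from the mature 5' end; `is_edited` is TRUE iff the substitution
#' list is exactly the single configured edit.
#'
#' @param read read sequence (>= 15 nt; U is mapped to T).
#' @param index a `mirna_index`.
#' @param max_mismatch substitution budget in the templated part (default 1).
#' @param edit configured edit, `list(position =, ref =, alt =)`.
#' @return a list (isomiR call) with fields `mature_name`, `offset5`,
#'   `offset3`, `tail`, `substitutions` (data.frame: mature_position, ref,
#'   alt), `is_canonical`, `signature`; or an object of class `unassigned`
#'   carrying a `reason` code.
#' @export
call_read <- function(read, index, max_mismatch = 1L,
                      edit = list(position = 6L, ref = "A", alt = "G")) {
  stopifnot(inherits(index, "mirna_index"))
  read <- as_dna(read)
  n <- nchar(read)
  if (n < index$min_templated)
    return(structure(list(reason = "too_short"), class = "unassigned"))
  read_raw <- charToRaw(read)
  # candidate (mature, offset) pairs via the split-anchor dictionary
  keyA <- paste0("A:", substr(read, 1L, 8L))
  keyB <- paste0("B:", substr(read, 9L, 15L))
  cand <- unique(c(index$anchors[[keyA]], index$anchors[[keyB]]))
  best <- NULL; best_name <- NULL
  for (cv in cand) {
    i <- cv[1]; off <- cv[2]
    entry <- index$entries[[i]]
    res <- evaluate_candidate(read_raw, n, entry, off, max_mismatch,
                              index$min_templated)
    if (is.null(res)) next
    nm <- entry$mature_name
    if (is.null(best) || call_better(res, best, nm, best_name)) {
      best <- res; best_name <- nm
    }
  }
  if (is.null(best))
    return(structure(list(reason = "no_alignment"), class = "unassigned"))
  finalize_call(read, best, index$entries[[best_name]])
}

finalize_call <- function(read, b, entry) {
  # translate ext-region coordinates into mature coordinates
  # mature position of read base i: (p + i - 1) - mature_at + 1
  mat_pos_of <- function(i) b$p + i - 1L - entry$mature_at + 1L
  subs <- if (length(b$subs_idx)) {
    data.frame(
      mature_position = vapply(b$subs_idx, mat_pos_of, integer(1)),
      ref = substring(entry$ext, b$p + b$subs_idx - 1L, b$p + b$subs_idx - 1L),
      alt = substring(read, b$subs_idx, b$subs_idx),
      stringsAsFactors = FALSE)
  } else {
    data.frame(mature_position = integer(0), ref = character(0),
               alt = character(0), stringsAsFactors = FALSE)
  }
  offset3 <- mat_pos_of(b$templated_len) - entry$mature_len
  tail <- if (b$tail_len > 0)
    substr(read, b$templated_len + 1L, nchar(read)) else ""
  list(mature_name = entry$mature_name,
       offset5 = b$offset5,
       offset3 = as.integer(offset3),
       tail = tail,
       substitutions = subs,
       n_subs = nrow(subs),
       is_canonical = b$offset5 == 0L && offset3 == 0L && tail == "" &&
         nrow(subs) == 0L,
       signature = paste0("o5:", b$offset5, ";o3:", offset3, ";tail:", tail,
                          ";sub:", paste(sprintf("%d%s>%s", subs$mature_position,
                                                 subs$ref, subs$alt),
                                         collapse = ",")))
}

call_is_edited <- function(call, edit) {
  s <- call$substitutions
  nrow(s) == 1L && s$mature_position[1] == edit$position &&
    s$ref[1] == edit$ref && s$alt[1] == edit$alt
}

#' Count the isomiR variants of one sample
#'
#' Calls every read (each unique sequence is resolved once) and tabulates
#' counts per (mature, variant signature); grouped per-miRNA counts are the
#' sums over that miRNA's variants. Assigned + unassigned = total reads.
#'
#' @param reads character vector of read sequences.
#' @param index a `mirna_index`.
#' @param max_mismatch substitution budget (default 1).
#' @param edit configured edit (see [call_read()]).
#' @param sample_id optional label carried into the table.
#' @return list of class `isomir_table`: `variants` (data.frame:
#'   mature_name, signature, offset5, offset3, tail, substitutions,
#'   is_edited, count), `grouped` (named counts per mature), `unassigned`,
#'   `total`.
#' @export
summarize_sample <- function(reads, index, max_mismatch = 1L,
                             edit = list(position = 6L, ref = "A", alt = "G"),
                             sample_id = NA_character_) {
  reads <- as_dna(reads)
  tab <- table(reads)
  uniq <- names(tab)
  cnt <- as.integer(tab)
  rows <- vector("list", length(uniq))
  unassigned <- 0L
  for (i in seq_along(uniq)) {
    call <- call_read(uniq[i], index, max_mismatch = max_mismatch, edit = edit)
    if (inherits(call, "unassigned")) { unassigned <- unassigned + cnt[i]; next }
    s <- call$substitutions
    rows[[i]] <- data.frame(
      mature_name = call$mature_name,
      signature = call$signature,
      offset5 = call$offset5, offset3 = call$offset3, tail = call$tail,
      substitutions = paste(sprintf("%d%s>%s", s$mature_position, s$ref, s$alt),
                            collapse = ","),
      is_edited = call_is_edited(call, edit),
      count = cnt[i], stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  variants <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mature_name = character(0), signature = character(0),
               offset5 = integer(0), offset3 = integer(0), tail = character(0),
               substitutions = character(0), is_edited = logical(0),
               count = integer(0), stringsAsFactors = FALSE)
  if (nrow(variants)) {
    agg <- stats::aggregate(count ~ mature_name + signature + offset5 +
                              offset3 + tail + substitutions + is_edited,
                            data = variants, FUN = sum)
    variants <- agg[order(agg$mature_name, agg$signature), ]
    rownames(variants) <- NULL
  }
  grouped <- if (nrow(variants))
    vapply(split(variants$count, variants$mature_name), sum, numeric(1)) else
      stats::setNames(numeric(0), character(0))
  structure(list(sample_id = sample_id, variants = variants,
                 grouped = grouped, unassigned = unassigned,
                 total = length(reads)),
            class = "isomir_table")
}

#' Summarize edited vs unedited counts of a target miRNA across samples
#'
#' For each sample, `edited` is the summed count of every variant of the
#' target miRNA whose substitution list contains the configured edit
#' (co-occurring 5'/3' offsets or tails do not disqualify a variant);
#' `unedited` sums all other variants of the target. When a per-sample
#' normalizer is supplied, normalized counts are raw counts times the
#' factor. The edited fraction is edited / (edited + unedited), flagged
#' undefined when the target has no reads.
#'
#' @param tables named list of `isomir_table` objects (one per sample).
#' @param target mature name of the miRNA of interest.
#' @param edit the configured edit, `list(position =, ref =, alt =)`.
#' @param normalizer optional named numeric per-sample scaling factors.
#' @param known optional character vector of valid mature names (e.g.
#'   `ref$matures$mature_name`); an unknown `target` then raises an error.
#' @return data.frame of class `editing_summary`: sample, edited, unedited,
#'   edited_norm, unedited_norm, fraction, defined.
#' @export
editing_table <- function(tables, target,
                          edit = list(position = 6L, ref = "A", alt = "G"),
                          normalizer = NULL, known = NULL) {
  if (!is.null(known) && !target %in% known)
    stop_invalid("target miRNA '%s' is not in the reference", target)
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, function(t) t$sample_id, character(1))
  rows <- lapply(names(tables), function(s) {
    v <- tables[[s]]$variants
    v <- v[v$mature_name == target, , drop = FALSE]
    edit_token <- sprintf("%d%s>%s", edit$position, edit$ref, edit$alt)
    has_edit <- vapply(strsplit(v$substitutions, ","), function(x)
      edit_token %in% x, logical(1))
    ed <- sum(v$count[has_edit]); un <- sum(v$count[!has_edit])
    f <- if (!is.null(normalizer)) {
      if (is.na(normalizer[s])) stop_invalid("no normalizer for sample %s", s)
      normalizer[[s]]
    } else 1
    data.frame(sample = s, edited = ed, unedited = un,
               edited_norm = ed * f, unedited_norm = un * f,
               fraction = if (ed + un > 0) ed / (ed + un) else NA_real_,
               defined = ed + un > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("editing_summary", "data.frame")
  out
}
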