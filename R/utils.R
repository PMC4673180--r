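# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' @noRd
assert_scalar_int <- function(x, name, min = -Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x))
    stop_invalid("`%s` must be a single integer", name)
  if (x < min)
    stop_invalid("`%s` must be >= %s (got %s)", name, min, x)
  as.integer(x)
}

# RNA -> DNA alphabet; everything internal works on A/C/G/T.
as_dna <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[[b]]
}

# Deterministic per-stream seed derivation from a single master seed.
# Keeps derived seeds inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  seed <- as.double(seed)
  stream_hash <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((seed * 69069 + stream_hash * 1234567) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(BASES, len, replace = TRUE), collapse = ""), character(1))
}

# Substitute `base` at 1-based `pos` of each string.
substitute_base <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}
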