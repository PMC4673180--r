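# Independent brute-force oracles. Each re-derives an operation from its
# definition by literal enumeration, deliberately sharing no code with the
# implementation it checks.

oracle_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  sum(av != bv)
}

# --- isomiR calling: enumerate every (mature, offset5, tail length)
# decomposition and apply the published tie-break order.
oracle_call_read <- function(read, ref, window = 3, max_mismatch = 1,
                             min_templated = 15) {
  read <- gsub("U", "T", toupper(read), fixed = TRUE)
  n <- nchar(read)
  if (n < min_templated) return(NULL)
  cands <- list()
  for (i in seq_len(nrow(ref$matures))) {
    mat <- ref$matures[i, ]
    pre <- ref$precursors[[mat$precursor_id]]
    ext_lo <- max(1, mat$start - window)
    ext_hi <- min(nchar(pre), mat$end + window)
    for (off in -window:window) {
      p5 <- mat$start + off            # precursor position of read base 1
      if (p5 < ext_lo) next
      for (tail_len in 0:(n - min_templated)) {
        tlen <- n - tail_len
        p3 <- p5 + tlen - 1            # precursor position of last templated
        if (p3 > ext_hi) next
        tmpl <- substr(pre, p5, p3)
        mm <- which(strsplit(substr(read, 1, tlen), "")[[1]] !=
                      strsplit(tmpl, "")[[1]])
        if (length(mm) > max_mismatch) next
        cands[[length(cands) + 1]] <- list(
          mature_name = mat$mature_name,
          offset5 = off,
          offset3 = p3 - mat$end,
          tail = if (tail_len) substr(read, tlen + 1, n) else "",
          n_subs = length(mm),
          subs = if (length(mm)) data.frame(
            mature_position = p5 + mm - 1 - mat$start + 1,
            ref = substring(tmpl, mm, mm),
            alt = substring(read, mm, mm), stringsAsFactors = FALSE)
          else data.frame(mature_position = integer(0), ref = character(0),
                          alt = character(0), stringsAsFactors = FALSE),
          tail_len = tail_len)
      }
    }
  }
  if (!length(cands)) return(NULL)
  key <- vapply(cands, function(c)
    sprintf("%02d|%02d|%02d|%s|%02d", c$n_subs, c$tail_len, abs(c$offset5),
            c$mature_name, c$offset5 + window), character(1))
  cands[[order(key)[1]]]
}

# --- TMM: literal sort-based implementation of the doubly trimmed,
# precision-weighted mean of M values.
oracle_tmm <- function(m, logratio_trim = 0.30, abs_trim = 0.05) {
  lib <- colSums(m)
  prop75 <- apply(sweep(m, 2, lib, "/"), 2, quantile, probs = 0.75)
  ref <- which.min(abs(prop75 - mean(prop75)))
  f <- numeric(ncol(m))
  for (s in seq_len(ncol(m))) {
    if (s == ref) { f[s] <- 1; next }
    ok <- m[, s] > 0 & m[, ref] > 0
    ys <- m[ok, s]; yr <- m[ok, ref]
    M <- log2(ys / lib[s]) - log2(yr / lib[ref])
    A <- 0.5 * (log2(ys / lib[s]) + log2(yr / lib[ref]))
    if (max(abs(M)) < 1e-6) { f[s] <- 1; next }
    n <- length(M)
    cut_m <- floor(n * logratio_trim)
    cut_a <- floor(n * abs_trim)
    ordM <- order(M)[(cut_m + 1):(n - cut_m)]
    ordA <- order(A)[(cut_a + 1):(n - cut_a)]
    keep <- intersect(ordM, ordA)
    if (!length(keep)) { f[s] <- 1; next }
    ps <- ys[keep] / lib[s]; pr <- yr[keep] / lib[ref]
    w <- 1 / (1 / ps - 1 + 1 / pr - 1)
    f[s] <- 2^(sum(w * M[keep]) / sum(w))
  }
  f / exp(mean(log(f)))
}

# --- Benjamini-Hochberg: literal step-up from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, p[o] * m / seq_len(m))
  for (i in (m - 1):1) if (m > 1)
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m); q[o] <- q_sorted
  q
}

# --- Yates chi-squared via the 2x2 shortcut formula.
oracle_yates_shortcut <- function(tab, continuity = TRUE) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  corr <- if (continuity) n / 2 else 0
  n * max(0, abs(a * d - b * c) - corr)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# squared two-sample z statistic for proportions (no correction)
oracle_z_squared <- function(tab) {
  n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ])
  p1 <- tab[1, 1] / n1; p2 <- tab[2, 1] / n2
  pp <- (tab[1, 1] + tab[2, 1]) / (n1 + n2)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z^2
}

# --- ReliefF, k = 1: literal Kononenko update over all instances.
oracle_relieff_k1 <- function(x, labels) {
  n <- ncol(x)
  rng <- apply(x, 1, function(v) max(v) - min(v))
  w <- numeric(nrow(x))
  for (r in seq_len(n)) {
    d <- vapply(seq_len(n), function(j)
      sum(abs((x[, j] - x[, r])[rng > 0] / rng[rng > 0])), numeric(1))
    same <- setdiff(which(labels == labels[r]), r)
    diff_cl <- which(labels != labels[r])
    h <- same[which.min(d[same])]
    m <- diff_cl[which.min(d[diff_cl])]
    for (f in seq_len(nrow(x))) {
      if (rng[f] == 0) next
      w[f] <- w[f] + abs(x[f, m] - x[f, r]) / rng[f] -
        abs(x[f, h] - x[f, r]) / rng[f]
    }
  }
  w / n
}

# --- SAGE: all-windows Hamming scan of every read against every
# CATG-anchored window of every transcript.
oracle_sage_counts <- function(reads, utrs, tag_length = 27, max_mismatch = 1) {
  windows <- list()
  for (tx in names(utrs)) {
    u <- utrs[[tx]]
    for (i in seq_len(max(0, nchar(u) - tag_length + 1))) {
      if (substr(u, i, i + 3) == "CATG")
        windows[[length(windows) + 1]] <- list(
          tx = tx, pos = i, seq = substr(u, i, i + tag_length - 1))
    }
  }
  counts <- setNames(integer(length(utrs)), names(utrs))
  for (r in reads) {
    if (nchar(r) < tag_length) next
    r <- substr(r, 1, tag_length)
    if (substr(r, 1, 4) != "CATG") next
    dists <- vapply(windows, function(w) oracle_hamming(r, w$seq), numeric(1))
    best <- min(dists)
    if (best > max_mismatch) next
    hits <- which(dists == best)
    if (length(hits) != 1) next
    counts[windows[[hits]]$tx] <- counts[windows[[hits]]$tx] + 1L
  }
  counts
}

# --- seed sites: brute substring comparison at every UTR position.
oracle_seed_scan <- function(utr, seed7) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  core <- rc(substr(seed7, 1, 6))
  m8 <- comp[[substr(seed7, 7, 7)]]
  out <- NULL
  for (i in seq_len(max(0, nchar(utr) - 5))) {
    if (substr(utr, i, i + 5) != core) next
    has_m8 <- i > 1 && substr(utr, i - 1, i - 1) == m8
    has_a1 <- i + 6 <= nchar(utr) && substr(utr, i + 6, i + 6) == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
      else if (has_a1) "7mer-A1" else "6mer"
    start <- if (has_m8) i - 1 else i
    out <- rbind(out, data.frame(start = start, type = type,
                                 stringsAsFactors = FALSE))
  }
  out
}
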