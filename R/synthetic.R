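#' Generate a synthetic miRNA reference
#'
#' Builds `n_mirnas` hairpin precursors (random DNA, 60-120 nt), each with a
#' single annotated mature miRNA of 18-25 nt lying fully inside the
#' precursor. At least `n_editable` matures are guaranteed to carry an A at
#' mature position `editable_position` (counted 1-based from the mature 5'
#' end), so that an A-to-G edited isoform can be planted inside the seed
#' region, mirroring the position-6 editing events seen for brain miRNAs.
#'
#' Sequences are stored in the DNA alphabet (T, not U); readers map U to T.
#'
#' @param n_mirnas number of precursor/mature pairs (>= 1).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @param n_editable how many matures must have an A at
#'   `editable_position` (default 1; these are the first miRNAs).
#' @param editable_position mature position forced to A for editable
#'   miRNAs (default 6, inside the seed).
#' @return an object of class `mirna_reference`: a list with `precursors`
#'   (named character vector), `matures` (data.frame: mature_name,
#'   precursor_id, start, end, arm), and `editable` (mature names).
#' @export
make_mirna_reference <- function(n_mirnas, seed, n_editable = 1L,
                                 editable_position = 6L) {
  n_mirnas <- assert_scalar_int(n_mirnas, "n_mirnas", min = 1)
  n_editable <- min(assert_scalar_int(n_editable, "n_editable", min = 1), n_mirnas)
  with_seed(derive_seed(seed, "mirna_reference"), {
    pre_len <- sample(60:120, n_mirnas, replace = TRUE)
    precursors <- random_dna(n_mirnas, max(pre_len))
    precursors <- substr(precursors, 1, pre_len)
    names(precursors) <- sprintf("pre-mir-%03d", seq_len(n_mirnas))
    mat_len <- sample(18:25, n_mirnas, replace = TRUE)
    arm <- sample(c("5p", "3p"), n_mirnas, replace = TRUE)
    # keep a >= 3 nt flank on both sides so alignment windows stay templated
    start <- vapply(seq_len(n_mirnas), function(i)
      sample(4:(pre_len[i] - mat_len[i] - 2), 1), integer(1))
    end <- start + mat_len - 1L
    matures <- data.frame(
      mature_name = sprintf("mir-%03d-%s", seq_len(n_mirnas), arm),
      precursor_id = names(precursors),
      start = start, end = end, arm = arm,
      stringsAsFactors = FALSE)
    for (i in seq_len(n_editable)) {
      pos <- start[i] + editable_position - 1L
      precursors[i] <- substitute_base(precursors[i], pos, "A")
    }
    structure(
      list(precursors = precursors, matures = matures,
           editable = matures$mature_name[seq_len(n_editable)]),
      class = "mirna_reference")
  })
}

#' Extract mature sequences from a miRNA reference
#'
#' @param ref a `mirna_reference`.
#' @return named character vector of mature sequences.
#' @export
mature_sequences <- function(ref) {
  stats::setNames(
    substr(ref$precursors[ref$matures$precursor_id],
           ref$matures$start, ref$matures$end),
    ref$matures$mature_name)
}

#' Write / read a miRNA reference as FASTA + TSV
#'
#' @param ref a `mirna_reference`.
#' @param fasta,tsv output paths (precursor FASTA; mature annotation TSV
#'   with 1-based inclusive coordinates).
#' @return the input paths, invisibly (`write`); a `mirna_reference`
#'   (`read`).
#' @export
write_mirna_reference <- function(ref, fasta, tsv) {
  write_fasta_seqs(ref$precursors, fasta)
  utils::write.table(ref$matures, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' @rdname write_mirna_reference
#' @export
read_mirna_reference <- function(fasta, tsv) {
  precursors <- read_fasta_seqs(fasta)
  matures <- read_mature_annotation(tsv)
  bad <- matures$start < 1 | matures$end > nchar(precursors[matures$precursor_id])
  if (any(bad))
    stop_invalid("mature interval outside precursor: %s",
                 paste(matures$mature_name[bad], collapse = ", "))
  structure(list(precursors = precursors, matures = matures,
                 editable = character(0)),
            class = "mirna_reference")
}

#' Describe one simulated small-RNA sample
#'
#' Bundles the per-sample simulation parameters: relative miRNA abundances,
#' the fraction of reads of each miRNA carrying the planted A-to-G edit,
#' the isomiR variant profile, read depth and per-base error rate.
#'
#' @param sample_id,patient_id,region,survival,infiltrated sample metadata;
#'   `region` is `"C"` (tumor center) or `"P"` (peritumor), `survival`
#'   `"ST"`/`"LT"`, `infiltrated` `"yes"`/`"no"`/`"na"`.
#' @param abundance named non-negative weights per mature miRNA (relative
#'   expression); not all zero.
#' @param editing_fraction named fractions in \[0,1\]: probability that a
#'   read of that miRNA carries the configured edit.
#' @param isomir_profile probabilities for the four simulated read classes
#'   `canonical`, `shift5`, `shift3`, `tail`; must sum to 1.
#' @param n_reads reads to simulate (default 50000).
#' @param error_rate independent per-base substitution probability.
#' @return a list of class `sample_design`.
#' @export
sample_design <- function(sample_id, abundance,
                          editing_fraction = numeric(0),
                          isomir_profile = c(canonical = 0.7, shift5 = 0.1,
                                             shift3 = 0.1, tail = 0.1),
                          n_reads = 50000L, error_rate = 0.001,
                          patient_id = sample_id, region = "C",
                          survival = "ST", infiltrated = "na") {
  if (length(abundance) == 0 || any(abundance < 0) || all(abundance == 0))
    stop_invalid("abundance weights must be non-negative and not all zero")
  if (length(editing_fraction) && (any(editing_fraction < 0) || any(editing_fraction > 1)))
    stop_invalid("editing_fraction values must lie in [0, 1]")
  need <- c("canonical", "shift5", "shift3", "tail")
  if (!all(need %in% names(isomir_profile)) ||
      abs(sum(isomir_profile) - 1) > 1e-8)
    stop_invalid("isomir_profile must name %s and sum to 1",
                 paste(need, collapse = ", "))
  structure(list(
    sample_id = sample_id, patient_id = patient_id, region = region,
    survival = survival, infiltrated = infiltrated,
    abundance = abundance, editing_fraction = editing_fraction,
    isomir_profile = isomir_profile[need],
    n_reads = assert_scalar_int(n_reads, "n_reads", min = 1),
    error_rate = error_rate), class = "sample_design")
}

# Per-mature variant sequence table used by the read simulator: canonical,
# templated 5'/3' one-base shifts (clipped to the precursor) and the base a
# non-templated tail must avoid.
variant_table <- function(ref) {
  mats <- ref$matures
  lapply(seq_len(nrow(mats)), function(i) {
    pre <- ref$precursors[[mats$precursor_id[i]]]
    s <- mats$start[i]; e <- mats$end[i]; n <- nchar(pre)
    canonical <- substr(pre, s, e)
    list(
      canonical = canonical,
      shift5 = if (s > 1) substr(pre, s - 1, e) else substr(pre, s + 1, e),
      shift3 = if (e < n) substr(pre, s, e + 1) else substr(pre, s, e - 1),
      shift5_off = if (s > 1) -1L else 1L,
      # base the precursor continues with after the mature 3' end; a tail
      # base must differ from it to be truly non-templated
      next_base = if (e < n) substr(pre, e + 1, e + 1) else NA_character_)
  }) |> stats::setNames(mats$mature_name)
}

#' Simulate one small-RNA sample
#'
#' Draws `design$n_reads` reads: each read picks a miRNA by abundance
#' weight, an isomiR class by `isomir_profile` (canonical, one-base
#' templated 5' or 3' shift, or one non-templated 3' tail base), carries
#' the configured A-to-G edit with probability
#' `editing_fraction[mature]`, and finally suffers independent per-base
#' substitution errors at `error_rate`. The edit is applied at the mature
#' coordinate `edit["position"]`, so 5'-shifted reads still carry it at the
#' correct offset within the read.
#'
#' @param ref a `mirna_reference`.
#' @param design a [sample_design()].
#' @param seed integer seed.
#' @param edit the planted edit as `c(position =, ref =, alt =)`
#'   (default position 6, A>G).
#' @return list with `reads` (character vector) and `truth` (data.frame per
#'   mature: simulated reads, planted edited reads, plus the design).
#' @export
simulate_small_rna_sample <- function(ref, design, seed,
                                      edit = list(position = 6L, ref = "A", alt = "G")) {
  stopifnot(inherits(ref, "mirna_reference"), inherits(design, "sample_design"))
  unknown <- setdiff(c(names(design$abundance), names(design$editing_fraction)),
                     ref$matures$mature_name)
  if (length(unknown))
    stop_invalid("design references matures absent from the reference: %s",
                 paste(unknown, collapse = ", "))
  vt <- variant_table(ref)
  with_seed(derive_seed(seed, paste0("reads_", design$sample_id)), {
    n <- design$n_reads
    mats <- names(design$abundance)
    m <- sample(mats, n, replace = TRUE, prob = design$abundance)
    cls <- sample(names(design$isomir_profile), n, replace = TRUE,
                  prob = design$isomir_profile)
    ef <- design$editing_fraction[m]
    ef[is.na(ef)] <- 0
    edited <- stats::rbinom(n, 1L, ef) == 1L

    seqs <- character(n)
    off5 <- integer(n)
    for (mm in unique(m)) {
      v <- vt[[mm]]
      idx <- which(m == mm)
      icls <- cls[idx]
      s <- character(length(idx))
      s[icls == "canonical"] <- v$canonical
      s[icls == "shift5"] <- v$shift5
      s[icls == "shift3"] <- v$shift3
      ti <- which(icls == "tail")
      if (length(ti)) {
        tail_bases <- sample(setdiff(BASES, v$next_base), length(ti), replace = TRUE)
        s[ti] <- paste0(v$canonical, tail_bases)
      }
      o <- integer(length(idx))
      o[icls == "shift5"] <- v$shift5_off
      seqs[idx] <- s
      off5[idx] <- o
    }
    # apply the planted edit at the mature coordinate
    ei <- which(edited)
    if (length(ei)) {
      read_pos <- edit$position - off5[ei]
      ok <- read_pos >= 1 & read_pos <= nchar(seqs[ei]) &
        substr(seqs[ei], read_pos, read_pos) == edit$ref
      tgt <- ei[ok]
      substr(seqs[tgt], read_pos[ok], read_pos[ok]) <- edit$alt
      edited[ei[!ok]] <- FALSE
    }
    # sequencing errors: uniform substitution to one of the 3 alternatives
    if (design$error_rate > 0) {
      n_err <- stats::rbinom(n, nchar(seqs), design$error_rate)
      for (i in which(n_err > 0)) {
        pos <- sample.int(nchar(seqs[i]), n_err[i])
        for (p in pos) {
          cur <- substr(seqs[i], p, p)
          substr(seqs[i], p, p) <- sample(setdiff(BASES, cur), 1)
        }
      }
    }
    truth <- data.frame(
      mature_name = mats,
      n_reads = as.integer(table(factor(m, levels = mats))),
      n_edited = as.integer(tapply(edited, factor(m, levels = mats), sum, default = 0)),
      stringsAsFactors = FALSE)
    list(reads = seqs, truth = truth, design = design)
  })
}

#' Simulate a paired tumor-center / peritumor count cohort
#'
#' Counts follow a negative-binomial model with a per-patient lognormal
#' baseline shared by the two samples of a pair, the standard bulk-count
#' assumption. A configurable number of planted features carries a log2
#' effect between the C and P members of every pair; all remaining features
#' are null.
#'
#' @param n_pairs number of C/P pairs (>= 2).
#' @param effects list: `n_features` (default 500), `n_planted` (default 5),
#'   `log2_effect` (C vs P, default 2; may be a vector recycled over planted
#'   features), `dispersion` (NB dispersion, default 0.2), `baseline_meanlog`,
#'   `baseline_sdlog` (feature mean distribution, default log(200), 1),
#'   `patient_sdlog` (patient baseline spread, default 0.4).
#' @param seed integer seed.
#' @return list with `counts` (feature x sample integer matrix; columns
#'   `P01_C`, `P01_P`, ...), `metadata` (data.frame: sample_id, patient,
#'   region, survival), and `truth` (planted feature ids and log2 effects).
#' @export
simulate_paired_cohort <- function(n_pairs, effects = list(), seed) {
  n_pairs <- assert_scalar_int(n_pairs, "n_pairs", min = 2)
  e <- utils::modifyList(list(
    n_features = 500L, n_planted = 5L, log2_effect = 2,
    dispersion = 0.2, baseline_meanlog = log(200), baseline_sdlog = 1,
    patient_sdlog = 0.4), effects)
  if (e$dispersion <= 0) stop_invalid("dispersion must be positive")
  with_seed(derive_seed(seed, "paired_cohort"), {
    nf <- e$n_features
    feat <- sprintf("feat_%04d", seq_len(nf))
    planted <- if (e$n_planted > 0) sort(sample(nf, e$n_planted)) else integer(0)
    lfc <- numeric(nf)
    lfc[planted] <- rep_len(e$log2_effect, length(planted))
    mu0 <- stats::rlnorm(nf, e$baseline_meanlog, e$baseline_sdlog)
    patients <- sprintf("P%02d", seq_len(n_pairs))
    counts <- matrix(0L, nf, 2 * n_pairs)
    colnames(counts) <- as.vector(rbind(paste0(patients, "_C"), paste0(patients, "_P")))
    rownames(counts) <- feat
    for (p in seq_len(n_pairs)) {
      base_p <- mu0 * stats::rlnorm(nf, 0, e$patient_sdlog)
      # symmetric split of the planted effect keeps pair means comparable
      mu_c <- base_p * 2^(lfc / 2)
      mu_p <- base_p * 2^(-lfc / 2)
      counts[, 2 * p - 1] <- stats::rnbinom(nf, mu = mu_c, size = 1 / e$dispersion)
      counts[, 2 * p] <- stats::rnbinom(nf, mu = mu_p, size = 1 / e$dispersion)
    }
    survival <- rep(rep(c("ST", "LT"), length.out = n_pairs), each = 2)
    metadata <- data.frame(
      sample_id = colnames(counts),
      patient = rep(patients, each = 2),
      region = rep(c("C", "P"), n_pairs),
      survival = survival, stringsAsFactors = FALSE)
    list(counts = counts, metadata = metadata,
         truth = list(planted = feat[planted], log2_effect = lfc[planted],
                      seed = seed))
  })
}

#' Simulate a 3'UTR transcript set with CATG-anchored tags
#'
#' Every transcript is guaranteed to contain at least one CATG tetramer
#' whose 3'-most occurrence leaves >= 27 nt to the sequence end, so a
#' 27-nt SAGE tag can always be anchored. Optional seed sites are planted
#' at fixed positions and recorded in the truth.
#'
#' @param n_transcripts number of transcripts (>= 1).
#' @param utr_length length of each UTR (>= 40).
#' @param planted_sites optional data.frame (`transcript` index,
#'   `position`, `type` in 8mer/7mer-m8/7mer-A1/6mer, `seed` 7-nt seed
#'   sequence) of sites to embed.
#' @param seed integer seed.
#' @return list with `utrs` (named character vector) and `truth`
#'   (planted site table).
#' @export
simulate_transcriptome <- function(n_transcripts, utr_length,
                                   planted_sites = NULL, seed) {
  n_transcripts <- assert_scalar_int(n_transcripts, "n_transcripts", min = 1)
  utr_length <- assert_scalar_int(utr_length, "utr_length", min = 40)
  with_seed(derive_seed(seed, "transcriptome"), {
    utrs <- random_dna(n_transcripts, utr_length)
    names(utrs) <- sprintf("tx_%04d", seq_len(n_transcripts))
    anchor_at <- utr_length - 30L
    for (i in seq_along(utrs)) {
      u <- utrs[[i]]
      substr(u, anchor_at, anchor_at + 3L) <- "CATG"
      # scrub CATGs too close to the 3' end to anchor a full 27-mer
      repeat {
        hits <- gregexpr("CATG", u, fixed = TRUE)[[1]]
        bad <- hits[hits > utr_length - 26L & hits > 0]
        if (!length(bad) || all(hits < 0)) break
        for (b in bad) substr(u, b + 3L, b + 3L) <- "A"
      }
      utrs[[i]] <- u
    }
    if (!is.null(planted_sites)) {
      for (j in seq_len(nrow(planted_sites))) {
        ps <- planted_sites[j, ]
        site <- seed_site_sequence(ps$seed, ps$type)
        tx <- if (is.numeric(ps$transcript)) names(utrs)[ps$transcript] else ps$transcript
        u <- utrs[[tx]]
        if (ps$position + nchar(site) - 1 > nchar(u))
          stop_invalid("planted site exceeds transcript length")
        substr(u, ps$position, ps$position + nchar(site) - 1) <- site
        utrs[[tx]] <- u
      }
    }
    list(utrs = utrs,
         truth = list(planted_sites = planted_sites, seed = seed))
  })
}

#' Generate disjoint subtype gene sets over a simulated gene universe
#'
#' @param n_subtypes number of subtype signatures (>= 1).
#' @param genes_per_set signature size (>= 1).
#' @param seed integer seed.
#' @param universe optional character vector of gene ids to draw from;
#'   default builds one of size `4 * n_subtypes * genes_per_set`.
#' @return named list of disjoint gene sets with the gene `universe`
#'   attached as an attribute.
#' @export
make_subtype_gene_sets <- function(n_subtypes, genes_per_set, seed,
                                   universe = NULL) {
  n_subtypes <- assert_scalar_int(n_subtypes, "n_subtypes", min = 1)
  genes_per_set <- assert_scalar_int(genes_per_set, "genes_per_set", min = 1)
  with_seed(derive_seed(seed, "gene_sets"), {
    if (is.null(universe))
      universe <- sprintf("gene_%05d", seq_len(4L * n_subtypes * genes_per_set))
    if (length(universe) < n_subtypes * genes_per_set)
      stop_invalid("gene universe too small (%d) for %d sets of %d",
                   length(universe), n_subtypes, genes_per_set)
    picked <- sample(universe, n_subtypes * genes_per_set)
    sets <- split(picked, rep(seq_len(n_subtypes), each = genes_per_set))
    names(sets) <- sprintf("subtype_%d", seq_len(n_subtypes))
    attr(sets, "universe") <- universe
    sets
  })
}

#' Simulate expression profiles with a planted subtype signature
#'
#' Gene expression is standard-normal noise; each sample's true subtype set
#' is shifted up by `shift` standard deviations, emulating the coordinate
#' up-regulation a single-sample gene-set score should detect.
#'
#' @param sets gene sets from [make_subtype_gene_sets()].
#' @param n_samples number of samples.
#' @param shift mean up-shift (in SDs) of the true subtype's genes.
#' @param seed integer seed.
#' @return list with `expr` (gene x sample matrix) and `truth` (named
#'   character vector of planted subtypes).
#' @export
simulate_subtype_profiles <- function(sets, n_samples, shift = 2, seed) {
  universe <- attr(sets, "universe")
  if (is.null(universe)) universe <- unique(unlist(sets))
  with_seed(derive_seed(seed, "subtype_profiles"), {
    subtype <- sample(names(sets), n_samples, replace = TRUE)
    expr <- matrix(stats::rnorm(length(universe) * n_samples),
                   length(universe), n_samples,
                   dimnames = list(universe, sprintf("S%03d", seq_len(n_samples))))
    for (j in seq_len(n_samples))
      expr[sets[[subtype[j]]], j] <- expr[sets[[subtype[j]]], j] + shift
    list(expr = expr, truth = stats::setNames(subtype, colnames(expr)))
  })
}

#' Simulate SAGE reads from planted per-transcript tag abundances
#'
#' Emits exactly `abundance[tx]` reads for each transcript, each read a
#' randomly chosen CATG-anchored tag of that transcript, optionally with
#' substitution errors.
#'
#' @param utrs named character vector of UTR sequences.
#' @param abundance named integer vector: reads per transcript.
#' @param tag_length tag length (default 27).
#' @param seed integer seed.
#' @param error_rate per-base substitution probability (default 0).
#' @return list with `reads` and `truth` (the abundance vector).
#' @export
simulate_sage_reads <- function(utrs, abundance, tag_length = 27L, seed,
                                error_rate = 0) {
  idx <- extract_reference_tags(utrs, tag_length)
  with_seed(derive_seed(seed, "sage_reads"), {
    reads <- character(0)
    for (tx in names(abundance)) {
      tags <- idx$by_transcript[[tx]]
      if (is.null(tags) || !length(tags))
        stop_invalid("transcript %s has no anchored tag", tx)
      reads <- c(reads, sample(tags, abundance[[tx]], replace = TRUE))
    }
    reads <- sample(reads)
    if (error_rate > 0) {
      n_err <- stats::rbinom(length(reads), nchar(reads), error_rate)
      for (i in which(n_err > 0)) {
        pos <- sample.int(nchar(reads[i]), n_err[i])
        for (p in pos) {
          cur <- substr(reads[i], p, p)
          substr(reads[i], p, p) <- sample(setdiff(BASES, cur), 1)
        }
      }
    }
    list(reads = reads, truth = list(abundance = abundance, seed = seed))
  })
}
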