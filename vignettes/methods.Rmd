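---
title: "Methods: isomiR calling, editing statistics and expression profiling of paired glioblastoma samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isomiR calling, editing statistics and expression profiling of paired glioblastoma samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gbmirnome` re-implements, as a tested pipeline over simulated data with
known ground truth, the computational analyses used to profile paired
glioblastoma tumor-center (C) and peritumor (P) tissue: isomiR detection
and A-to-G editing quantification from small-RNA reads, TMM/cpm
normalization and filtering, pooled-proportion editing statistics,
paired differential expression, ReliefF feature ranking, ssGSEA subtype
classification, CATG-anchored SAGE tag counting, and seed-site target
analysis of an edited miRNA. This vignette explains each model, its
assumptions, the tunable parameters, and the choices made where the
design was genuinely open.

## The isomiR caller

A mature miRNA is annotated as an interval on its precursor hairpin.
Real small-RNA reads deviate from the annotated mature sequence in
stereotyped ways — templated 5'/3' end shifts (the drosha/dicer cut
varying by a base or two), non-templated 3' tailing (mono-uridylation,
adenylation), and internal substitutions, of which A-to-I editing (read
as G by sequencers) is the biologically prominent case. The caller
aligns each read, without gaps, against the precursor-templated
*extended region* `[start - window, end + window]` of every mature
(window default 3 nt), at every 5' offset within the window. Trailing
read bases that cannot be templated are classified as a 3' tail,
provided the templated prefix retains at most `max_mismatch`
substitutions (default 1) and is at least 15 nt long. Among all valid
decompositions the best call has, in order: fewest substitutions,
shortest tail, smallest |5' offset|, then the lexicographically smallest
mature name (and a 5'-over-3' shift as a final deterministic
tie-break). Substitution coordinates are reported 1-based from the
mature 5' end, so the editing event of interest is "position 6, A>G" —
inside the seed.

Two details matter for editing quantification:

* A variant counts as *edited* if its substitution list contains the
  configured edit, regardless of co-occurring end shifts or tails; the
  edited and unedited counts of the target miRNA are summed over all
  its variants.
* With `max_mismatch = 1`, a read carrying the edit *plus* a sequencing
  error exceeds the budget and is left unassigned, rather than being
  counted with a wrong substitution. This deliberately biases the
  edited-fraction estimate down by an amount of order the per-base
  error rate times read length, instead of letting errors inflate
  editing counts.

The alignment window (3) and mismatch budget (1) are declared defaults,
not published values; both are arguments. For speed, candidate
(mature, offset) pairs are retrieved through a split-anchor dictionary:
the first 15 templated bases are split into an 8-mer and a 7-mer, and
one substitution can spoil at most one of them, so the exact-match half
always recovers every candidate within the budget. A brute-force
enumeration of all (offset, substitution, tail) decompositions — the
test oracle — confirms the dictionary path exactly.

## Editing statistics

Per sample, the edited fraction of the target miRNA is
`edited / (edited + unedited)`, flagged undefined when the target has no
reads. For the group comparison, edited and unedited counts are pooled
(summed) over the member samples of two groups — C vs P, or short-term
vs long-term survivor centers — and tested with the two-proportion
chi-squared test with continuity correction:
$$X^2 = \sum_{\text{cells}} \frac{\max(0, |O - E| - \tfrac12)^2}{E},$$
with expectations from the margins under independence and a 1-df upper
tail p-value. The continuity term is clamped at zero so that
equal-proportion tables give exactly $X^2 = 0$ rather than a negative
artifact. Pooled counts default to TMM-scaled ("normalized") counts
rounded to integers, mirroring the source procedure of testing summed
normalized counts; a raw-count mode is provided because testing scaled
counts is statistically non-standard, and the output records which was
used. Tests verify the implementation against the 2x2 shortcut formula,
against the squared two-sample z statistic (without correction), against
`prop.test`, and for calibration under the null (rejection rate at most
~0.05-0.06; the correction is conservative).

In the default simulated cohort the C/P contrast is planted (edited
fractions 0.15 vs 0.45) while the ST/LT contrast is not, so the second
test acts as a negative control and accepts the null.

## TMM normalization and cpm filters

Library scaling factors are computed by the trimmed mean of M-values:
against a reference sample (the one whose upper-quartile proportion is
closest to the mean upper-quartile), per-feature log2 proportion ratios
M and mean log2 abundances A are formed over features positive in both
libraries; the extreme 30% of M per side and 5% of A per side are
discarded by rank; the factor is 2 to the precision-weighted mean of the
retained M. Two numerical choices are deliberate:

* M and A are *defined* as differences/means of `log2(count/total)`,
  and exact ties at trim boundaries are broken by feature order. Trim
  windows can split tied values, so the arithmetic form is part of the
  algorithm's definition — otherwise two correct implementations can
  legitimately disagree.
* Precision weights are the inverse *relative* delta-method variance
  computed from the proportions, `1/((1-p_s)/p_s + (1-p_r)/p_r)`. Using
  proportions rather than raw depths makes the factors exactly
  invariant to rescaling any single library, a property the
  depth-weighted variant does not have (its weights shift with depth).
  With comparable library sizes the two weightings are proportional,
  and the package agrees with `edgeR::calcNormFactors` to ~2% on random
  matrices (edgeR serves as a cross-check, never as the implementation).

Counts per million divide by effective library size
(`total x factor`), with an optional pseudocount. The expression filter
follows the paired design: a feature is kept when its cpm reaches 10 in
at least one member of *strictly more than* 4 of the 10 C/P pairs
("more than 4" is read as >= 5 and exposed as a knob, because the
source sentence is ambiguous); an unpaired variant (at least `min_cpm`
in at least `min_samples` samples) covers the second filter used for
the infiltration comparison.

## Paired differential expression

The negative-binomial GLM used in the original analysis belongs to an
external package; this pipeline substitutes an explicit paired sign-flip
permutation test with the same contract. The statistic per feature is
the mean over pairs of `log2((cpm_C + 1)/(cpm_P + 1))`; the null flips
each pair's sign independently; the two-sided p-value is
`(1 + #{|null| >= |obs|}) / (n_perm + 1)`, BH-adjusted across features.
A pseudocount of 1 is used for every log ratio throughout the package:
the bundled real count tables contain a zero healthy-control cell, so
zeros must be handled, and the source's method is unstated.

The sign-flip null has an intrinsic resolution: with $n$ pairs the
smallest achievable two-sided p-value is $2/2^n$. At 10 pairs
(~2e-3) this is fine for small panels, but detecting 20 planted
features among 2020 at BH FDR < 0.05 requires p <= 5e-4, below that
floor. The package's power benchmark therefore simulates 16 pairs
(floor ~3e-5), a cohort size chosen from this resolution argument, not
from the data; the null-uniformity check runs at the study's 10 pairs.

Group-vs-control log2 fold changes are ratios of group means (not means
of per-sample ratios — the alternative is documented as an open
reading), and the shared signature keeps features with
`log2FC >= 1.5` in *every* group (inclusive, "at least 1.5") or
`<= -1.5` in every group. Both bundled real tables pass this rule
intact, a regression test on in-study data magnitudes.

## ReliefF ranking with leave-one-out averaging

ReliefF scores a feature by contrasting its differences to nearest
same-class and different-class neighbors: with all instances used,
$$W_f = \frac{1}{n}\sum_R \left[\overline{\mathrm{diff}}_f(R, \mathrm{misses}) - \overline{\mathrm{diff}}_f(R, \mathrm{hits})\right],$$
where diff is the absolute difference scaled by the feature's range,
neighbors are the k nearest by Manhattan distance on range-normalized
features (k = 10 by default, clipped to availability, uniform within
k), and constant features score 0. The merit of a feature is its weight
averaged over leave-one-out folds (drop one sample, recompute), ranked
descending with lexicographic tie-break. Inside folds a class may be
reduced to one member; the driver then tolerates the singleton (an
instance without same-class neighbors contributes only its miss term)
and skips a fold only if a class is emptied. The expression input is
`log2(TMM-cpm + 1)`; the transform, k and the distance are declared
knobs — the source names none of them, and range normalization keeps
the transform choice mild.

Heatmap export takes the top-N (default 50) features by average merit
and emits per-pair `log2((C+1)/(P+1))` matrices in three panels: all,
underexpressed (negative mean), overexpressed (non-negative mean; rows
with exactly zero mean land here so the panels partition the rows).

## ssGSEA subtype classification

For one sample, genes are ranked by decreasing expression with rank
weights $r = N..1$ (stable id-order tie-break, documented because the
score depends on rank order) and the enrichment score of a set S is the
sum over the ranked walk of $P_{in}(i) - P_{out}(i)$, where $P_{in}$
accumulates $r_j^\alpha$ over set genes and $P_{out}$ counts non-set
genes. Alpha defaults to 0.75 (the convention of the public module the
original analysis invoked; the source states no alpha); alpha = 0 is
supported and gives closed-form values used by the tests (a top-ranked
singleton set in a 3-gene profile scores exactly 1.5, its bottom-ranked
mirror -1.5) plus invariance under monotone transforms. Set genes
absent from the profile are dropped before scoring, so padding a set
with unmeasured genes does not move the score. No cross-sample
rescaling is applied: scores are comparable only within a sample, which
is all the argmax subtype call requires; exact ties are broken by
declared set order and flagged.

## SAGE tag counting

Reference tags are every window of `tag_length` (default 27) starting at
a CATG tetramer and lying fully inside the 3'UTR, with the 3'-most
anchor ranked 1. A read (truncated to the tag length) is counted iff its
CATG prefix is exact, it matches an indexed tag with at most 1
substitution *outside* the anchor (the anchor defines the tag class, so
it may not absorb the mismatch — a decision the source leaves open), and
its best matches resolve to a single (transcript, position); a read
matching two positions equally well is discarded as multi-mapped even
within one transcript (the stricter reading of "single mapping
position"). Matching is Hamming only — fixed-length tags admit no
indels — and strand-specific. Discard tallies (no CATG prefix, too many
mismatches, multi-mapped, unmapped, too short) account for every read:
counted + discarded = total. A read failing the budget is classified a
near-miss ("too many mismatches") when its best distance is within
twice the budget, "unmapped" otherwise. The same split-anchor
dictionary trick as the isomiR caller makes matching fast, with an
all-windows Hamming scan as the test oracle.

## Seed-site target shift

The seed is mature positions 2-8. A position-6 A-to-G edit falls inside
it, so the edited and unedited forms recognize different canonical
sites. The scanner finds, on the given UTR strand, reverse-complement
matches of the seed core (positions 2-7) and classifies each locus
strongest-first: 8mer (positions 2-8 paired plus A opposite position 1),
7mer-m8, 7mer-A1, 6mer; ambiguous bases never match; overlapping loci
are all reported. This canonical-site scan is a declared simplification
of the original pipeline's intersection of two external prediction
programs with proprietary scoring; it preserves the qualitative
contract — a seed edit shifts the predicted target set — which the
package summarizes as lost/gained/shared transcripts and a Jaccard
index.

## The synthetic cohort: what it emulates, and what it does not

The generator produces every input with recorded truth: a miRNA
reference (random hairpins 60-120 nt, one mature of 18-25 nt each, an A
forced at mature position 6 of editable entries), paired small-RNA
samples, negative-binomial paired count cohorts, subtype expression
profiles, gene sets, and CATG-anchored UTRs. Study conditions are the
defaults: 10 C/P pairs at 50,000 reads per sample (read depth is
unstated in the source; this default is desk-scale), edited fractions
0.15 (C) vs 0.45 (P) with the healthy control at the peritumor level,
per-base error 0.001, isomiR profile 70% canonical / 10% 5'-shift /
10% 3'-shift / 10% tailed, NB dispersion 0.2 with a per-patient
lognormal baseline shared within a pair, 5 planted C-vs-P miRNAs at
log2 effect 2, and 3+3 miRNAs up-/down-shifted by log2 effect 3 in all
tumor samples vs the control (the shared-signature structure). All
generators are pure functions of (configuration, seed), with per-stream
seeds derived from one master seed.

What the simulation does not emulate: colorspace reads, adapters,
realistic quality strings, cross-mapping between paralogous miRNA
families, guanine-rich UTR composition biases, or patient-level
clinical covariates. Passing tests therefore demonstrate correctness of
the algorithms under the stated generative model, not performance on
real libraries.

One caveat the default demo makes visible: with only 30 miRNAs in the
panel, planted abundance effects shift the *composition* of every
library, and TMM estimated from so few features corrects it imperfectly;
the paired permutation test can then flag tiny (|log2FC| ~ 0.05-0.15)
but systematic shifts on null miRNAs. This is the known compositionality
limitation of scaling normalization on small panels — at the 2000-feature
benchmark scale the empirical false discovery proportion is at its
nominal level — and it is why signature calls combine an FDR threshold
with an effect-size threshold (|log2FC| >= 1.5).

## Problem sizes and reproducibility

The test suite and the acceptance script run the editing study at the
full 10 pairs x 50,000 reads; the ReliefF recovery benchmark at 20
cohorts of 505 features; the differential-expression benchmark at 10
cohorts of 2020 features x 16 pairs x 10,000 permutations; and the
end-to-end pipeline twice at its defaults to confirm byte-identical
outputs. Every random stage is seeded; rerunning any driver or
`run_pipeline()` with the same configuration reproduces every table
checksum-for-checksum (the run manifest records config, package version
and output checksums; its wall times are the only non-reproducible
field, which is why it is excluded from the byte-comparison contract).
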