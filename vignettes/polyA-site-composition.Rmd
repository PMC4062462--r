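---
title: "Mapping poly(A) sites and profiling 3'UTR / 3'COR base composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping poly(A) sites and profiling 3'UTR / 3'COR base composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis

When a pre-mRNA is 3'-processed, the transcript is cleaved and
polyadenylated; the genomic sequence downstream of the cleavage junction —
the 3' cleaved-off region (3'COR) — is discarded, while the 100 or so
transcript bases upstream form the distal 3'UTR. `polyAcomp` reconstructs
cleavage junctions from polyadenylated transcript sequences alone and asks a
compositional question: how do the base frequencies of the 3'UTR and 3'COR
around each junction compare with the whole-genome background, within and
across species groups (mammals, non-mammal animals, dicotyledonous and
monocotyledonous plants)?

The procedure is deliberately simple and strict:

1. **Tail screening.** A transcript is accepted as polyadenylated when it
   ends in at least 12 consecutive A's (`min_tail = 12`). The tail is taken
   as the *maximal* trailing A-run. U's are normalised to T on input.
2. **Anchor extraction.** The 100 bases immediately upstream of the tail
   (80 in short-read mode) form the anchor. Anchors containing ambiguity
   codes are rejected — an N can never exact-match. Transcripts are
   deduplicated by anchor before mapping.
3. **Zero-mismatch placement.** Each anchor is matched exactly against both
   strands of the reference assembly. Exactness is the contract: any
   implementation must agree with a naive scan of every offset, which the
   test suite enforces against a quadratic-time oracle.
4. **Site calling.** A hit defines the junction (last templated base). The
   site base (position 0, the genomic base under the first tail A) and the
   100-base downstream window are extracted, reverse-complemented on the
   minus strand so every reported window reads 5'→3' in transcript
   orientation. Sites are deduplicated by their upstream window; the
   representative of a multi-locus anchor is the lexicographically smallest
   (chrom, junction, strand) triple.
5. **Artifact flagging.** A genomic A-run of ≥ 12 bases starting at
   position 0 means oligo-dT priming (or read fragmentation) could have
   fabricated the "tail"; such sites carry `ip_flag`. Flagged sites are
   never silently dropped — exclusion (`exclude_ip_sites`) is a
   reporting-level choice, since the biological screen operates at the
   species level, not the site level.
6. **Profiles and ratios.** Per-position A/C/G/T counts across all sites
   give the junction-relative metaprofile; pooled window compositions, the
   region/genome ratio of each base (U matched to T), the per-position
   ratio track, and the U/A ratio of the distal window follow.
7. **Group statistics.** Species are the experimental unit: one-way ANOVA
   and Duncan's multiple range test with a letter display compare
   region-by-group U contents and region/genome U ratios; an equal-variance
   two-tailed t-test compares distal-window U/A ratios between
   super-groups; a 2×2 Pearson chi-square (no continuity correction, i.e.
   spreadsheet CHITEST semantics) compares pooled 6-base A counts between
   mapping methods.

## Coordinate conventions

All internal coordinates are 0-based, half-open, on the forward strand of
the deposited assembly. Junction-relative positions are:

| positions | meaning |
|---|---|
| −100..−1 | 3'UTR window (`UTR100`) — the anchor itself |
| 0        | site base: the genomic base under the first tail A |
| +1..+100 | 3'COR window (`COR100`) — downstream of, and excluding, the tail start |
| −100..−51 | distal window (`DISTAL50`), clear of near-site A/U-rich motifs |
| 0..+5    | `SIXBASE`, the internal-priming diagnostic window |

Position 0 belongs to neither `UTR100` nor `COR100` by default. Two
published readings of "the 100 bases downstream" exist; the
`cor_includes_site` switch moves `COR100` to 0..+99 for the inclusive
reading, while the default keeps the exclusive one, which makes the
201-base arithmetic (100 + 1 + 100) exact. The 6-base window always
includes position 0.

Because the tail is trimmed maximally, a genome-templated A immediately
before the true cleavage point would shift the called junction upstream
past it. This is an inherent ambiguity of tail-anchored mapping — from the
transcript alone, a terminal templated A is indistinguishable from the
first tail A. The synthetic generator therefore never places an A at
position −1 (see below), and real-data users should read called junctions
as "the 3' end of the maximal templated non-A-terminated prefix".

## Whole-genome background

The background composition is the percentage of A, C, G and T over all
chromosomes (or large scaffolds — any FASTA record counts). Non-ACGT
letters are excluded from both numerator and denominator; soft-masked
lowercase letters are uppercased and counted, since whole-genome totals are
wanted, not repeat-masked ones. The background uses the deposited strand
as-is by default; `symmetrize_background` averages A with T and C with G
for a strand-symmetric background. Region/genome ratios are computed per
species and *then* averaged across species — the ratio of group means is a
different (and wrong, for the species-level ANOVA design) quantity, and a
regression test pins the order of operations.

## Group statistics

`duncan_mrt()` implements the protected stepwise multiple range test: group
means are ranked; a span of `p` adjacent ranked means is tested against the
least significant range `q(α_p, p, ν) · sqrt(MSE / n_h)` where
`α_p = 1 − (1 − α)^(p−1)` and `q` is the studentized-range quantile
(`stats::qtukey`); a span contained in a non-significant wider span is
declared non-significant without testing. Letters are read off the maximal
non-significant spans. Two choices were genuinely open:

* **Unequal group sizes.** `n_h` is the harmonic mean of the two compared
  group sizes (the Kramer extension). Published software defaults for
  unequal-n Duncan tests vary; this choice is documented and pinned by
  tests rather than guessed as anyone's intent.
* **Quantile source.** Critical values come from `qtukey`, spot-checked in
  the tests against published Duncan tables (e.g. `r(0.05, 2, 16) = 2.998`).

The t-test is the classical pooled-variance two-tailed test; a zero pooled
variance with equal means returns `p = 1` flagged degenerate rather than
erroring. The 6-base chi-square contingency is built as (A count, non-A
count) × method over the pooled 6-base windows — the construction is an
assumption of this package and is stated as such.

## The synthetic-data generator

Real genome/mRNA snapshots are neither portable nor stable, so every stage
is validated against `generate_dataset()`, which emulates the data model
the analysis assumes:

* chromosomes drawn i.i.d. from `background_probs` — default
  A/C/G/T = 0.30/0.20/0.20/0.30, the A+T-rich regime typical of the
  genomes this analysis targets;
* planted, stranded junctions (~50/50 strand split) whose upstream windows
  are drawn from `utr_probs` (default 0.28/0.17/0.18/0.37 — U-rich, C-poor,
  the U ≫ A ≫ G > C regional pattern) and downstream windows from
  `cor_probs` (default 0.30/0.17/0.19/0.34, slightly less U-rich than the
  UTR);
* poly(A) tails uniform on 12–30 bases; optional verbatim duplicates;
* optional internal-priming artifacts: a genomic A-run of 12–20 bases is
  planted at position 0 and the supporting "transcript" ends inside it, so
  its tail is genome-templated;
* optional fragmentation into short reads: every transcript keeps its
  3'-terminal fragment (tails stay detectable) and `n_internal` additional
  fragments end at random internal positions, the mechanism by which
  fragmentation fabricates false tails at genomic A-stretches.

Two guards make planted truth *exactly* recoverable, so the end-to-end test
can demand coordinate-identical output: the last templated base is never an
A (otherwise maximal trimming would shift the junction), and a non-artifact
downstream window opening with ≥ 12 A's (probability ≈ 2×10⁻⁶ per site) is
redrawn. Sites are planted on a 250-bp grid so windows never collide.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: sequencing error, quality scores, splicing within
the anchor, alternative polyadenylation at one locus, repeat structure
(anchors are unique almost surely in i.i.d. sequence; real genomes have
paralogs and repeats that multi-map), and composition heterogeneity along
chromosomes (isochores). The pipeline's behaviour under those conditions is
bounded by its strictness — a repeat-hosted anchor contributes one site by
the dedupe rule — but is not quantified here.

## Numerical and reporting choices

* Percentages and ratios are reported to 2 decimals with half-up rounding
  (`round_half_up`), matching published table conventions; full precision
  is kept internally and in machine-readable output.
* Count-derived compositions must sum to 100 exactly; user-supplied
  published rows are accepted within ±0.05 of 100 (printed rounding — one
  published row sums to 99.99).
* Degenerate inputs are flagged, not silently absorbed: empty site sets and
  zero-ACGT genomes error; zero-variance statistics return flagged
  conventional values.
* A species with fewer than `min_sites` (default 100) unique sites is
  marked excluded with a warning, mirroring the practice of dropping
  species with too few mapped sites from cross-species comparison.

## Problem sizes used in validation

The test suite runs on simulated species of 20–200 planted sites on
genomes of 12–100 kb (the exact-match oracle is quadratic, so its
equivalence checks use 80 kb of genome and short probe patterns), 1000
replicates for the ANOVA type-I-error simulation, 400 replicates for the
protected-test level, and a 900-kb single-chromosome genome with ~800 kb of
transcript coverage and 1.5 million sampled fragments for the paired
A-rich/balanced fragmentation comparison. These sizes were chosen so each
stochastic assertion sits at least three standard errors from its pass
boundary under the stated generative model.
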