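---
title: "solidfrac: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{solidfrac: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solidfrac)
```

## What the pipeline does

Human peripheral blood carries RNA in cells, in extracellular membrane
vesicles (microvesicles, exosomes), and in cell-free ribonucleoprotein
complexes. Sequential centrifugation separates whole blood into five
fractions — cells (1,200g pellet), platelet-poor plasma, a 16,000g
plasma pellet enriched in microvesicles and cell-free mitochondria, a
160,000g pellet enriched in exosomes, and the vesicle-depleted 160,000g
supernatant — and small RNA-seq of each fraction asks which RNA classes
travel in which compartment, and how the profiles shift in disease
cohorts (here: healthy donors versus lung squamous cell carcinoma and
lung adenocarcinoma patients, one pooled library per fraction per
cohort, 15 libraries in all).

`solidfrac` implements the computational side of that design as a
reusable, tested pipeline:

1. **Color-space read handling.** SOLiD reads are di-base encoded: each
   symbol 0–3 encodes the transition between adjacent bases, anchored
   on a known primer base (identical pair → 0, A/C or G/T → 1, A/G or
   C/T → 2, complementary pair → 3). With bases mapped A,C,G,T → 0–3
   this code is the XOR of the two base codes, which the implementation
   exploits; tests check it against a table built literally from the
   pairing rule.
2. **Iterative 3'-trimming alignment.** Inserts are size-selected to
   >19 nt but reads are 50 nt, so short inserts run through into the 3'
   adapter. Reads are mapped full length first, then trimmed at the 3'
   end in 11 steps of 4, 3 and 2 nt down to 19 nt, stopping at the
   first length that aligns.
3. **Three-tier hierarchical classification.** Tier 1 holds adapters
   plus structural and repeat RNAs (mitochondrial transcripts, rRNA,
   tRNA, Y RNA, U snRNAs/7SK, SINE including 7SL, LINE, LTR, DNA and
   other repeats); tier 2 holds exonic mRNA/ncRNA transcripts; tier 3
   is the genome. A read is assigned by the first tier that places it,
   so e.g. a mitochondrial read never leaks into tier 2 even when a
   nuclear transcript shares sequence.
4. **Class contribution tables** (one placement per read, `k = 1`) and
   **FPKM quantification** (up to two placements, `k = 2`) with a
   minimum-alignment-count eligibility filter of 100 summed fragments.
5. **Differential distribution testing** with upper-quartile
   normalization and a negative-binomial Wald test: fractions against
   fractions with cohorts as replicates, and cohorts against cohorts
   within each fraction.

A synthetic-data generator reproduces the library geometry and class
mixtures, so every stage runs and is tested with no external download.

## The trimming ladder

`make_trim_schedule(50, 19)` is pinned to steps
`4,3,3,3,3,3,3,3,2,2,2` (lengths 50, 46, 43, 40, 37, 34, 31, 28, 25,
23, 21, 19). Eleven steps of sizes 4/3/2 from 50 to 19 do not determine
a unique multiset or order; this default uses all three sizes with
larger trims first so adapter sequence is shed quickly. For other
length pairs the schedule uses the fewest steps with sizes in {4,3,2},
larger first; a difference of exactly 1 nt is not representable and is
rejected. Both defaults are overridable via the `steps` argument.

Trimming stops at the first ladder length that yields a placement;
deeper trims are never tried for a placed read. This prevents a long
read from also matching as a shorter, less specific fragment, and makes
the output deterministic.

## Alignment semantics

The aligner is an exhaustive-by-construction matcher, not a heuristic:
a pigeonhole 6-mer index proposes candidate diagonals (a read with at
most `max_mismatches` mismatches over ≥19 symbols always contains one
clean segment among `max_mismatches + 1`, whose leading 6-mer is an
exact index hit), and each candidate is verified by full mismatch
counting. When segments would be shorter than the seed the aligner
falls back to scanning every offset. Tests compare it record-for-record
against an independent brute-force scan over all offsets, strands and
ladder lengths.

Color-space reads are compared in color space against the
color-encoded reference; the first color, which encodes the
primer-to-first-base transition, is checked against the primer
transition at the candidate position. One base substitution appears as
two adjacent color mismatches, so the default `max_mismatches = 2` (in
color space) tolerates roughly one base error. The mismatch allowance
of the study's external aligner is not documented; 2 is this package's
configurable default, not a reproduced constant. Reverse-strand
matching color-encodes the reverse complement of each reference, which
is equivalent to reversing the color string. Qualities are carried for
format fidelity but do not enter alignment — no quality threshold is
part of the method.

At most `k` placements per read are reported (`k = 1` for contribution
tables, `k = 2` for quantification), ranked deterministically: fewest
mismatches, longest aligned length, lowest reference id (C-locale
lexicographic), lowest position, `+` strand before `-`. The external
tool's tie-breaking is unspecified; a fixed total order was chosen so
that reruns are identical. All reported coordinates are 1-based and
fully closed.

## Contribution tables and quantification

Adapter/primer matches are filtered in tier 1 and excluded from the
reportable total: contribution tables list no adapter row, so
percentages are over mapped, biological reads only. Percentages sum to
100 by construction; a library with zero reportable reads yields `NA`
percentages and a warning rather than an error.

For FPKM, a read with two placements contributes half a fragment to
each feature (uniform split, switchable to primary-only), which makes
fragment counts sum exactly to the number of placed reads. Features are
tier-1 (minus adapter) and tier-2 entries; genome placements count
toward the mapped total but genome loci are not features — locus
discovery on the genome tier is out of scope. Eligibility for testing
is a summed fragment count of at least 100 across the libraries of the
comparison, evaluated per contrast.

## Differential testing

For each contrast, libraries are scaled by upper-quartile factors
(75th percentile of nonzero counts, divided by their geometric mean so
normalized counts keep the raw scale). The test models normalized
counts as negative binomial with `Var = mu + alpha * mu^2`.

Dispersion is estimated per feature by method of moments, then
*moderated*: the raw estimate is shrunk toward a fitted mean-dispersion
trend `alpha(mu) = a0 + a1/mu` with weight `d / (d + prior_df)`, where
`d` is the group's residual degrees of freedom and `prior_df = 4` by
default. With three replicates per group, raw per-feature moment
estimates are extremely noisy; a few features get accidentally tiny
variance estimates and, without moderation, wildly optimistic standard
errors. Simulation during development showed that the unmoderated test
holds its size at the 0.05 level but is anticonservative deep in the
tail (about 9-fold at p < 0.001), which corrupts FDR control; with
`prior_df = 4` both the 0.05 level (empirically ≈ 0.04 under a
dispersion-0.1 null at 3-vs-3) and the tail are calibrated while
8-fold effects remain essentially always detected. Replication
structure follows the study's two modes: `per_condition` (estimate in
each group, take the per-feature maximum) when both groups have
replicates, `blind` (pool all libraries as one group) when either group
is a single library.

The test itself is a Wald test on the log of the group means,
`Var(log mean) ≈ (1/mu + alpha) / n`, against a normal reference. A
t reference with the naive 4 degrees of freedom was rejected by the
same simulations as far too conservative (empirical size ≈ 0.01)
because the max-of-groups dispersion already inflates the standard
error. Group means of zero are stabilized at `0.5/n` for the statistic;
the reported log2 fold change is the raw ratio of normalized means
(infinite when one side is all zero, 0 when both are). Benjamini-
Hochberg q-values are computed within each contrast over eligible
features only; tests verify them against a brute-force BH computation.

`run_contrasts()` enumerates the study layout: 10 fraction-pair
contrasts (3 cohort libraries per side, per-condition dispersion) and
10 cohort contrasts (healthy versus each patient cohort within each
fraction; 1-vs-1, blind dispersion).

## The synthetic-data generator

The generator defines the conditions everything is tested under:

* **References**: random sequences with class-typical lengths — tRNA
  70–90 nt, Y RNA ~100 nt, snRNA 100–331 nt, the four rRNA species at
  121/156/1,869/5,070 nt, mitochondrial transcripts 70–1,600 nt, repeat
  consensi 100–6,000 nt, mRNA 500–3,000 nt, ncRNA 200–2,000 nt, plus a
  60-kb genome stand-in. Every sequence is synthetic; nothing is
  downloaded, and no vendor adapter sequence is used (the default
  adapter is a fixed synthetic 35-mer). An audit checks that no
  50-nt substring is shared between entries on either strand, so class
  assignment on simulated data has a unique truth.
* **Reads**: class drawn from the library's mixture profile, feature
  within class by log-normal weights (`sdlog = 1`: a handful of
  features dominate each class, as in real small RNA libraries),
  fragment uniform within the feature with insert length uniform in
  [20, 100] nt (the >19 nt size selection), read = first 50 nt of
  insert + adapter, color-encoded from primer base `T` (the platform
  convention; the study does not state its primer base). The default
  per-color error rate is 0 — the study states no error model — and a
  uniform substitution rate is available for robustness experiments.
* **Mixtures**: the default class proportions per (fraction, cohort)
  are the published relative-contribution percentages of the five
  fractions and three cohorts, renormalized to sum to 1 per library.
* **Determinism**: a `sim_config` seed fixes everything byte-for-byte;
  per-library seeds are derived from the fixture seed.

What the generator does *not* emulate: real sequence content (human
homology, GC bias), PCR duplication, quality-dependent errors,
missing color calls (`.` is rejected at parse, never imputed), or
chimeric inserts. Passing tests therefore demonstrate the pipeline's
logic — tier precedence, trimming, accounting, calibration — under the
study's geometry, not performance on real SOLiD data.

## Numerical choices and degenerate inputs

* Reads shorter than 19 nt get a `too_short` status, never an error.
* A read placed nowhere across all tiers is `unmapped` and appears in
  no table; reportable + adapter + unmapped always sums to the input.
* Empty read sets, empty tiers and zero-read libraries return empty,
  well-typed results.
* A library with all-zero counts fails upper-quartile normalization
  with an error naming the library.
* Dispersion estimates are floored at 1e-8; the trend fit needs 10
  usable features and otherwise falls back to the median, then to the
  floor.

## Problem sizes used by the test suite

Unit tests run on instances of a few hundred nt and tens of reads,
where the brute-force oracle is exact and fast. The headline
property tests use a 100,000-read fraction-III-style library (class
mixture recovered within ±2 percentage points; in practice the maximum
deviation is ~0.2 points), 50 random aligner-oracle instances, 1,000
color-space roundtrips, and 1,000-feature 3-vs-3 null and planted-
effect simulations. The full 15-library pipeline test runs at 800
reads per library, which already exercises every stage including all
20 contrasts. These sizes are the package's chosen operating points
for routine verification; all are plain function arguments, so larger
runs are one argument away.

## Known limitations

* The aligner is ungapped, as the trimming-ladder method assumes;
  indels are out of scope.
* No numeric equivalence with the study's external tools (Bowtie,
  Cufflinks/Cuffdiff) is claimed anywhere: the pipeline reimplements
  the documented *procedure*, with its own documented choices where
  the tools' internals are unspecified.
* Genome-tier quantification stops at class attribution; novel-locus
  discovery and annotation are not implemented.
* The published significance lists for real libraries cannot be
  reproduced because the underlying reads were never deposited; only
  the machinery that would produce such lists is provided.
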