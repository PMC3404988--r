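---
title: "Methods: T-RFLP kleptoplast profiling and amino-acid isotope trophic positions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: T-RFLP kleptoplast profiling and amino-acid isotope trophic positions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trflpr)
```

## The measurement model

Terminal restriction fragment-length polymorphism (T-RFLP) profiles a mixed
amplicon pool by one number per template type: the length of the
fluorescently labelled terminal fragment after restriction digestion. For
kleptoplast source profiling, the chloroplast *rbcL* gene is amplified from
sea-slug digestive-gland DNA with a degenerate consensus primer pair whose
forward primer carries the 5' label, the product is cut with TaiI
(recognition `ACGT`), and a capillary sequencer reports peak height versus
called fragment size. Because different source-alga clades place their
5'-most TaiI site at different distances from the labelled primer, the
predicted fragment length identifies the clade, and peak height measures
the clade's share of the amplicon pool.

The analysis chain is therefore:

1. *Design*: predict, per reference sequence, the labelled fragment length
   (`extract_amplicon()`, `predict_trf()`), group clades whose predicted
   lengths cannot be told apart on a sizing trace (`trf_categories()`), and
   rank candidate enzymes by how many clades they resolve
   (`screen_enzymes()`).
2. *Profile*: quality-filter chromatograms, match observed peak sizes to
   predicted category lengths, and normalise heights to relative abundances
   (`qc_chromatograms()`, `assign_peaks()`, `relative_abundance()`,
   `aggregate_by_month()`).
3. *Test*: compare a category's per-individual relative abundance between
   collection months with a permuted Brunner-Munzel test
   (`compare_months()`).
4. *Trophic position*: estimate where the animal feeds from the
   glutamic-acid/phenylalanine delta-15N offset (`trophic_position()`,
   `group_tp()`).

Key modelling assumptions, stated once: chloroplast genome copy number is
taken as constant across source algae, so *rbcL* amplicon share is read as
kleptoplast share; PCR amplification efficiency is taken as uniform across
clades (the motivation for consensus primers); and peak height (not area)
represents template quantity.

## Coordinates and sequence conventions

Match positions are 1-based, R's native convention. A terminal-fragment
length is the count of bases from the labelled 5' terminus through the last
base before the cut, i.e. `match_start - 1 + cut_offset`. TaiI is shipped
as recognition `ACGT` with `cut_offset = 4` (cleavage immediately 3' of the
site on the labelled strand); the offset is an explicit, configurable field
of `restriction_enzyme()` because cleavage-convention differences between
prediction tools show up as constant +/- few-bp shifts in predicted
lengths. Degenerate matching treats IUPAC codes on either side as
nucleotide sets that match when they intersect; matching is delegated to
Biostrings and checked in the test suite against an independent
set-expansion oracle.

When several primer sites exist, the amplicon runs from the 5'-most forward
site to the 3'-most compatible reverse site - the maximal outer product,
which dominates in PCR. If the labelled primer is the reverse one, the
amplicon is reverse-complemented so the labelled terminus is always
position 1.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `qv_min` | 75 | quality score | chromatograms kept only when QV strictly exceeds 75 |
| `size_min`, `size_max` | 100, 1200 | bp | peaks outside the size-standard range are noise (inclusive window) |
| `tolerance` (assignment and merging) | 1.5 | bp | typical capillary size-calling precision; two clades separated by more than `2 * tolerance` are resolvable, anything closer merges |
| dedup `threshold` | 0.001 | p-distance | clones closer than this (strictly) are treated as PCR copies |
| chimera `min_divergence` | 0.005 | p-distance | discordant halves below this are indistinguishable from within-clade variation |
| `n_perm` | 10000 | draws | Monte-Carlo permutation budget; exhaustive enumeration replaces it when `choose(n, n_x) <= 20000` |
| `beta`, `tef` | 3.4, 7.6 | permil | producer-level Glu-Phe offset and trophic enrichment factor of the standard marine calibration; configurable for other calibrations |

The observed-to-predicted size tolerance deserves a note: fragment-analysis
software does not export one, so the default of 1.5 bp is a deliberate
package choice kept consistent with the category-merging rule (categories
are merged exactly when a peak could sit within tolerance of both).

## The permuted Brunner-Munzel test

The Brunner-Munzel statistic addresses the nonparametric Behrens-Fisher
problem: it tests `P(X < Y) + 0.5 P(X = Y) = 1/2` using pooled midranks and
a rank-based variance estimate, without assuming equal variances. At the
sample sizes of monthly field collections (often 3-8 individuals) the
t-approximation is unreliable, so the null distribution is built by
reassigning the pooled values to groups of the observed sizes:

- all `choose(n, n_x)` assignments are enumerated when there are at most
  20,000 of them, and the two-sided p-value is the exact proportion of
  assignments with `|W*| >= |W_obs|`;
- otherwise `n_perm` seeded Monte-Carlo reassignments are drawn and
  `p = (1 + #{|W*| >= |W_obs|}) / (1 + n_perm)`, which cannot be zero.

Degenerate assignments need a convention: when the pooled rank variance is
zero, the statistic is defined as 0 if the group mean midranks agree (all
values tied) and +/-Inf under perfect separation, so perfectly separated
samples count themselves and their mirror image in the tail - three fully
separated values per group give exactly p = 2/20 = 0.1. Group sizes of one
contribute zero variance. The comparison `|W*| >= |W_obs|` is applied with
a relative slack of 1e-9 so ties in rank configurations are never lost to
floating-point rounding. The permutation loop is compiled (Rcpp) and driven
by R's RNG, so `set.seed()`/`seed =` reproduce runs exactly. No
multiple-testing correction is applied by default (month pairs are reported
with raw p-values); `p.adjust()` composes naturally with `tidy()` output
when a family of comparisons is tested.

## Trophic position

`TP = (d15N_Glu - d15N_Phe - beta) / tef + 1` is linear in the two deltas,
so averaging specimens before or after applying the formula gives the same
full-precision group mean; the distinction only appears once printed
(rounded) group means are fed back into the formula. That is exactly the
situation with published summary tables, and why `group_tp()` reports both
`tp_mean` (mean of per-specimen TPs) and `tp_from_mean_deltas`. One
published giant-clam adductor-muscle group illustrates it: the rounded
group means 16.1 and 5.5 give TP 1.947, which displays as 1.9, while
averaging unrounded per-specimen values prints 2.0. Display rounding is
half-away-from-zero at one decimal, matching how isotope tables are
printed; dispersion defaults to the sample standard deviation (n-1), with
the population convention available - the published tables do not state
which was used.

## What the synthetic generators emulate

`simulate_reference_set()` builds clades around a shared ancestral core:
every reference carries a literal expansion of both primers and exactly one
engineered recognition site whose position sets the clade's T-RF; stray
upstream recognition matches are scrubbed so the engineered site is always
5'-most. Within-clade variation is placed strictly downstream of the cut
site, so a clade's predicted T-RF is exact by construction - which is what
makes the generator usable as ground truth. Engineered length collisions
reproduce the real phenomenon of indistinguishable taxon pairs; an
8-clade set with two collisions yields exactly 6 categories.

`simulate_clone_library()` draws clones multinomially, applies uniform
point substitutions (default 0.001/base, the scale of polymerase error over
a cloning experiment) and splices a configurable fraction of two-parent
chimeras at a breakpoint in the middle third of the alignment.
`simulate_electropherogram()` emits one peak per clade at the predicted
length with Gaussian size jitter (default sigma 0.3 bp) and lognormal
multiplicative height noise (default CV 10%; lognormal keeps heights
positive), height proportional to mixture weight - the constant-copy-number
assumption made explicit. `simulate_aa_isotopes()` inverts the TP formula
with independent Gaussian errors on both deltas; the default
phenylalanine baseline of 7.3 permil is a typical shallow-water value.

What the generators deliberately do **not** emulate: indels and alignment
uncertainty (all sequences are generated equal-length, because every
distance operation downstream assumes an alignment), phylogenetically
structured substitution processes, differential PCR efficiency between
clades, peak shape/baseline artefacts, and size-calling bias that varies
with fragment length. Passing the recovery tests therefore shows the
pipeline's arithmetic and decision rules are right under the stated noise
model - not that field electropherograms are free of matrix effects.

The reference sequences for the two single-species validation algae are not
bundled; the corresponding check runs on synthetic stand-ins engineered to
the published 306 and 331 bp lengths, which exercises the same code path
but validates geometry by construction rather than against the archived
accessions.

## Degenerate inputs and tie-breaks

- A peak exactly equidistant from two categories is flagged ambiguous and
  left unassigned rather than arbitrarily attributed.
- Unassigned peak height stays in the RA denominator (the total is "all
  T-RF peak heights"); a flag removes it for sensitivity analysis.
- Uncut amplicons are excluded from category building by default; a flag
  admits full amplicon length as a pseudo-T-RF.
- Clone-dedup representatives are the most frequent member sequence, ties
  broken by smallest id; two clones at exactly the threshold distance stay
  separate (the rule is strict `<`).
- All-tied samples give Brunner-Munzel statistic 0 and p = 1; chromatograms
  with zero total height raise an error rather than returning NaN profiles.
- Monthly five-number summaries use linear interpolation between order
  statistics (quantile type 7) and say so in an output attribute; months
  with fewer than three individuals are flagged low-n, and categories
  absent from a sample enter its month summary as 0%.

## Problem sizes used by the shipped checks

The test suite sizes its simulations to be decisive yet quick: 1,000
random amplicons for the digestion-oracle equivalence, 5,000 null
replicates (10 vs 10, 1,999 Monte-Carlo draws each) for the test-size
calibration against the [0.044, 0.056] band, 100 electropherogram
replicates for 50/30/20 mixture recovery within 3 percentage points, 500
replicates for isotope-estimator unbiasedness, and 400-clone libraries for
chimera-fraction recovery. These are the package's chosen experiment sizes;
enlarging them only narrows the Monte-Carlo bands.

## Known limitations

The chimera screen is a deterministic midpoint-split nearest-reference
test: it captures the intent of tree-based screening (discordant 5' and 3'
ancestry) without external databases, but it cannot detect chimeras of
parents closer than `min_divergence`, breakpoints far from the midpoint
reduce its contrast, and it presumes the references span the true parents.
Alignment is out of scope - real clone data must be aligned before
`p_distance()`/`dedup_clones()`. QV is consumed as a supplied scalar; raw
trace processing, baseline correction and peak deconvolution belong to the
fragment-analysis software. Published per-month p-values cannot be
recomputed without the per-individual peak tables, which were never
printed; the package instead demonstrates calibration and power of the test
on simulated data.
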