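---
title: "Discovering chromosome-specific satellites by oligonucleotide profiling"
author: "oligoSat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering chromosome-specific satellites by oligonucleotide profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(oligoSat)
```

## The problem

Some chromosomes carry a sequence identity of their own.  In *Drosophila*,
the X and the dot chromosome are each recognized by chromosome-specific
binding proteins, and both turn out to be overpopulated by particular
tandemly repeated, noncoding sequences — satellite DNA — that turn over
rapidly between species.  Detecting such satellites, characterizing their
repeating unit (the *monomer*, classically a 359-bp sequence on the
*D. melanogaster* X), mapping their dispersed copies genome-wide, testing
whether copies evolve in concert, and asking how their density relates to
local recombination rate together form a small analysis pipeline.  oligoSat
implements that pipeline end to end, together with a synthetic-genome
generator so every stage can be validated against known ground truth
without any external data.

## The profiling statistic

The central statistic is a length-normalized relative k-mer frequency.
For a k-mer $w$ occurring $k_X$ times on a focal chromosome of total
length $L_X$ and $k_A$ times on the pooled background chromosomes of total
length $L_A$,

$$ X/A(w) \;=\; \frac{k_X \, L_A}{k_A \, L_X}. $$

A value of $i$ means $w$ is $i$ times more frequent per bp on the focal
chromosome.  Computing this for every consecutive k-mer position along the
focal chromosome gives its oligonucleotide profile
(`relativeProfile()`).  Two structural consequences are worth noting and
are covered by tests: the statistic is symmetric (swapping the groups maps
every ratio $r$ to $1/r$), and it is scale invariant (duplicating the
background changes neither numerator nor denominator per bp).  When the
two groups have equal counts for a k-mer, the statistic reduces to the
length ratio $L_A / L_X$; with $L_X = 0.34\,L_A$ this is $2.94$, a useful
analytic fixed point that the acceptance script recomputes from an actual
profile.

Key parameter choices:

* **k = 13** (default, configurable 1–26).  Long enough that a 13-mer is
  effectively chromosome-specific in a ~10^8 bp genome, and prime, so the
  profile is not dominated by simple di-/trinucleotide repeats whose
  periods divide composite k.
* **Canonical strands** (default `canonical = TRUE`).  Satellite arrays
  occur in both orientations, so a k-mer and its reverse complement are
  pooled under one canonical key.  The original profiling literature does
  not pin down a strand convention, so both modes are supported and the
  choice is recorded in every container.
* **N handling.**  Windows containing any non-ACGT base are skipped on
  both sides of the ratio; assembly gaps can therefore never manufacture
  enrichment.
* **Zero-background k-mers.**  A k-mer absent from the background gets a
  sentinel denominator count of 1 and a `backgroundAbsent` flag.  These
  are the most focal-specific signals; dropping them would hide exactly
  the clusters the method exists to find.

Counting is exact and streaming (2-bit rolling codes in compiled code);
only the distinct-k-mer table is materialized, and profiles are computed
one chromosome at a time.

## Cluster calling

Satellite arrays appear in the profile as runs of positions with very
high ratios.  `callClusters()` takes maximal runs of positions with ratio
strictly above a threshold (default 20, so ties at the threshold are
excluded), merges runs separated by at most `mergeGap` bp, and discards
merged runs shorter than `minLen` bp.

The threshold 20 is the classical working definition of an
overrepresented cluster for this statistic.  The merge gap (200 bp) and
minimum length (500 bp) are this package's own choices: typical satellite
clusters span roughly 1–20 kb, so 500 bp admits the smallest real
clusters while suppressing single-k-mer spikes, and 200 bp bridges the
short low-ratio interruptions that substitution-diverged copies produce
inside a real array (every substitution breaks k consecutive k-mers).
Because runs are defined on valid positions only and merging is purely
distance-based, N-gaps inside an array do not split a cluster unless they
exceed the merge gap.

## Monomer inference

Where a dedicated tandem-repeat finder would be used externally, oligoSat
infers the repeating unit internally and deterministically:

* `estimatePeriod()` scores each candidate period $p$ by the fraction of
  positions whose 8-mer seed recurs exactly $p$ bp downstream
  (autocorrelation of exact seed matches).  Every multiple of the true
  period also scores highly, so sub-multiples are resolved by preferring
  the smallest period scoring at least 90% of the best.  A best score
  below 0.2 is reported as "no period": random sequence scores near
  $4^{-8}$ per offset, far below this floor, while a tandem array with
  up to ~10% per-copy divergence stays at or above it (per-site match
  probability ~0.81 gives an 8-mer score of ~0.19; this is the design
  limit of the default seed length).
* `buildConsensus()` maps position $i$ to consensus column
  $((i-1) \bmod p) + 1$ and takes the per-column majority base.  Ties
  break to the lexicographically smallest base so the consensus is
  deterministic; columns without A/C/G/T evidence become N.  Both steps
  are rotation invariant (a circularly rotated array yields the same
  period and a rotation-equivalent consensus), which matters because an
  array has no privileged start.
* `groupFamilies()` single-links monomers whose best pairwise identity —
  computed forward and reverse-complement against the doubled partner, so
  any circular rotation can match — exceeds 0.7, and elects the longest
  member of each family as representative.  The 0.7 threshold is a
  package decision: empirically related satellite variants show
  similarities well above it (e.g. ~0.79 between known sibling
  satellites), while the best local identity between unrelated random
  sequences of this length stays far below.  Family labels are numbered
  by each family's lexicographically smallest member id, making the whole
  assignment invariant to input order.

## Genome-wide mapping

`searchMonomer()` is a self-contained BLASTN-like nucleotide search:
exact 11-mer seed matches on both strands are extended ungapped in both
directions under match +1 / mismatch −2 with an X-drop of 12, and each
surviving high-scoring pair receives a Karlin–Altschul expectation value
$E = K m n e^{-\lambda S}$ with $m$ the monomer length and $n$ the total
searched length.  $\lambda$ is solved numerically for the chosen scores
(the positive root of $\frac14 e^{\lambda} + \frac34 e^{-2\lambda} = 1$
for the defaults); $K$ uses the standard ungapped nucleotide value 0.621
for +1/−2 and is reused as an approximation for other schemes.  Hits with
$E$ below 10^−4 are reported; overlapping same-strand extensions collapse
to the highest-scoring one.  Gapped alignment is deliberately out of
scope: diverged satellite copies are recovered through the short seed and
the mismatch tolerance of extension, and the E-calibration and
planted-copy-recovery tests confirm that this suffices at the divergence
levels the generator emulates (≤ ~10% substitutions; copies with many
indels would be found only partially).

`coverageTable()` reports per-chromosome hit counts and percent covered
(union of hit intervals, overlaps counted once), plus the summary ratio
used for chromosome comparisons: the pooled focal percent divided by each
background chromosome's percent, averaged over background chromosomes.
`groupLoci()` applies the 1-kb rule — hits whose consecutive members are
within 1,000 bp belong to one locus — as a transitive closure, verified
against a brute-force oracle.

Internally all intervals live in `GRanges` (1-based, closed), the
standard container of this ecosystem; BED output is 0-based half-open and
round-trips losslessly.

## Concerted evolution

Satellites homogenize locally: copies within a locus resemble each other
more than copies from different loci.  To test this, copies are star-
aligned to the family consensus (`alignToConsensus()`: global alignment,
match +1 / mismatch −1 / linear gap −2, then projection onto consensus
columns, dropping copy insertions), which places every copy in a common
coordinate system — the same thing a multiple alignment provides, but
deterministic and dependency-free.  Hamming distances
(`pairwiseDistances()`) exclude gap-containing columns pairwise rather
than listwise, maximizing the compared sites per pair.  Copies shorter
than half or longer than twice the consensus are filtered before
alignment.

`withinBetweenTest()` performs a one-sided Wilcoxon rank-sum test
(within-locus distances smaller than between-locus).  The exact
distribution is used for tie-free groups up to size 20; tied groups up to
size 10 are handled by full permutation enumeration over midranks;
anything larger uses the normal approximation with tie and continuity
corrections.  The approximation agrees with the exact distribution to
within 0.01 for group sizes of 5 and above (at size 4 the worst-case
discrepancy is ~0.015, which is why the exact path covers all small
groups).

One statistical caveat is handled explicitly in the validation design:
all-pairs distance sets are not independent observations (each copy
appears in many pairs), so the rank-sum test on all pairs is descriptive
rather than exactly calibrated.  The type-I-error validation therefore
draws each distance from a disjoint copy pair, under which the test's
independence assumptions hold exactly and its size is verified to be
nominal (~5% at α = 0.05 over 1,000 null replicates).

## Satellite density and recombination rate

`makeWindows()` tiles the genome into 250-kb windows (trailing short
windows are flagged), counts hits by their start coordinate (so no hit is
double-assigned) while clipping covered bp at window boundaries (so bp
totals are conserved), and attaches the length-weighted mean
recombination rate from a user-supplied map.  `fitExponential()` fits

$$ \text{response} = e^{a + b\,\cdot\,\text{rate}} $$

by Poisson regression with a log link — chosen because it handles
zero-count windows naturally and matches the exponential form directly;
the coverage response uses covered bp with log window length as exposure,
so its intercept is the log coverage fraction at rate 0.  A
log-least-squares mode (`log(y+1)` on rate) is available for sensitivity
comparison.  Parameter recovery is verified both on noise-free data
(coefficients to 3 decimals) and on Poisson-sampled windows at reference
coefficients (−4.56, 2.14), recovered within 3 standard errors at 2,000
windows.

`predictRatio()` turns a fitted slope into an expected focal/background
coverage ratio from the groups' median per-window rates, with a
correction multiplier (default 4/3) on the focal median to account for
the smaller effective population size of an X chromosome; the intercept
cancels.  At slope 1.98 with medians 3.32 and 2.78 cM/Mb the formula
evaluates to $e^{1.98(4/3 \times 3.32 - 2.78)} \approx 26.1$.  Median
rates are computed over windows, one unweighted value per window.
`correlationReport()` adds a Spearman rank correlation as a
model-agnostic companion to the parametric fit.

## The synthetic-genome generator

`simulateGenome()` produces genomes whose statistical structure matches
what the pipeline assumes, with complete ground truth, so that recovery
can be asserted rather than eyeballed.  Its defaults define the standard
validation conditions and were chosen once, on scale arguments:

* **Geometry:** one 1-Mb focal chromosome against two 2-Mb background
  chromosomes.  The 1:4 focal:background length ratio matches the
  X:autosome proportion of a *Drosophila*-like karyotype; the absolute
  sizes keep a full pipeline run in seconds while leaving dozens of
  250-kb windows for the density model.
* **Monomer:** a random 359-bp unit (the classical X satellite monomer
  length); composition 58% AT, a *Drosophila*-like euchromatic base
  composition.
* **Loci:** 10 focal loci versus 1 per background chromosome, with
  8–40 copies per locus (arrays of ~2.9–14.4 kb, inside the typical
  1–20 kb cluster range).  A minimum spacing of 2 kb keeps planted
  arrays distinct so "exactly one cluster per array" is well defined.
* **Divergence:** locus founders carry 0.05 substitutions/site from the
  ancestral monomer (between-locus divergence); copies carry 0.02/site
  of which a fraction `h = 0.9` is homogenized back to the founder.
  Homogenization is modelled phenomenologically (founder + per-site
  reversion probability) rather than by simulating unequal
  crossing-over, because the downstream analysis consumes only the
  within-smaller-than-between distance signature, which this controls
  directly; `h = 1` makes same-locus copies identical and `h = 0`
  recovers independent mutation (expected pairwise distance
  $2\mu(1-\mu)$ per site, verified).
* **Recombination landscape:** piecewise-constant per 250-kb window —
  exactly the analysis window, so the density model is well-specified
  for fit-recovery tests — with focal rates drawn U(1.3, 5.3) and
  background rates U(0.6, 5.0), giving group medians near 3.3 and 2.8
  cM/Mb, the X-versus-autosome contrast scale.  Locus positions are
  drawn with per-window weight proportional to
  $\text{width} \times e^{b\,\cdot\,\text{rate}}$ with b = 2.14.

What the generator deliberately does **not** emulate: transposable
elements and other interspersed repeats, higher-order repeat structure,
indel mutation within copies, GC heterogeneity along chromosomes, and
the assembly artifacts of real heterochromatin.  Passing the validation
suite therefore shows that the pipeline recovers planted structure under
clean, well-specified conditions; on real assemblies, repeat-masking
choices, collapsed arrays and scaffold assignment will dominate the
error budget in ways these simulations cannot measure.

## Problem sizes used by the validation suite

The test suite runs the full pipeline on the default 5-Mb simulated
genome; oracle-equivalence checks use 100 random sequences up to a few
kb; period recovery uses 50 simulated clusters with periods U[100, 1000]
and divergence up to 10%; the rank-sum size check uses 1,000 null
replicates of 15+15 distances; exponential-model recovery uses 2,000
windows.  These sizes were chosen so each property is measured with
comfortable statistical margin while the whole suite completes in about
a minute.

## Known limitations

* The search is ungapped; heavily indel-diverged copies are reported as
  fragmented or truncated hits.
* $K$ in the E-value is exact only for the default +1/−2 scoring.
* `estimatePeriod()`'s 8-mer seeds lose power beyond ~10% per-copy
  divergence, and periods below 20 bp are outside the default search
  range (they belong to simple-repeat territory that k = 13 profiling
  deliberately discounts).
* The footnote-style coverage ratio divides by each background
  chromosome's percent and is therefore unstable when a background
  chromosome is nearly satellite-free; it is reported as `Inf` rather
  than silently clamped.
* All-pairs distance tests are descriptive under pseudo-replication (see
  above); calibrated inference should subsample disjoint pairs.
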