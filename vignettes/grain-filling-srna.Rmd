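---
title: "Profiling small RNAs across grain filling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling small RNAs across grain filling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirgrain)
```

## The problem

Cereal grain filling — the two to four weeks after pollination in which the
endosperm accumulates starch and storage protein — is accompanied by large
shifts in the small RNA population. A typical study sequences one sRNA
library per developmental stage (e.g. 5, 15, 25 and 30 days after
pollination), collapses reads to unique sequences, classifies them against
non-coding RNA catalogs, quantifies conserved miRNAs, tests stage-wise
differential expression without replicates, clusters fold-change
trajectories into a handful of developmental archetypes, searches
unannotated reads for novel miRNA precursors, and predicts targets by
complementarity. `mirgrain` implements that pipeline as composable,
tibble-first functions, with a ground-truthed simulator standing in for
the sequencing libraries.

## Preprocessing model

Reads are canonicalized to the DNA alphabet internally (U stored as T; RNA
rendered back with `to_rna()` on structure-facing output). Adapter removal
is an exact, leftmost match of the adapter's first `min_overlap` bases
(default 8): deterministic, sufficient for synthetic data, and a config
knob because real protocols vary. Reads containing N are always dropped;
mean-Phred filtering (default threshold 20) applies only when FASTQ
qualities exist — FASTA input skips it. The informative size range is
18–30 nt inclusive at both boundaries. `total_clean_reads` per library —
the TPM denominator — is defined as the post-filter read count, i.e. the
column sum of the collapsed table.

## The exact two-library count test

With a single library per stage there are no replicates, so differential
expression uses the exact conditional test for two Poisson counts: given
`x` reads in a baseline library of `N1` clean reads and `y` in a treatment
library of `N2`,

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,\bigl(1 + N_2/N_1\bigr)^{x+y+1}},$$

a negative-binomial law with size $x+1$ and success probability
$1/(1+N_2/N_1)$. The lower tail $C$ sums $y' \le y$, the upper tail $D$
sums $y' \ge y$; both include the observed point, so $C + D = 1 +
p(y\,|\,x)$ exactly.

Numerical choices:

* Terms are evaluated in log space via `lgamma`; tails are summed on
  max-scaled probabilities so a tail of $10^{-30}$ keeps full relative
  precision. The upper tail is summed directly (never as $1 - C$), with a
  truncation point taken from the exact negative-binomial quantile so the
  discarded mass is below $10^{-17}$ of the total.
* The two-sided p-value is `min(1, 2 * min(C, D))`; a one-sided option
  exists. Doubling the smaller tail is the standard two-tailed
  combination for an asymmetric discrete test.
* Only the point probability is exactly symmetric under swapping
  `(x, N1)` with `(y, N2)` when `N1 = N2`; the tails condition on
  different margins, so two-sided p-values for `(x, y)` and `(y, x)`
  agree only asymptotically. The test suite checks the exact point
  symmetry and the asymptotic tail agreement separately.
* No multiple-testing correction by default (single-library staged designs
  conventionally filter at raw p < 0.05); Benjamini–Hochberg is available
  via `adjust = "BH"`.

TPM is `count / total_clean_reads * 1e6`. Fold-changes are
`log2(treatment TPM / control TPM)` with a pseudo-TPM of 0.01 added to
both operands only when one of them is zero: stages where a miRNA becomes
undetectable stay finite without perturbing nonzero ratios.

## Trajectory clustering

Features passing the high-expression filter (maximum stage TPM at or above
`tpm_min`, default 20, inclusive) are clustered on their log2 fold-change
trajectories versus the baseline stage. Rows are not standardized —
fold-changes already share a scale. Clustering is agglomerative (average
linkage, Euclidean metric, both configurable) through `stats::hclust`,
whose tie handling is deterministic for a fixed input order; canonical
relabeling (clusters ordered by ascending mean trajectory, then size, as
Roman numerals) makes the output invariant to row permutations. The
default `k = 8` mirrors the eight archetypes recurrent in grain-filling
profiles: strong early induction held high, gradual induction, mild
induction, rapid repression, repression with partial recovery, and gradual
repression. Cluster summaries report a monotonicity class (`up`, `down`,
`transient_up`, `transient_down`, `flat`) using a 0.25 log2-unit dead
zone.

## Hairpin discovery

Unannotated reads are mapped exactly (full length, both strands) onto a
user-supplied transcript set from which protein-coding entries are assumed
removed. Around each locus a ladder of candidate windows is cut (flanks
20, 40, 60, 100 and 140 nt on the long side, 20 nt on the short side, both
orientations) so the read can sit on either arm; windows are capped at
300 nt.

Folding is weighted base-pair maximization over nested structures
(G:C = 3, A:U = 2, G:U = 1; minimum hairpin loop 3 nt), implemented in
C++ with a deterministic traceback. The score is minus the weighted pair
sum — an arbitrary stability scale, not kcal/mol. The exhaustive
enumeration oracle in the test suite pins this definition exactly for
short sequences. A thermodynamic backend (ViennaRNA/Mfold) would be
preferable for specificity; it is not available in this build, and the
consequences are stated below.

Acceptance requires six named criteria, each a config key: (c1) the
mature lies entirely on one arm of a single stem-loop (no self-pairing,
partners confined to the opposite arm of one hairpin extent); (c2) at
most 4 unpaired mature bases; (c3) no asymmetric bulge wider than 2 nt
between consecutive paired mature bases; (c4) the mature does not overlap
the terminal loop; (c5) folding score at most −15 in fallback units;
(c6) at least half the hairpin's bases paired. The star is derived by
Dicer geometry (2-nt 3′ overhangs on both strands), projecting through
the nearest paired mature base when a terminus is unpaired; a star that
runs off the window rejects the candidate. Candidates sharing a mature
and ≥50% reciprocally overlapping hairpin extents are deduplicated to the
best-scoring window — extents, not windows, so the result does not depend
on which ladder window first contained the hairpin, and orientation is
ignored because a stem-loop read in either direction at one locus is the
same physical precursor. Accepted matures are named `Ta-miRNNN-5p/-3p` in
descending total count, and two matures on opposite arms of one precursor
are linked as a 5p/3p pair.

Known limitation: with pair-maximization folding, dinucleotide-shuffled
decoy windows of realistic GC content are accepted at roughly 0.7% — the
scoring overestimates structure, so specificity against shuffled controls
is weaker than a thermodynamic backend would give. A green recall test
therefore establishes sensitivity on planted precursors, not
zero-false-positive specificity.

## Target prediction

Complementarity scoring uses a penalty ("expectation") scheme: per duplex
position 0 for a Watson–Crick pair, 0.5 for G:U, 1 for a mismatch, 2 for
an indel, doubled at miRNA positions 2–13 (the seed-proximal core), with
at most one indel per site. This exact weight set is this package's
definition (the upstream web tool does not publish its internals) and
every weight is configurable. Scanning evaluates every transcript
position with a penalty-minimizing dynamic program (C++), keeps sites at
or below `max_expectation` (default 3), and merges overlapping windows to
the best-scoring site, ties leftmost. A mismatch or indel on miRNA
positions 9–11 calls translational inhibition; G:U wobbles still pair and
do not trigger the call; everything else is cleavage.

Site accessibility (UPE) folds the site plus 17 nt upstream and 13 nt
downstream, once freely and once with the site forced unpaired; UPE is
the score difference (≥ 0). Because fallback units are not kcal/mol, the
conventional cutoff of 25 only flags hits (`upe_flag`), it never drops
them.

## The simulator: what it emulates and what it does not

`sim_config()` states the world: four stage libraries, eight archetype
trajectories (multiplicative factors over stages, baseline 1), conserved
families whose members sit within 1 substitution of a family seed
(pairwise ≤ 2) and whose seeds are ≥ 5 apart, decoy fragments drawn from
planted rRNA/tRNA/snRNA/snoRNA references, unannotated decoys screened
against the catalogs, hairpin precursors spliced into transcripts, and
reverse-complement target sites with designed mismatches. Per-species
base abundances are log-uniform over three decades; counts are a single
multinomial draw per library (no replicates, matching the design), with a
Dirichlet overdispersion switch for power studies. Planted precursors are
validated at build time through the hairpin module's own window ladder
and re-drawn until they pass, so the planted truth is discoverable by
construction.

Library depth defaults to $10^6$ reads per stage. Real libraries of this
kind run 13–15 million reads; $10^6$ is the depth at which the stated
calibration properties (empirical log2 fold-change within ±0.2 of truth,
TPM convergence) are checked, and it keeps desk-scale runs fast. At depth
$10^6$ a species at TPM 100 carries binomial noise of 10% CV, so
convergence is asserted as a 5-σ sampling-noise bound that tightens to 5%
relative error as abundance grows, plus a 5% median bound — a per-species
5% maximum at TPM 100 would be statistically impossible at any seed.

The simulator does not model sequencing error beyond optional 1-nt length
jitter, quality-score realism, replicate variability, or genomic (as
opposed to transcript-based) precursor context. Green tests on simulated
data therefore establish correctness of the computations and
recoverability of planted signal, not robustness to error modes the
generator does not produce.

## Determinism

Every stochastic step derives its seed from the configured master seed;
identical inputs and seed reproduce byte-identical collapsed tables,
classifications and manifests. Folding and clustering tracebacks are
deterministic; classification ties break by mismatch count then reference
name; scan ties break leftmost.
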