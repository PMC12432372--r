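---
title: "Methods: signatures, kataegis, and genetic subtyping in flsubtype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signatures, kataegis, and genetic subtyping in flsubtype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flsubtype)
```

## Scope

flsubtype implements the genomic layer of a follicular-lymphoma (FL)
characterization workflow: per-sample somatic SNVs are summarized into
96-channel substitution catalogs and decomposed into mutational signatures;
clustered mutations (kataegis) are detected per genome and attributed to the
two B-cell kataegis processes (AID and POLH); and gene-level lesions —
mutations, copy-number changes, and structural variants — are encoded into an
integer matrix and clustered into genetic subtypes by NMF consensus
clustering. A synthetic cohort generator reproduces the statistical structure
each stage assumes, so the whole pipeline runs, and is tested, without any
patient data.

## Mutation catalogs

Single-base substitutions are classified pyrimidine-centered into 96
channels: six substitution types (C>A, C>G, C>T, T>A, T>C, T>G) crossed with
the four 5' and four 3' flanking bases, ordered lexicographically
(`sbs96_channels()`). Records whose reference base is a purine are folded to
the reverse-complement channel, so `G>A` in reference context `TGT` counts as
`A[C>T]A`. Contexts come either from a `context` column or from an indexed
genome; a context whose middle base disagrees with the record's REF is an
error (it indicates corrupted input, not strand ambiguity), while records
containing N are skipped and counted. Row sums always equal the number of
usable SNVs per sample.

## Signature extraction and refitting

De-novo extraction (`extract_signatures()`) factorizes the transposed
catalog $V \approx WH$ with multiplicative updates minimizing the
generalized Kullback–Leibler divergence, the convention of the mutational
signature literature; a Frobenius option exists. For each candidate rank
$k$, `n_restarts` seeded random starts are run; the restart components are
matched to the best-error restart by cosine similarity and the mean
silhouette width of those matched groups (cosine distance) measures
stability. The selected $k$ is the largest with mean silhouette at least
0.8. This selection rule is this package's own documented choice — stability
selection is standard in signature extraction, but the exact published rule
behind the FL analysis is not restated anywhere we could implement from —
and `k` can always be fixed explicitly, which is what the recovery tests do.

One numerical detail matters for reproducibility: only $W$ is drawn
randomly; $H$ is initialized deterministically as $W^\top V$ (rescaled).
Because the updates for $H$ are then column-separable and the $W$ updates
depend on samples only through permutation-invariant sums, the whole
factorization is *exactly* equivariant under sample reordering — permuting
the catalog's rows permutes exposures and changes nothing else, which the
tests assert to machine precision.

Refitting against fixed profiles (`refit_exposures()`) is per-sample
non-negative least squares via an in-package Lawson–Hanson active-set
solver; exposures are in mutation counts because profiles sum to one, and
the per-sample residual norm is attached. On orthogonal designs the NNLS
solution has a closed form, which the tests use as one oracle; a
grid-refinement search and an independent solver are the others.

## Kataegis detection

For each tumor the *abnormal distance line* (ADL) is one tenth of the mean
adjacent intermutation distance, with distances computed within chromosomes
and pooled genome-wide. Every run of 10 consecutive same-chromosome
mutations spanning at most 10 kb forms a window; its nine internal distances
are split at the ADL and compared with the sample-wide below/above counts by
a one-tailed Fisher's exact test (hypergeometric upper tail), and windows
with $p < 10^{-4}$ become candidates. Overlapping candidates are pooled
transitively and the pooled region's $p$ recomputed on its full distance
set; a pool that fails the threshold is split back greedily into maximal
passing prefixes.

Conventions the definition leaves open, fixed here and tested:

* a distance exactly equal to the ADL counts as *above* (conservative toward
  fewer calls);
* "every set of 10 adjacent mutations" is read as all stride-1 windows, not
  disjoint blocks;
* the window span is first-to-last member position, inclusive — a 10-mutation
  run spanning 10,001 bp forms no window;
* a window contributes 9 internal adjacent distances to its 2×2 table, and
  the comparison background is the sample's overall distance distribution
  *including* the window's own distances (an `exclude` option exists);
* the pooled ADL is genome-wide, not per-chromosome averaged.

The detector is verified against a brute-force implementation (explicit
window enumeration, tail probabilities by hypergeometric summation,
independent merging code) for exact agreement of coordinates, member counts
and p-values, calibrated under a uniform null (calls per sample bounded by
windows × threshold), and required to recover planted 10-mutation runs with
spacing at ADL/10 essentially always.

## K1/K2 decomposition and the K1-high/low split

Each event's member mutations form a 96-channel catalog refit by NNLS
against fixed K1/K2 profiles; the K1 contribution is $K1/(K1+K2)$, with
events above 0.5 labeled K1-dominant. The published K1/K2 kataegis profiles
(AID- and POLH-attributed) are not available as printable vectors, so the
package bundles synthetic stand-ins constructed from the motif biology:
`K1.like` concentrates C>G/C>T in the 16 channels with a 5' A/T (the AID
WRCY preference); `K2.like` is T-centered with emphasis on 5' A (POLH's WA
motif). They are labeled synthetic throughout; their essential property —
disjoint, hence orthogonal, support — makes decomposition accuracy exactly
quantifiable (a pure-K1 event must score 1.0; an equal mixture 0.5 in
expectation with binomial noise). Users with real reference profiles supply
them as a `signature_set`.

Per sample, the K1 contribution is the unweighted mean over its events
("per kataegis", not per mutation — a deliberate reading, configurable by
weighting upstream); samples strictly above the cohort median are K1-high,
at-or-below K1-low, so a single-sample cohort is K1-low and even cohorts
split in half. Events are classed as Ig (V, S, or J&C, by interval overlap,
largest overlap winning) or, failing that, by the distance from the event
midpoint to the nearest TSS anchor with a boundary-inclusive 2 kb cutoff;
distance is plain position arithmetic, not the gap convention of
`GenomicRanges::distance()`, which differs by one.

## Lesion encoding and consensus subtyping

Lesion calls are encoded per (sample, marker) into 0–3: nonsilent mutations
and indels 2, synonymous 1, none 0; high-grade CNV gain 2 and low-grade gain
1 at gain peaks; high-grade loss 2 and low-grade loss 1 at loss peaks; SV
presence 3. The printed tier boundaries overlap at 3.7 (gain) and 0.80
(loss) copies; this package resolves the ties as: gain scores 2 strictly
above 3.7 and 1 on [2.4, 3.7]; loss scores 2 at or below 0.80 and 1 on
(0.80, 1.6]. Copy numbers in the neutral gap (1.6, 2.4) score 0 — they are
legitimate observations, not errors — and a loss observed at a gain peak (or
vice versa) scores 0 because peaks are directional. Scores are used raw (not
column-scaled) for clustering, matching the integer design of the encoding;
a user can rescale upstream if desired.

Consensus clustering runs Frobenius-objective NMF (the classic consensus
setup) `n_runs` times per candidate K from seeded random starts, assigns
samples to their maximum-loading factor, and averages co-assignment
indicators into a consensus matrix. The cophenetic coefficient — the
correlation between `1 - consensus` and the cophenetic distances of its
average-linkage dendrogram — selects K over 2..10, ties resolved toward the
smaller K (parsimony). Final labels cut that dendrogram at the selected K,
which also gives all-zero samples (retained, flagged) a deterministic
assignment. Cluster markers are then tested per (marker, cluster) by
two-sided Fisher's exact tests on lesioned (score > 0, so synonymous counts)
versus not, in-cluster versus rest; assignment additionally requires an
in-cluster odds ratio above 1, and a one-sided option exists since the
original description does not specify sidedness. New samples are classified
by nearest centroid under cosine distance; an all-zero profile has no
direction and receives the smallest-norm centroid's label with a
low-confidence flag.

## The synthetic cohort

The generator emulates exactly the features the statistics rely on:

* background SNV positions uniform per chromosome (counts
  Poisson-distributed around the per-genome rate, on the order of the
  2,000–12,000 SNVs expected from FL genomes at 2.8–6 mutations/Mb),
  giving approximately exponential intermutation distances — the detector's
  null;
* channels drawn from per-sample signature mixtures, with positions sampled
  among genome sites carrying the channel's trinucleotide context, and
  substitutions stored on the reference strand (VCF semantics) so catalog
  folding is actually exercised;
* planted kataegis runs of specified size and span, labeled with their
  generating signature for recovery scoring;
* a 3-cluster lesion cohort (default 127 markers × 120 samples, enrichment
  0.9 within cluster versus 0.05 outside, marker kinds cycling through the
  four scored lesion classes) with copy numbers sampled across every
  encoding tier, including occasional neutral values that must score 0.

It deliberately does *not* simulate sequencing reads, alignment or calling
artifacts, indels, tumor purity, germline contamination, or chromatin-scale
covariates of mutation rate. Passing tests therefore demonstrate the
correctness and calibration of the statistical machinery under its stated
model, not robustness to upstream calling error; with real cohorts the
inputs to these functions are whatever the variant-calling pipeline
produced.

## Numerical and calibration choices

* NMF runs are capped at 500 (KL extraction) or 60 (consensus) update
  sweeps with a relative-improvement stop of 1e-6 / 1e-4 checked every 10
  sweeps. Consensus clustering only consumes each run's maximum-loading
  assignments, which stabilize long before the objective does, so the tight
  consensus cap changes no label while keeping 100-run-per-K sweeps cheap.
  Running 100 (not fewer) seeded starts per K matters for model selection:
  with planted 3-cluster structure the K = 2 factorization can merge the
  same pair of clusters in every run of a small batch, producing a perfect
  — and misleading — consensus that ties K = 3; across 100 starts the merge
  choice varies and the tie disappears.
* All randomness descends from one master seed through a deterministic
  integer spawner (kept below 2^31), so full pipeline reruns are
  byte-identical; tests assert this on file checksums.
* The rank-sum test uses exact enumeration when both groups have at most 10
  untied observations and the tie-corrected normal approximation with
  continuity correction otherwise. Its calibration is checked at n = 30 per
  group over 10,000 null replicates against the binomial band around 0.05.
* Fisher's exact test is conditionally conservative on discrete tables: its
  achievable size is strictly below nominal and approaches 0.05 only as the
  margins grow (exact size ≈ 0.040 at 200 per group, ≈ 0.049 at 5,000 per
  group, computed by summing the null table distribution). The calibration
  check therefore uses 5,000-per-group binomial null tables, where
  discreteness is minimal; the residual conservatism is a property of the
  test itself, not of this implementation, and the exact-agreement checks
  against hypergeometric enumeration are the sharper guarantee.
* Test problem sizes are chosen to make each property measurable yet quick:
  oracle equivalence on 50 genomes of ≤ 2,000 SNVs, null calibration on 200
  genomes, recall on 500 planted runs, signature recovery on 30 × 3,000
  catalogs, and subtype recovery across 50 cohort replicates of the
  127 × 120 matrix at 100 NMF runs per K.

## Known limitations

The K-selection rule for extraction is a documented stand-in; with few
samples or near-collinear mixtures it can over-select, which is why recovery
experiments fix k. The K1/K2 fixtures reproduce motif structure, not the
published weight vectors, so absolute K1 contributions on real data depend
on the profiles supplied. Merged-event splitting is greedy left-to-right;
in pathological overlap chains a different split could pass as well — the
brute-force oracle implements the same rule, so equivalence testing does not
adjudicate that choice. The consensus step's NMF uses multiplicative
updates, which converge to stationary points only; stability across 100
seeded runs, not per-run global optimality, is the operative guarantee.
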