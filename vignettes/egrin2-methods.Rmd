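---
title: "Ensemble post-processing: models, statistics and design choices"
author: "egrin2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble post-processing: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Microbes retune most of their transcriptome with a small number of
transcription factors by reusing cis-regulatory sites combinatorially and
conditionally. A single biclustering run over a transcriptome compendium
captures one plausible condition-dependent modularisation; it is noisy and
incomplete. `egrin2` takes an *ensemble* of such runs — each trained on a
subsample of conditions, each emitting biclusters with de novo motifs — and
mines the pooled output for what recurs:

* **GREs** (gene regulatory elements): clusters of at least 10 mutually
  similar PSSMs across runs, summarised by a combined matrix and mapped
  genome-wide.
* **Corems** (conditionally co-regulated modules): link communities on the
  backbone of the gene–gene co-occurrence network; because communities are
  sets of *links*, genes naturally belong to several corems — unlike
  regulons or single-run clusters.
* Per-corem **condition activity** (when is the corem co-regulated?), the
  GREs implicated in that co-regulation, and a GRE-based gene regulatory
  network evaluated against binding-site and fitness gold standards.

# Models and statistics

## Motif similarity and the empirical null

Motifs are probability matrices over (A, C, G, T). The distance between two
motifs is the minimum, over all relative offsets in both orientations with
at least `min_overlap = 6` aligned positions, of the mean per-position
Euclidean distance between aligned probability rows. It is a symmetric
premetric (zero for identical and palindromic reverse-complement pairs).

Pair significance is empirical: the null is built from `n_null` (default
1000) pairs of column-shuffled motifs drawn from the observed collection,
and a pair's p-value is the fraction of null distances strictly below the
observed distance, with Benjamini–Hochberg correction across all pairs and
edges kept at FDR 0.01. Two refinements matter in practice, and both are
deliberate design choices of this package:

1. **Near-duplicate exclusion.** An ensemble contains many near-copies of
   each real motif — that is the signal. Shuffles of duplicate-content
   pairs coincide on short windows far more often than unrelated pairs, so
   pairs with distance below half the median are excluded as null sources.
   The cutoff must stay below the unrelated pairs' bulk; excluding more
   (say, everything below the median) would bias the null toward poorly
   matching base compositions and silently inflate significance.
2. **Alignment-length conditioning.** The distance is a minimum over
   alignments as short as 6 columns, and short windows are much easier to
   match by chance. Each pair is therefore compared against the null's best
   distance over alignments *at least as long as the pair's own best
   alignment* — the same correction motif-comparison tools apply when they
   normalise for alignment length. Without it, 6-column flukes define the
   null's minimum and full-width matches can never reach the FDR threshold.

The p-value deliberately has no "+1" correction: a distance smaller than
every null draw is off the null's scale, and with ~2 × 10^4 pairs under
test, a floor of 1/(n_null+1) would make FDR ≤ 0.01 unreachable even for
exact copies.

## Markov clustering and the combined PSSM

The similarity network (weights `1 − d/d_max`, `d_max` the largest retained
distance) is clustered with the Markov Cluster algorithm: self-loops,
column normalisation, then alternating expansion (matrix squaring) and
inflation (elementwise power, default 2.0 — the algorithm's canonical
regime; the reference framework does not state a value) until the matrix
stabilises (1e-6, 200 iterations). Clusters are the connected components of
the converged matrix's support; every motif lands in exactly one cluster.
Clusters of at least 10 members become GREs. Members are aligned to the
cluster medoid and the combined PSSM is the per-position unweighted mean of
the aligned members, truncated to positions covered by at least half the
members and renormalised (the coverage rule is this package's choice; only
"unweighted mean of aligned matrices" is inherited).

## Genome scanning with exact p-values

A PSSM is scored at every position on both strands as a log2 odds ratio
against a 0-order background, with a pseudocount (default 0.001) mixed into
the motif probabilities. Per-position scores are discretised to 1e-3 log2
units and the exact null score distribution is obtained by
dynamic-programming convolution of the per-position score distributions —
for motif widths where all 4^w words can be enumerated, the DP tail equals
brute-force enumeration to floating-point precision. Benjamini–Hochberg
runs per PSSM across all scanned positions (both strands, all replicons),
and hits are reported at q ≤ 0.01. Reverse-strand matches are recorded at
forward-strand coordinates with the strand noted, so overlap tests work in
one coordinate system. For a GRE, member hits are pooled and promoter
profiles count significant member matches per start-codon-relative position
("summing", not deduplicating, by default).

## Coordinates and promoter windows

Internally all coordinates are 0-based, half-open, forward-strand; GFF3 I/O
converts from 1-based inclusive; BED passes through. The promoter window
spans 875 nt upstream to 125 nt downstream of the start codon *along the
gene's strand*, reported as forward-strand intervals; circular replicons
wrap (the window may split in two), linear replicons clip. Both organisms
this framework was built around have circular chromosomes, so `circular`
is the default topology and plasmid topology is a per-replicon input.

## Co-occurrence, backbone, link communities

The ensemble becomes a weighted gene–gene network: the weight of an edge is
the number of biclusters containing both genes. The multiscale backbone
keeps an edge iff, at either endpoint with degree `k ≥ 2` and normalised
weight `p = w/s`, the disparity p-value `α = (1 − p)^(k−1)` falls below
0.05 (the OR rule is the cited filter's convention; degree-1 endpoints are
uninformative and contribute α = 1). The closed form equals the integral
of the filter's density `(k−1)(1−x)^(k−2)` — asserted to 1e-9 in the test
suite.

Corems are link communities: links sharing a node are compared by the
Jaccard index of the inclusive neighbourhoods of their non-shared ends
(unweighted, the cited algorithm's basic form), clustered by single
linkage, and the dendrogram is cut where the partition density

D = (2/M) Σ_c m_c (m_c − n_c + 1) / ((n_c − 2)(n_c − 1))

is maximal (ties resolved toward the coarser cut; D_c is 0 for communities
of up to 2 nodes, 1 for cliques, 0 for trees). A community's induced gene
set with at least 3 genes is a corem — 3 because the density is only
meaningful from 3 nodes up; no threshold is inherited. Single-linkage cut
at height h is exactly the connected components of the link graph
thresholded at similarity 1 − h, which is how the test oracle recomputes
the optimum independently.

## Condition activity: RSD permutation test

A corem is co-regulated in a condition when the relative standard deviation
RSD = |σ/μ| of its genes' expression (σ the sample standard deviation) is
significantly low: per condition, the null is the RSD of 1000 random gene
sets of the same size drawn from all matrix genes, and
p = (1 + #{null ≤ observed})/(1 + 1000). Conditions with |μ| < 1e-12 or
fewer than two values are undefined and never co-regulated — on log-ratio
data a near-zero mean is common and carries no information. The
co-regulated set uses raw p ≤ 0.05 (the inherited rule); BH q-values are
reported alongside and can gate the set via `use_q`.

A per-condition test at the 5% level *must* pass ~5% of genuinely inactive
conditions — that is what the calibration suite verifies. Consequently the
raw co-regulated set of a real corem always carries a sprinkle of isolated
false-positive conditions. `coregulated_blocks()` aggregates maximal runs
of at least 3 consecutive co-regulated conditions, which removes isolated
false positives and recovers planted contiguous blocks exactly on
synthetic data; users who need a set, not a test, should prefer it.

## GRE association, enrichment, operons

A GRE is implicated in a corem iff (1) it has a significant match inside
the promoter window of at least one corem gene, and (2) at least one of its
member PSSMs originates from the top 10% of biclusters ranked by the number
of corem genes they contain (boundary ties included; a supporting bicluster
must share at least one corem gene, otherwise an all-zero ranking would
make the criterion vacuous). Composition weights are supporting-bicluster
counts normalised over associated GREs — a declared stand-in for a
model-based influence score, and labelled as such in outputs.
Condition-group enrichment is a hypergeometric upper tail with BH across
groups. An operon is flagged as predicting condition-specific transcript
isoforms when its genes intersect corems in at least two distinct non-empty
patterns.

## TF matching and evaluation

The genome is partitioned into 50 nt bins; a member PSSM significantly
overlaps a TF's sites when the hypergeometric upper tail of hit-bin /
site-bin overlap is ≤ 0.01; a GRE matches a TF when the binomial upper tail
of its significant-member count (at rate 0.01) survives BH at FDR 0.05
across all (GRE, TF) pairs; only each GRE's most significant TF is kept
(one TF may win several GREs). TFs need at least 3 unique binding sites.
The binned-hypergeometric and binomial constructions are declared
substitutes: the reference framework states only the two thresholds, not
the tests. The GRE-based network draws TF → gene edges through promoter
hits, with confidence `(1 − hit q)(1 − match q)` — only the ranking
matters. Precision–recall restricts predictions to the gold standard's
universe, ranks by confidence with lexicographic tie-breaks, anchors the
trapezoid at (0, precision of the first prediction), and also reports
correct predictions at 10/25/50% precision. Fitness coherence compares
within-corem pairwise Pearson correlations of fitness vectors against all
universe pairs with a one-sided two-sample KS test (A stochastically
greater than B).

# The synthetic fixture

The generator is first-class, tested code; its defaults are the package's
reference study conditions: 200 genes on one circular replicon, forward
strand, promoters of 1000 nt (so one gene's −875/+125 window never covers a
neighbour's planted site), 100 conditions, 5 disjoint planted modules of
10–20 genes, one active block of 15 contiguous conditions per module, motif
width 14 at 2.0 bits/position, 20 runs each sampling half the conditions,
gene dropout 0.1, spurious-gene rate 0.05, expression noise 0.3, motif
emission 1, Dirichlet motif-column noise 0.02 (concentration 50). The
noiseless preset zeroes every noise source; downstream recovery must then
be exact, which is the pipeline's strongest integration test.

Three structural choices deserve explanation:

* **Planted motifs are mutually dissimilar** (pairwise alignment distance
  ≥ 0.45, by rejection sampling). Two planted motifs sharing most of their
  consensus are one regulatory element to any conceivable discovery
  method; recovery metrics are only meaningful when the ground truth is
  identifiable.
* **Decoy motifs are fresh random PSSMs, column-shuffled**, not shuffles of
  the planted matrices: spurious motifs discovered in random gene sets are
  independent of real signal, and deriving decoys from planted motifs
  would correlate the noise with the signal (near-one-hot shuffles
  recreate long exact sub-windows of the source).
* **Module activity is block-structured** (contiguous condition blocks),
  mirroring condition-subset semantics and making the expected RSD
  analytically checkable.

What the fixture does **not** emulate: higher-order sequence composition
(the background is i.i.d. uniform, which keeps the scan p-value oracle
exact), mixed gene strands and nested operator sites, overlapping planted
modules (supported by `module_gene_overlap_fraction` but off by default),
replicate structure or batch effects in expression, and the long-tailed
bicluster-quality distribution of real runs. Passing recovery tests on the
fixture therefore demonstrates the statistics and the plumbing, not
performance on any real compendium.

# Numerical choices

* Scan scores are binned at 1e-3 log2 units; p-values are exact for the
  binned score, and the observed score is binned identically, so DP and
  enumeration agree to machine precision.
* MCL converges at max-change < 1e-6 (200-iteration cap, with a warning and
  the current interpretation on non-convergence); entries below 1e-12 are
  pruned each iteration for stability.
* Permutation p-values carry the +1 correction and are seed-deterministic;
  every stochastic stage derives a stage seed from the single pipeline
  seed, and repeated runs of one configuration are byte-identical (the
  manifest records counts and a parameter hash but no timings).
* RSD denominators below 1e-12 are "undefined", not infinite.
* Ranking tie-breaks (PR curve, best-TF, corem ids) are lexicographic so
  every ordering is total and reproducible.

# Problem sizes used by the test suite

The suite runs the full pipeline twice at the reference conditions
(noiseless and noisy), the disparity oracle on 100 random graphs of up to
50 nodes, the link-community oracle exhaustively on all connected graphs
on up to 5 vertices (with ≤ 8 edges) plus seeded sparse graphs on 6–9
vertices, scan-oracle enumeration at widths 5 and 8 with a 10^4-position
uniformity check, and a 10^4-test calibration of the RSD permutation test.
These sizes were chosen so the whole suite completes in minutes while every
statistical claim is still exercised at meaningful resolution.

# Known limitations

* The combined PSSM of a GRE can be slightly diluted by chance members
  (unrelated motifs sharing an exact alignment window); the medoid
  alignment and coverage rule bound, but do not eliminate, this effect.
* The per-condition co-regulated set inherits the 5% type-I rate of its
  test by construction; use `coregulated_blocks()` for a cleaned set.
* The empirical motif null assumes motif widths in the ensemble are
  broadly comparable; with extremely heterogeneous widths the
  overlap-conditioned classes thin out.
* GRE "influence" on a corem is approximated by supporting-bicluster
  composition; it is reported as a composition, not a causal weight.
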