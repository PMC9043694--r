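---
title: "k-anonymous sequence obfuscation: model, algorithms and design choices"
author: "seqanon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{k-anonymous sequence obfuscation: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqanon)
```

## The privacy model

`seqanon` implements *k*-anonymous release of DNA sequence collections.
A released dataset is *k*-anonymous when every record is
indistinguishable from at least *k* − 1 others, bounding the probability
of re-identifying any donor by 1/*k*. For sequences this is achieved by
**generalization**: sequences are grouped into clusters of at least *k*
members, the members of each cluster are aligned, and every column where
they disagree is replaced by the IUPAC code that covers all observed
symbols. The cluster is then released as this single generalized
sequence. Nothing is suppressed — agreeing positions are published
exactly — so utility loss is confined to the disagreeing columns.

The assumption that makes this work is **high mutual similarity**: the
input is expected to be one locus from one species, where most pairs
differ at a handful of positions. The machinery still functions on
diverse inputs, but the released sequences then degenerate towards long
runs of ambiguity codes and the release loses its value.

## The generalization lattice and the information-loss distance

The 16 extended-alphabet symbols form a four-level lattice ordered by
base-set inclusion: bases A, C, G, T (level 1); the six two-base codes
R, W, M, K, S, Y (level 2); the four three-base codes D, V, H, B and
the alignment gap `-` (level 3); and N (level 4), which covers any base
or a gap. The gap is modelled as a singleton symbol {−} so that
generalizing a base against a gap yields N — the only symbol covering
both — at cost 4. This choice is forced by the arithmetic of the
worked example below.

Obfuscating two aligned symbols replaces them by their **lowest common
ancestor** `g(a, b)`, the unique lowest-level symbol whose base set
contains both base sets. The per-column information loss is

$$\mathrm{dist}(a, b) = 2\,\mathrm{lev}(g(a,b)) - \mathrm{lev}(a) - \mathrm{lev}(b),$$

and the distance between two aligned sequences is the column sum. The
distance is symmetric, zero exactly on equal symbols, and satisfies the
decomposition identity
`dist(a, b) = dist(a, g) + dist(b, g)` with `g = g(a, b)`; the test
suite asserts all of these exhaustively over the 256 symbol pairs
against a brute-force minimal-superset search.

```{r lattice}
ob <- obfuscatePair("CCTGTAAA", "CA-GTRAA")
ob$generalized
ob$cost
ob$events
```

The generalization table is precomputed once from the base-set
definition (with uniqueness of the minimum asserted during
construction), so lookups are O(1).

## Alignment

Clustering needs pairwise alignments, and the alignment objective
matters: the information loss of a released pair is decided by how the
pair is aligned. `alignPair()` therefore runs an exact global dynamic
program whose costs *are* the lattice distances — a substitution column
costs `dist` of its symbols and a residue against an inserted gap costs
`dist(residue, "-")`. The aligner consequently minimizes exactly the
loss that obfuscation will incur, and no separate match/mismatch/gap
parameters exist to tune. Heuristic seed-and-extend search tools can
replace the built-in ranking through `adapterConfig()` /
`externalSearch()` for users who have one installed; the built-in exact
aligner is the default because it makes every downstream number
deterministic and testable against enumeration oracles.

Numerical choices, all fixed for bit-reproducibility:

* Tie-breaking in the traceback prefers diagonal, then a gap in the
  second sequence, then a gap in the first.
* Homolog ranking breaks equal costs by input order.
* Event columns are reported 1-based, following R convention.
* An optional band (half-width `band` plus the length difference)
  restricts the matrix for long, highly similar pairs; the default is
  the full matrix, which is always exact. A too-narrow band fails
  loudly rather than returning a suboptimal path silently.
* Lowercase input is upcased; U is rejected outright (DNA-only tool) —
  silently mapping U to T would hide upstream data problems.

## Clustering

`iterMegablast()` reconstructs the iterative scheme: while at least 2*k*
sequences remain, draw a query uniformly at random (seeded), rank the
rest by alignment cost, cluster the query with its top *k* − 1 homologs,
obfuscate and remove. When between *k* and 2*k* − 1 sequences remain
they form the final cluster: the query and top homolog are obfuscated
first, then each further member is aligned against the *current
generalized sequence* and obfuscated onto it. This chained fold works
unchanged because both the aligner and the distance are defined on the
full 16-symbol alphabet — ambiguity codes are first-class inputs, which
real control-region data (rich in Ns) requires anyway.

When a later alignment inserts new gap columns into the generalized
sequence, the same columns are inserted into the stored aligned forms of
earlier members (and recorded event positions are re-mapped), so all
members share the final coordinate system; per-member distances are then
measured against the final generalized sequence in those coordinates.
This projection is the minimal consistent choice for a shared coordinate
system. For the leftover cluster the query is drawn with the same seeded
generator as everywhere else.

The seed is a required, logged parameter: the method is stochastic only
through query order, and averaging over repeated seeded runs is the
intended way to report its performance (the evaluation harness does this
by default with 10 repeats).

`degreeOfAnonymity()` reports the smallest released cluster and the
implied re-identification bound. Note that for *N* = 3 the single triple
gives a bound of 1/3 — stronger than 1/2 — while any dataset containing
a pair reports 1/2 at *k* = 2.

## Baselines

`mwmCluster()` computes an exact minimum-weight perfect matching on the
full pairwise distance matrix. No installed R package provides exact
weighted matching on general graphs, so the package carries a dense
O(n³) blossom implementation (maximum-weight matching with dual labels;
minimization by weight reversal on the complete graph, with weights
doubled internally so dual updates stay integral). It is validated in
the test suite against exhaustive enumeration over all perfect
matchings. An approximate matcher would contaminate every comparison in
which matching is the reference optimum, which is why exactness is
non-negotiable here.

For odd *N* a dummy node with zero-cost edges picks the leftover
optimally; the leftover then joins the matched pair whose closer member
is nearest (ties: earlier pair). This attachment rule is this package's
choice, documented rather than attributed. `greedyCluster()` extracts
the globally closest remaining pair with ties broken by smaller row,
then column index. `randomCluster()` is the seeded no-information
baseline. For *k* = 2 the matching total is optimal by construction, so
on every instance mwm ≤ greedy in total loss — a dominance the tests
assert alongside enumeration-verified optimality. The pairing baselines
are defined for *k* = 2 only; `iterMegablast()` supports general *k*,
absorbing up to 2*k* − 1 leftovers into its final cluster.

## The synthetic data generator

`simulateDataset()` emulates the regime the method targets without any
external data: one reference sequence is drawn from a configurable base
composition, and every dataset sequence derives *independently* from it
(star topology) by per-site substitutions, short indels (geometric
lengths, mean 2 — the indel structure is this package's choice) and
N-masking. The star model is the simplest one with a closed-form
expected pairwise mismatch probability,
$p = 2s(1-s) + \tfrac{2}{3}s^2$ for substitution rate *s*, which the
tests verify within three standard errors on 50 independent pairs.

Two presets encode benchmark-like regimes:

* `dataset1-like`: 56 sequences of 6580 nt, G-enriched composition,
  substitution rate 0.002/site, indel 5e-4, ambiguity 2e-4 — a small
  set of long, conserved promoter-locus sequences.
* `dataset2-like`: 372 sequences of 500 nt, C-enriched composition,
  substitution rate 0.01/site (hypervariable control-region-level
  diversity, ~2% pairwise), indel 1e-3, and a tenfold higher ambiguity
  rate 2e-3, reflecting that short mitochondrial reads carry many more
  Ns.

The rates are fixed properties of the presets, chosen once on the
biological grounds above; they are not tuning knobs. What the star
topology deliberately does **not** model is phylogenetic structure:
real loci contain clades of near-identical haplotypes, which make the
choice of clustering method matter more than it does here, where
pairwise distances are approximately the sum of two independent
per-sequence mutation loads. Passing the comparative tests on synthetic
data therefore demonstrates correctness and the expected ordering of
methods, not the magnitude of separation achievable on real data.

## Evaluation

`evaluateMethods()` reports the average distance between sequences and
their obfuscated releases under **both** normalizations — per sequence
(sum of per-member distances over *N*) and per cluster (sum of cluster
totals over the cluster count) — because either convention is defensible
and published tables do not always say which is used. Deterministic
methods are run once with zero reported spread; stochastic methods run
`repeats` times with derived seeds. `sweepN()` evaluates across dataset
sizes (deterministic prefix by default, seeded random subsets on
request) to reproduce the shape of distance-versus-*N* comparisons.

Problem sizes used by the heavier checks are deliberate choices:
the comparative test runs the `dataset2-like` regime at 60 sequences
with 10 repeats, where the expected ordering (iterative clustering below
random pairing, within 15% of the matching optimum) is already stable;
alignment oracles use 500 random pairs up to length 12, with plain
exponential enumeration anchoring an independent dynamic program on
pairs up to length 6, because full enumeration at length 12 (hundreds of
millions of alignments per pair) adds no assurance over the layered
oracle.

## Known limitations

* Quadratic alignment: full-matrix alignment of two 6.6 kb sequences
  allocates a ~170 MB score matrix; use the band for long inputs.
* The blossom matcher is dense O(n³): fine for hundreds of sequences,
  not for tens of thousands.
* Suppression-based anonymization, differential privacy and
  cryptographic schemes are out of scope, as are local alignment and
  multiple sequence alignment.
* `k`-anonymity protects membership within a cluster; it does not
  defend against attackers holding partial sequence information that
  intersects the released ambiguity codes.
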