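---
title: "Weighted statistical binning: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted statistical binning: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statbin)
```

## The problem

Summary methods for species-tree estimation (MP-EST, ASTRAL, R*) take a
collection of per-locus gene trees and combine them, exploiting the fact
that under the multispecies coalescent (MSC) the most probable gene tree
topology agrees with the species tree for many quantities of interest
(e.g. rooted triplets). Their Achilles heel is gene-tree estimation
error: individual loci are short, and poorly estimated gene trees
degrade the summary. *Statistical binning* addresses this by grouping
loci whose estimated gene trees show no strongly supported conflict,
concatenating each group into a "supergene" alignment, re-estimating a
tree per supergene, and summarizing the supergene trees instead.

The *weighted* variant repeats each supergene tree as many times as its
bin has genes. This is not cosmetic: if bins are unequal in size, the
unweighted supergene-tree distribution is a flattened version of the
gene-tree distribution, and in the limit of many loci and long sequences
it converges to one copy of every possible gene tree — a flat
distribution from which no summary method can recover the species tree.
Weighting restores the gene-tree frequencies, which is exactly what a
summary method needs, and makes the binned pipeline statistically
consistent under the GTR+MSC model.

## The binning algorithm

Two gene trees with bootstrap supports are *combinable at threshold B*
if, after collapsing every branch with support `< B`, they share a
common refinement. We test this pairwise over splits: splits `A|A'` and
`B|B'` on one leaf set are compatible iff one of the four intersections
is empty, and pairwise compatibility of split sets on a common leaf set
implies joint realizability in a single tree. The *incompatibility
graph* has one vertex per gene and an edge wherever two trees are not
combinable.

Binning is a balanced greedy coloring of this graph, in two stages:

1. a greedy clique (repeatedly add the highest-degree vertex adjacent
   to all current members; ties to the lowest input index) seeds one
   bin per clique member;
2. remaining genes are processed in a dynamic order — always the gene
   in conflict with the most existing bins, ties to the lowest input
   index — and each is placed in the *smallest* bin it has no conflict
   with. Only the bin-size tie is random (a caller-supplied seed,
   default 42, drives it); every other tie-break is deterministic, so
   runs are reproducible.

Threshold semantics, fixed package-wide: a conflict requires support
`>= B` on the conflicting branch in *both* trees; equivalently,
collapsing removes branches with support strictly below `B`. The source
material alternates between "at least" and "above"; we adopt `>=` and
apply it consistently.

When every input tree is fully resolved with all supports `>= B`, the
bins are provably exactly the classes of identical topologies; the test
suite checks this mechanism by fuzzing (100 seeded cases in the
acceptance suite). Under the same condition the weighted output is the
input topology multiset, and deduplicating to one tree per topology
(the unweighted limit) demonstrably destroys resolution on a skewed
4-taxon example.

## Supergenes and fully partitioned likelihood

Each bin's alignments are concatenated (taxa missing from a locus are
gap-filled across its column range) and a partition map is kept,
emitted in the RAxML dialect `DNA, g1 = 1-100`. A *fully partitioned*
maximum-likelihood analysis optimizes an independent set of branch
lengths (and in general substitution parameters) per partition on a
shared topology; its score is the sum of per-partition optimized
log-likelihoods. The key consequence (and the reason partitioned
analysis matters for correctness): if one topology is optimal for every
partition separately, it is optimal for the concatenation, and constant
partitions cannot change the optimum — whereas an *unpartitioned*
analysis shares one branch-length set, so constant sites drag the
estimated lengths down.

The in-house solver is deliberately minimal: Jukes–Cantor only,
exhaustive enumeration of unrooted topologies (hard cap at 8 taxa), and
per-branch Brent optimization. For JC the site likelihood is linear in
`exp(-4d/3)` of any single branch, so each one-dimensional problem
needs two prunings and a scalar search; coordinate sweeps stop when two
consecutive sweeps gain less than `1e-6` log-likelihood units. Branch
lengths live in `[1e-8, 10]`, initialized at 0.1. All-gap columns
contribute likelihood 1. This is sufficient to verify every
likelihood-level claim exactly at desk scale; GTR+Gamma estimation at
realistic scale is delegated to the external RAxML adapter, which the
test suite exercises only in dry-run mode.

## Simulation: what the generator emulates

`simulate_gene_trees()` implements the standard MSC: within a
species-tree branch of duration `T` coalescent units, `k` lineages
coalesce after `Exp(k(k-1)/2)` waiting times; survivors pass upward,
and coalescence completes above the root. Branch lengths are classical
coalescent units (2N generations). Sequence evolution is GTR+Gamma
(discrete, 4 mean-one categories when a shape is set; JC defaults) with
a normalized generator and a `rate_scale` converting coalescent to
substitution units.

The 15-taxon fixture is a rooted ultrametric caterpillar whose 12
unrooted internal branches are all equal and short, a high-ILS regime.
One unit subtlety deserves record: the published protocol sets internal
branches to 0.005 substitutions per site with `theta = 4*N*mu = 0.05`
and quotes "0.1 coalescence units". That 0.1 is `tau/theta` — time in
4N-generation units. In the classical 2N-generation units our simulator
(and its closed-form test oracles) use, the branches are
`2 * 0.005 / 0.05 = 0.2` units. `fifteen_taxon_model()` applies this
conversion; with it, the mean gene-tree/species-tree discordance over
10,000 simulated loci is ~82%, reproducing the published figure, while
a literal 0.1-classical-unit reading gives ~91.6%. The generic
`make_caterpillar_species_tree(n, internal_len)` takes its argument at
face value (classical units).

What the generator does *not* emulate: rate variation across lineages
or loci beyond i.i.d. Gamma sites, indels (alignments are always
correct), and the biologically derived model trees of large simulated
collections. A green end-to-end test therefore establishes correctness
of the machinery under the stated model, not robustness to alignment
error or molecular-clock violations.

## Estimation and summaries

Gene trees are estimated in-house by neighbor joining on Jukes–Cantor
distances (saturated pairs capped at `d = 5`; pairs with no comparable
columns are an error), with nonparametric site bootstrapping. Each
bootstrap replicate draws its column indices from a stream seeded by
(master seed, replicate index), so enlarging `b` never perturbs earlier
replicates. NJ on JC distances is statistically consistent on
JC-generated data, which is all the property suite requires; it stands
in for the published RAxML estimation.

Species-tree summaries:

- **Greedy consensus** — bipartitions sorted by frequency (ties broken
  by canonical split order — the reference tooling leaves this
  unspecified, so we fix a deterministic order), added when compatible
  with everything already kept; supports are 100 x frequency.
- **R\*** — per taxon triplet, the strict-plurality rooted topology
  (ties omit the triplet), assembled by Aho's BUILD; components that
  will not separate yield a polytomy rather than an error. R* is a
  consistent summary method under the MSC, which is the only property
  the theory needs from the summary step; it replaces the external
  MP-EST/ASTRAL binaries inside the test surface.
- **MLBS** — replicate `R_i` holds the i-th bootstrap tree of every
  gene (or supergene, replicated by bin size in the weighted pipeline);
  each `R_i` is summarized, and the greedy consensus of the `b` species
  trees carries occurrence-frequency supports.

Rooted-triplet summaries need rooted trees; NJ trees are unrooted, so
the pipeline roots them at a designated outgroup (for caterpillar
fixtures, the deepest leaf). Rooting discards supports, since node
labels do not survive rerooting unambiguously.

## Evaluation statistics

Missing-branch (FN) rate, branch-length ratios over shared true
branches (a shared branch with zero true length is an error, not an
Inf), per-triplet Jensen–Shannon divergence with its ECDF, and the
support-ordered edge-quality curve (true positives by descending
support, then false positives by ascending support, flagging false
positives above 75%). The JS logarithm base is not stated in the source
material; we default to the natural log (bound `log 2`) and expose the
base as an argument, noting the ECDF shape is invariant up to scale.

## Numerical and design choices, in one place

- Support scale 0–100; missing support is `NA`, never 0, and collapsing
  a tree with missing supports is an error the caller must resolve.
- Splits are 31-bit masks over sorted leaf labels (max 30 taxa), with
  the canonical side excluding the lexicographically smallest taxon.
- The MSC/triplet closed forms (`1 - (2/3) e^{-T}` etc.) are used as
  test oracles at `p = 30000` with ~4-sigma binomial tolerances.
- Desk-scale substitutes, stated explicitly: NJ+JC for RAxML, R* for
  MP-EST/ASTRAL, `b = 20` MLBS replicates for the published 200 in the
  end-to-end test (the shapes of all replicate sets are still asserted
  exactly).
- The end-to-end consistency surrogate uses a 6-taxon caterpillar with
  internal branches of 0.5 coalescent units and 0.2 substitutions per
  coalescent unit: enough ILS that gene trees disagree, little enough
  that `k = 5000` sites saturate bootstrap support, which is what the
  theory predicts and the test asserts.

## Limitations

The exhaustive ML solver refuses more than 8 taxa by design; the
compatibility test is quadratic in genes and fine to a few hundred loci
at 30 taxa or fewer; the BUILD fallback returns polytomies where the
triplet constraints are jointly unsatisfiable rather than searching for
a maximum-consistent subset; and no significance machinery (ANOVA/FDR)
is provided — those analyses are outside this package's scope.
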