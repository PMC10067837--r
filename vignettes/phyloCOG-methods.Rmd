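---
title: "Orthologous clusters, marker supermatrices and gene gain/loss reconstruction with phyloCOG"
author: "phyloCOG authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phyloCOG methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloCOG)
```

# Overview

phyloCOG implements a comparative-genomics pipeline for prokaryotic genome
sets: building clusters of orthologous genes (COGs) from whole-proteome
protein sequences, refining them with paralogy-aware gene-tree
decomposition, assembling a concatenated marker supermatrix for
species-tree inference, reconstructing gene gain/loss histories on a
rooted species tree from phyletic patterns, and extracting clade-specific
gene signatures.  Because the headline statistics of any such analysis
depend on the input genome collection and on external tool versions, the
package ships a synthetic genome-set generator with recorded ground truth
so that every stage can be validated at desk scale; the test suite and the
acceptance script exercise the pipeline exclusively on such simulated
data.

# The synthetic genome-set generator

The generator defines the study conditions under which the package is
validated.

**Species tree.**  A Yule process: starting from a single split, a
uniformly chosen extant lineage splits until the requested number of
leaves is reached; every branch length is an independent exponential draw
with mean 0.1.  This gives 20-leaf trees a total length near 3.8, so a
rate of 1 per unit branch length corresponds to roughly four expected
events per family across the tree — a convenient scale for validating
rate inference.  The real shape of any particular published phylogeny is
irrelevant to the correctness properties being tested.

**Gene content.**  Each family is present at the root with probability
`rootPresenceProb` and evolves along every branch under the two-state
Markov chain (gain rate $g$: absent to present; loss rate $l$: present to
absent).  The branch process is simulated as an exact jump process
(exponential waiting times, possibly several flips per branch), so the
endpoint transition probabilities equal the analytical chain
$P(0 \to 1) = \tfrac{g}{g+l}(1 - e^{-(g+l)t})$ exactly, and with $g = 0$
the survival of a present family is $e^{-lt}$.  This choice keeps the
simulator matched to the inference model: maximum-likelihood rate fitting
on simulated matrices is asymptotically unbiased, which the recovery
tests verify directly.  Recorded events are the *net* per-edge state
changes — a double flip within one branch is invisible at both ends and
cannot be detected by any posterior-based method, so it is not scored.

**Duplications.**  A present family acquires Poisson($d \cdot t$) extra
copies on *terminal* branches only.  This keeps the exact accounting
identity "number of duplication events = sum over leaves of (copy count
− 1)" testable, and is sufficient to exercise paralogy-aware subtree
parsing and index-ortholog selection; inherited ancient duplications with
sequence-level divergence between paralog clades are deliberately out of
scope.

**Sequences.**  One random root sequence per family (uniform over the 20
amino acids); a family's reference sequence evolves down every branch by
per-site substitution with probability $1 - e^{-d t}$ to a uniformly
chosen different residue (a Jukes–Cantor-like 20-state model, no rate
heterogeneity, no indels).  A genome's copy is the reference sequence at
that leaf; duplicate copies are identical to it.  The reference sequence
evolves at every node whether or not the family is present there, so a
family regained after loss re-emerges with a sequence that is still
recognisably homologous — mirroring re-acquisition of the same family
rather than the birth of an unrelated one.  Families absent from every
leaf are unobservable, dropped from the matrix, and counted: this is
what motivates the ascertainment correction in the gain/loss module.

What passing tests on these data do *not* show: robustness to indels and
alignment error, to domain shuffling or partial homology, to
rate-heterogeneous or compositionally biased sequences, or to horizontal
transfer between contemporaneous lineages (gains are branch-local state
flips).  The defaults (20 genomes, protein length 120–150, within-family
divergence 0.2–0.3) were chosen so that within-family identity stays
well above the ~5 % random background while keeping the full pipeline
runnable in minutes on one CPU; the problem sizes used by the tests are
20 genomes × 50 families for exact clustering recovery, 5 000 families
for rate/ancestral-content recovery, and 20 genomes × 500 families for
the end-to-end run.

# Clustering and refinement

**Similarity search** (`allVsAllSimilarity`) performs k-mer prefiltered
Smith–Waterman local alignment under BLOSUM62 (gap open 11, extend 1).  A
pair is a hit when fractional identity over aligned columns is at least
0.5 *and* the aligned span covers at least 0.5 of both sequences; both
thresholds are configurable.  The 0.5 "sequence similarity threshold" of
MMseqs2-style clustering is interpreted as minimum fractional identity
with bidirectional coverage — MMseqs2's `--min-seq-id` semantics; a
bit-score-ratio reading exists but identity is the default here.  The
k-mer prefilter (k = 5, one shared k-mer) is safe at the identity levels
the thresholds accept: a pair at ≥ 50 % identity over ≥ 60 columns is
overwhelmingly likely to share an exact 5-mer, while unrelated random
sequences share one with probability well under 1 %.

**Greedy clustering** (`greedyCluster`) is a set-cover surrogate: the
longest unassigned protein becomes a centroid and absorbs its unassigned
hits.  Singletons are excluded from the cluster set (clusters require
members) but retained for ortholog-coverage accounting.

**Cluster alignment** (`alignCluster`) is a center-star progressive
alignment: the center is the member with the maximum summed pairwise
global alignment score, all members are aligned to it, and the pairwise
gap patterns are merged.  De-gapping any row reproduces the member
sequence exactly — an invariant the tests enforce.  An `aligner` hook
accepts any function mapping an `AAStringSet` to an equal-width MSA, so
an external aligner (e.g. MAFFT or MUSCLE) can be substituted without
changing the pipeline; the internal aligner is the default so nothing
outside R is required.

**Profile merging** (`profileSimilarity`, `mergeFullLength`) replaces
HMM–HMM comparison with a frequency-vector profile alignment: columns are
residue-frequency vectors, the column-pair score is
$\sum_{x,y} f_a(x) f_b(y) B62(x,y)$, and the two profiles are aligned
globally with a linear per-column gap penalty of 5.  "Full-length
similarity" is operationalised as mutual span coverage ≥ 0.8 with score
per aligned column ≥ 0.5; connected components of the resulting merge
graph are merged and re-aligned.  No published number exists for the
span threshold; 0.8 is this package's choice and both thresholds are
configurable.

**Gene trees** (`buildGeneTree`) use neighbor joining on the distance
$-\ln(\max(\text{identity}, 0.01))$ over shared non-gap columns, with a
`treeBuilder` hook for external ML tools.  Negative NJ branch lengths
are clamped to zero.  **Midpoint rooting** (`midpointRoot`) places the
root halfway along the longest leaf-to-leaf path; ties between equally
long paths are broken by the lexicographically smallest pair of endpoint
labels, and a tree already rooted at its midpoint is returned unchanged.

**Paralogy-aware decomposition** (`parseSubtrees`) maximises the ratio of
taxonomic coverage to the paralogy index.  For a leaf set $S$ spanning
$G(S)$ distinct genomes this objective is $|G(S)|^2 / |S|$.  The search
is a recursive greedy cut: every edge of the current (sub)tree is scored
by the minimum of the two part ratios; if no cut improves both parts over
the whole, the part is emitted as one cluster, otherwise the best cut is
applied and both parts are parsed recursively.  Ties prefer the larger
clade, then the smallest leaf label.  The published description states
the objective, not the search; on trees of up to eight leaves the greedy
recursion provably matches a brute-force enumeration of all single cuts,
which the acceptance tests check on randomized paralogous gene trees.
Cuts are allowed at terminal edges too (splitting off one leaf), which
the clade-only reading would forbid; with the squared-coverage objective
such cuts only win when a lone sequence genuinely depresses both parts.

**Refinement** (`refineClusters`) iterates align → merge → split until an
iteration performs zero merges and zero splits, or five iterations — a
logged, convergence-capped reading of "several iterations".  The
iteration log (merges and splits per round) is kept in the cluster set's
metadata and written as JSON lines by the pipeline.

**AAI** (`computeAAI`) is the mean percent identity between the two
genomes' index orthologs over aligned non-gap columns, across all shared
clusters.

# Marker selection and the supermatrix

Universal markers are clusters with a full genome complement and a
bounded paralog budget.  "At most 4 additional paralogs" is ambiguous
between a total and a per-genome budget; the total reading
($\sum$ counts − number of genomes ≤ 4) is the default and the per-genome
reading is available via `perGenome = TRUE`.

Within each marker, the **index ortholog** of a genome is the member
maximising the BLOSUM62 score against the alignment consensus (most
frequent non-gap residue per column, alphabetical ties); score ties fall
to the smallest protein id.

**Column filtering** removes columns with gap fraction above 0.667 or
**homogeneity** below 0.05.  Homogeneity here is the consensus-normalised
mean substitution score
$h = \operatorname{mean}_{r \ne -} B62(r, c) / B62(c, c)$ with $c$ the
column consensus; all-gap columns score 0.  This formula is this
package's construction: it maps a column onto a roughly $[-1, 1]$ scale
on which the stated threshold 0.05 is meaningful (a column split evenly
between A and W scores 0.125 and survives; random columns fall below).
Both thresholds and the formula's ingredients are configurable, and
`filterColumns` is idempotent.

Filtered marker alignments are **concatenated** in sorted cluster-id
order, one row per genome, with a partition map in 0-based half-open
coordinates internally and 1-based inclusive RAxML-style partition files
on disk.  Species-tree ML inference itself is out of scope: the
supermatrix is written as FASTA and relaxed PHYLIP for external tools,
and the internal NJ tree builder can supply a tree for testing.

# Gain/loss reconstruction

The model is a two-state continuous-time Markov chain of gene presence
with a single global (gain, loss) pair — a deliberate simplification of
mixture/variable-rate gain-loss models; the posterior-difference event
rule, which is the part carried into downstream statistics, is preserved
exactly.  The root prior defaults to the stationary presence probability
$g/(g+l)$.

* `transitionProbability` is the closed-form 2×2 chain.
* `patternLikelihood` is Felsenstein pruning, vectorised over families;
  the **ascertainment correction** divides by
  $1 - P(\text{absent everywhere})$, because all-absent families cannot
  form clusters.  It is on by default in fitting and can be toggled.
* `fitRates` maximises the summed corrected log-likelihood over
  log-rates in $[-6, 6]$ (L-BFGS-B) from the deterministic start
  $g = l = 1$, after collapsing duplicate patterns with weights.
* `marginalPosteriors` runs the up-down (outside) algorithm; sibling
  messages are recombined by explicit products rather than division, so
  zero partial likelihoods (e.g. loss-free models) cannot produce 0/0.
* `callEvents` emits a gain on an edge when the child-minus-parent
  presence posterior exceeds the threshold, a loss when its negative
  does; "exceeding 0.5 in magnitude" is read strictly (> 0.5, not ≥),
  so a delta of exactly 0.5 is not called.
* `ancestralContentSize` sums posteriors over families at a node — the
  expected gene content of that ancestor — and reports both the raw sum
  and the rounded integer.

Copy counts are binarized at ≥ 1 throughout this module; duplications do
not enter the presence/absence model.  Numerical notes: likelihoods of
20-leaf patterns stay far above double-precision underflow, so no
log-space scaling is applied; the exhaustive-enumeration oracle bounds
the relative error at $10^{-10}$ on all trees with up to six leaves.

# Clade signatures

Pure set queries on the phyletic matrix with presence = count ≥ 1: the
clade core (families present in every clade genome), clade-specific
gains (core families absent from every outgroup genome), clade-absent
common genes (families absent from the clade and present in at least a
fraction of the outgroup — "common" has no published definition, so the
default threshold is 2/3 and configurable), and ortholog coverage (how
many of a genome's proteins, singletons included, sit in clusters that
also contain a reference genome).  Paralog counts never affect signature
membership.

# Pipeline, determinism and I/O

`runPipeline` chains simulate/load → cluster → supermatrix → gain/loss →
signatures, writing standard formats (per-genome FASTA wrapped at 60,
Newick with internal labels, TSV matrices with a `family` first column,
RAxML partition files, JSON-lines iteration logs) plus a JSON run report
with parameter values, stage counts and wall time.  Every TSV carries a
header comment with the tool version, seed and a hash of the scientific
configuration.  All randomness flows from the single seed through
R's RNG with save/restore semantics, so a rerun with an identical
configuration reproduces byte-identical data outputs (the report differs
only in its wall-time field).  The focal clade for signature queries
defaults to the smaller clade under the species-tree root when not
specified.  A thin command-line wrapper with `simulate`, `cluster`,
`supermatrix`, `gainloss`, `signatures` and `run` subcommands is
installed under `inst/scripts/phylocog.R`; the package functions are the
primary interface and the wrapper adds nothing beyond argument parsing.

# Known limitations

Single global gain/loss rates (no per-family or per-branch variation);
no stochastic mapping of event counts per branch; duplications are
terminal-branch only and sequence-identical; the center-star aligner is
exact only up to its star topology and is meant for within-family
identity levels where alignment is easy; the greedy subtree search is
not guaranteed optimal beyond the tree sizes where it is oracle-checked;
and species-tree inference is delegated to external tools by design.
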