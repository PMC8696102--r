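---
title: "Descriptor-based multiple structure alignment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor-based multiple structure alignment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `descalign`, the tunable
parameters and their defaults, the numerical and design decisions that were
genuinely open, and what the shipped synthetic studies do and do not
demonstrate.

## The alignment model

A multiple alignment is a set of columns, each mapping a subset of the
structures to exactly one residue per structure; no residue appears in two
columns. The sole constraint placed on alignments is local: every aligned
residue pair must be supported by a pair of similar local descriptors.
There is no global superposition, no sequence-order constraint across
segments, and no topology constraint, which is what lets hinge motions,
segment swaps and circular permutations align naturally. Geometry enters
instead through scoring (tension and region augmentation, below).

### Descriptors

The descriptor of residue *i* contains every residue *j* in contact with it:
`d_alpha <= 6.5` &#8491;, or `d_C <= 8` &#8491; with
`d_alpha - d_C >= 0.75` &#8491;, where `d_alpha` is the C&alpha;–C&alpha;
distance and `d_C` the distance between the side-chain geometric centers of
the two residues (unweighted mean over side-chain heavy atoms; glycine and
unresolved side chains fall back to C&alpha;, keeping every residue
contact-evaluable). The second clause admits longer-range pairs whose side
chains point toward each other. Around the center and every contact residue
a 5-residue element is built; a contact too close to a chain terminus to
carry a full element is dropped, and a residue whose own central element
does not fit has no descriptor. Elements sharing residues are merged into
segments; elements never span chain breaks. Two adjacent but non-overlapping
windows remain separate segments — merging happens on overlap, not on
sequence adjacency.

### Descriptor-pair similarity

The similarity thresholds between two descriptors are not fixed by the
alignment model itself, so they are explicit parameters:

| parameter | default | meaning |
|---|---|---|
| `min_elements` | 3 | aligned whole elements required (central included) |
| `rmsd_max` | 2.5 &#8491; | C&alpha; RMSD of one rigid fit of the whole correspondence |
| `window_rmsd_max` | 3.5 &#8491; | per-element candidate filter during matching |

The defaults were calibrated once on the synthetic fixtures so that
self-matches and noisy copies (up to &sigma; &asymp; 0.5 &#8491;) are
accepted while an ideal-helix window against an ideal-strand window (5-point
best-fit RMSD &asymp; 3.5 &#8491;) is rejected already at the central
element. Matching is an iterated closest-element procedure: the central
elements anchor a superposition; elements are paired greedily by window RMSD
under the current transform, subject to residue-level injectivity (an
element may thereby align across segment boundaries, so one segment can
align to two smaller ones); the transform is refit on all corresponded
atoms and the matching repeated (two rounds); elements are peeled
worst-first if the global RMSD exceeds `rmsd_max`. Greedy matching does not
guarantee the largest correspondence, but on the fixtures the anchored
two-round scheme is insensitive to the order ties are broken in, and it is
deterministic. A pair's `n_segments` is the number of the first descriptor's
segments represented in the correspondence; since an element window never
spans two segments, "represented" means at least one matched element.

### Cliques and conflicts

Descriptor pairs over one structure pair form a consistency graph (edge =
union of the two correspondences still injective; geometric agreement is
deliberately *not* required at the edge level). The pairwise alignment is a
maximum-weight clique, node weight = correspondence size. Graphs up to
`exact_limit = 25` nodes are solved exactly by depth-first branch-and-bound
with a remaining-weight bound; the first optimum found in increasing vertex
order makes ties resolve to the lexicographically smallest clique. Larger
graphs use replicator dynamics `x <- x * Ax / (x'Ax)` on the Motzkin–Straus
form (adjacency `A`, zero diagonal): strict local maxima of `x'Ax` on the
simplex are uniform distributions on maximal cliques, so each converged
point is turned into a clique by inserting vertices along decreasing
support (plain and weight-biased orders) and completing greedily by weight.
`restarts = 32` randomized initializations (uniform plus Dirichlet noise)
are preceded by deterministic weight-greedy seeds; candidate cliques from
pairwise search are compared by the exact size of their union
correspondence, not the weight proxy. Convergence: change below
`replicator_tol = 1e-8`, an iteration cap of `replicator_iter = 10000`, and
an early stop when the leading support order is stable between 25-iteration
checkpoints (the extracted clique depends only on that order). On graphs
beyond `clique_beam = 600` nodes the search runs on the heaviest nodes only;
the correspondence size is the objective, so light nodes essentially never
enter the maximum.

For two structures pairwise consistency implies global consistency, but
merging alignments of three or more can force two residues of one structure
together transitively (`detect_conflicts` reports such components).
`resolve_conflicts` removes the node subset clearing all conflicts at
minimal lost alignment size — exactly, per connected component, by bitmask
enumeration up to 16 nodes (ties: fewer nodes removed, then the
lexicographically smallest set), with a greedy cover and a warning beyond
that (not reached in any shipped study).

### Profile alignment, trees and the evolutionary loop

Aligning two multiple alignments merges columns: a merge candidate (one
column from each side) must be supported by at least one descriptor pair
linking residues of the two columns, and is scored by
`supporting descriptor pairs x newly co-aligned residue pairs`. Candidates
are pruned to the best 3 per column on either side (a beam; support for a
true merge concentrates, so the beam only sheds register noise), a maximal
consistent merge set is found with the same clique machinery
(`profile_restarts = 1` replicator restarts here — the candidate conflict
structure is a bipartite matching and the deterministic greedy seeds carry
the search; the full restart schedule would be spent on a problem it cannot
improve), and unmerged columns pass through unchanged. Restricting the
output to either input's structures reproduces that input exactly.

Guide trees are drawn by stochastic neighbor joining: the pair of clusters
to join is sampled with probability proportional to the average inter-cluster
similarity (pairwise alignment sizes); an all-zero table degenerates to
uniform sampling. Progressive alignment down a tree gives a specimen; its
fitness is the score of the root alignment.

The steady-state evolutionary loop (defaults: `pop_max = 20`, `p_m = 0.7`,
`stall = 50`, `max_evals = 2000`, `n_trees = 10` initial trees,
`identity_max = 0.8`) applies mutation (recompute one tree node and its
ancestors) or crossover (tree-distance-sampled centroids, subsets grown by
alternating nearest-neighbor assignment — the alternation exhausts the
structure set by construction, so centroid resampling is never needed).
Insertion is elitist with niching: a child enters if the population is below
capacity or if it beats the member most similar to it; on entry, members
more than 80% identical (Jaccard index on induced residue-pair sets) are
removed. A phase ends after `stall` consecutive children that fail to
improve the best-ever fitness — the stall rule stands in for the otherwise
unspecified notion of convergence. The search space starts from the
descriptor pairs the pairwise alignments actually used and is extended one
structure at a time: the freed structure is the one whose summed
pairwise-alignment fitness most exceeds its leave-one-out contribution to
the best multiple alignment (best fitness minus fitness of the alignment
with that structure's residues removed).

### Scoring

For each pair of aligned residues in contact in at least one of the two
structures, the two 5-residue elements' C&alpha; atoms (up to 10 points;
duplicated correspondences from overlapping windows counted once) are
superposed and the RMSD recorded. The averaging order follows the
definition literally: contact values are averaged per residue (per aligned
column, within one structure pair), the per-residue means are squared, the
squares averaged per structure pair, and the per-pair values averaged over
the alignment. Contacts whose residues lack a valid element in either
structure are skipped. Tension is invariant under rigid motion of any
single structure.

A structure pair's aligned residue pairs decompose into regions — connected
components under the contact relation (in either structure). Each region of
at least `min_region = 3` pairs carries its own least-squares rotation;
smaller regions reuse the largest region's rotation and are flagged. The
augmented size is
`|largest| + sum |region| * augment_const * (1 + cos(alpha)) / 2`, with
&alpha; the angle between the region's rotation and the largest region's:
coherently rotated regions count in full, opposed ones not at all. The
proportionality constant of the augmentation factor (`augment_const = 1`)
and the reading of the factor as `(1 + cos(alpha))/2 in [0, 1]` are package
choices: this normalization is the unique affine form that is 1 at
&alpha; = 0 and 0 at &alpha; = &pi;. Ties for the largest region break by
larger residue span, then by position.

Fitness combines size and quality linearly:
`sum over structure pairs of augmented size - lambda_tension * tension * aligned pairs`,
with `lambda_tension = 0.05` &#8491;<sup>-2</sup>. The combination rule is
not dictated by the model; a linear penalty was chosen for monotonicity and
transparency, and the weight calibrated once on the fixtures so that the
ground-truth alignment of a noisy family outscores size-equal random and
register-shifted alignments (the fixture tests pin this). Element RMSDs in
tension are C&alpha;-only, matching the geometry the descriptors are built
from. Per-contact element RMSDs are memoized in the alignment context, so
repeated fitness evaluations inside the evolutionary loop cost little.

### Two-stage protocol

Stage 1 restricts the search space to descriptor pairs spanning at least
`min_segments = 3` segments — multi-segment descriptors characterize packed
cores, so the stage-1 alignment is a core alignment that may miss loops and
linkers. Stage 2 admits the remaining descriptor pairs one at a time
(largest first), each only if it shares at least one aligned residue pair
with the current alignment and merges without conflict; stage-1 content is
never removed. If no descriptor pair anywhere passes the stage-1 filter,
the full pool is used from the start.

## The synthetic generator

`make_chain` builds idealized chains from helix (1.5 &#8491; rise,
100°/residue, 2.3 &#8491; radius), strand (3.4 &#8491; rise, alternating
±0.5 &#8491; offset) and loop blocks, packed on a 9.5 &#8491; square grid so
that consecutive blocks touch — mimicking helix-bundle packing densities.
Pseudo side-chain centers sit 1.5 &#8491; along the local curvature
bisector. `make_family` derives copies by (in order) an optional hinge
rotation beyond a pivot, independent Gaussian noise on every atom, and an
optional circular permutation implemented as renumbering at a cut with the
geometry untouched, together with the full-column ground-truth alignment.

The default two-domain template packs two three-helix domains (helix
lengths 8/8/8 and 10/6/8) around a 4-residue linker. Three helices per
domain give each domain an internal core with 3+-segment descriptors, so a
hinge that breaks the inter-domain interface leaves every structure
anchored in stage 1; the unequal helix lengths make the domains
non-interchangeable, so a circular permutation has a unique correct
alignment — both properties of real multidomain proteins that a more
symmetric toy template lacks (a template with two identical domains makes
the permuted copy's alignment genuinely ambiguous under a domain swap, which
is a property of the toy, not of the method).

What the fixtures do not emulate: real backbone irregularity (ideal helices
are more self-similar than real ones, so register-shifted descriptor pairs
are *more* abundant here than in real data — adversarial in that one
respect), side-chain rotamers and packing chemistry, insertions/deletions
between family members, and crystallographic artifacts (altloc, gaps,
multiple models are exercised by constructed PDB fixtures and a bundled
real lysozyme structure instead). Passing the recovery studies therefore
shows the machinery is correct and robust to noise, permutation and hinge
motion at desk scale; it does not by itself establish accuracy on curated
reference sets, which require external data.

## Study conditions and problem sizes

The shipped recovery study uses five copies of the 60-residue template with
&sigma; = 0.3 &#8491; per-atom noise, copy 2 circularly permuted at the
domain boundary (cut 31) and copy 3 hinge-rotated 45° at the linker (pivot
30), five independent seeds (`benchmark_family_spec()`). Runs use the
desk-scale configuration `benchmark_params()`: 4 guide trees, population 8,
40 children per phase, stall 10, 8 replicator restarts (1 for profile
merges). These reduced schedules were fixed together with the study design:
on families of this size the initial progressive population already sits
near the optimum and longer schedules only re-confirm it. The clique
heuristic-versus-exact study runs 200 random graphs with up to 18 nodes and
edge densities 0.3/0.5/0.7; conflict-resolution minimality is checked
exhaustively on 100 instances of up to 10 nodes; the neighbor-joining
sampling law uses 10,000 draws on a 3-structure table.

## Degenerate inputs and numerical conventions

Superposition uses the SVD (Kabsch) solution with the determinant
correction, so reflections are never returned; rotation angles come from
the trace, clamped to [-1, 1]. Structures with fewer than 5 residues per
chain yield no descriptors; two structures with no similar descriptors give
an empty (not erroneous) alignment. Residues without a C&alpha; are skipped
on parsing with a warning; alternate locations resolve to highest occupancy
(first on ties); only the first model of a multi-model file is read.
Multi-chain structures concatenate into one residue list but elements never
cross chain boundaries. All randomness flows through R's generator; a
single seed makes a full run — including its output files — bitwise
reproducible.

## Known limitations

Descriptor-pair matching is greedy (anchored, two-round) rather than
exhaustive; pathological descriptors could in principle admit a larger
correspondence than the one found. Profile merging considers only column
merges supported by current descriptor pairs, so an error frozen into both
children of a guide-tree node can only be undone by a mutation above that
node. The FASTA writer must linearize permuted alignments; blocks that
cannot be emitted in every structure's sequence order are written in
master-structure (first present structure) order, which is a convention,
not information loss (the residue-range output is order-exact). Runtime is
dominated by the all-pairs descriptor comparison, quadratic in residue
count per structure pair; families of hundreds of residues per structure
are practical, whole proteomes are not the target.
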