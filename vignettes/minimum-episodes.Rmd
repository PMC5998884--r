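---
title: "Inferring duplication episodes from rooted and unrooted gene trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring duplication episodes from rooted and unrooted gene trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupisodes)
```

## The model

A species tree `S` is rooted, binary, and uniquely leaf-labeled; it is fixed
for a whole analysis. Gene family trees carry species names on their leaves,
possibly repeated, possibly covering only a subset of the species. The lca
mapping sends a gene leaf to its species leaf and an internal node to the lca
of its children's images; a node is a *duplication* when it maps to the same
species node as one of its children, otherwise a *speciation* (leaves
included). The duplication cost `D(G, S)` counts duplication nodes.

Evolutionary scenarios are represented as DLS trees: binary trees with
duplication (`+`) and speciation (`~`) internal nodes, and gene-sequence and
loss leaves. A duplication's children carry equal species sets, a
speciation's disjoint ones, and compatibility with `S` means every node's
species set is a cluster of `S`. `gt()` extracts the gene tree a scenario
explains by pruning losses and contracting degree-2 nodes.

Episodes cluster duplications across families: two duplications may share an
episode when they have the same cluster and are not comparable within one
family. For a scenario set R the episode count is
`MES(R, S) = sum over species nodes v of max over scenarios of duppath(T, v)`,
the longest comparable-duplication chain with cluster `cluster(v)`. The
minimum episodes (ME) score minimizes `MES` over scenarios that keep the
number of duplications minimal; for a rooted tree these scenarios are
exactly the placements of each duplication `d` inside its interval
`I(d) = [M(d), s]`, with `s` the child of `M(g)` towards `M(d)` for `g` the
lowest speciation above `d` (the species root when there is none), monotone
along comparable duplications.

## Unrooted reconciliation and the plateau

For an unrooted tree `U`, rooting on each edge gives a duplication cost; the
argmin edge set (the *plateau*) is a connected subtree. `edge_maps()`
computes the image of both directed sides of every edge with two
message-passing sweeps, and `plateau()` obtains all rooting costs from a
second two-sweep dynamic program over per-side duplication counts, so the
whole analysis is linear in `|U|` lca operations. The brute-force route —
root every edge and reconcile — is kept as `plateau_brute()` and is the
oracle in the tests, never the implementation.

Edges are typed by their two side images against the *effective top*: the
image of all species present in `U`. The published theory assumes gene trees
map to the species root; families restricted to a species subset would
otherwise misclassify every edge, so classification substitutes the
effective top while the interval model keeps the true species root as its
ceiling, leaving episode placement above the effective top available. This
is the package's own generalization choice; on families spanning all species
it coincides with the literal definition.

A plateau has either exactly one empty edge or at least one double edge.
Plateau leaves are speciations in every optimal rooting, internal plateau
nodes away from the empty edge duplications in every optimal rooting, and
the empty edge's endpoints are conditional. These role guarantees are
asserted wholesale in the test suite across randomized instances.

## Equivalence classes and decomposition

Rootings with equal speciation frontiers (maximal non-root speciations,
identified by node ids of `U`) form 1, 3 or 5 classes: the whole plateau
when a double edge exists; otherwise the empty edge alone (*plain* class)
plus one *complex* class per plateau single edge of an S2 star, consisting
of that edge and the plateau edges beyond it. `equiv_classes()` builds the
classes structurally and the definitional frontier partition is recomputed
independently in the tests and compared.

`decompose_class()` detaches, for a complex class `X`, the maximal subtrees
hanging off the leaves of the class subgraph (their roots are speciations in
every class rooting) and replaces each by a copy of the species subtree
below its image, yielding the reduced unrooted tree `U^X`. Copies carry no
provenance (`orig = NA`) so episode members are always reported on real gene
tree nodes; the only synthetic member is the root of a chosen rooting.
Score preservation of the decomposition is tested by comparing the
class-based solver with the naive enumeration over plateau rootings.

## Solvers

* `rme_score()` (rooted inputs) processes species nodes bottom-up. At node
  `s` it force-assigns every unassigned duplication whose interval top is
  `s`, at the lowest level above its already-placed same-tree descendants,
  then pulls unassigned duplications whose interval covers `s` into free
  levels `<= lambda(s)`. A pull is attempted only when all same-tree
  descendant duplications are already assigned — a refinement of the
  published sketch, since pulling a duplication below a still-unassigned
  descendant could break monotonicity. Candidates are ordered by deeper
  interval bottom, then tree index, then node id, and the pass repeats until
  stable, so results are deterministic. Optimality is not argued here; it is
  enforced by `brute_force_rme()`, which enumerates all monotone interval
  placements, across hundreds of randomized instances in the tests.
* `gnaw()` evaluates a complex class against a rooted background by solving
  the rooted problem once per class edge. This is the definitional contract
  (the minimum over class rootings); the published linear-time joint dynamic
  program is an optimization of the same quantity that this implementation
  does not need at its problem sizes, and skipping it also removes the
  assumption that background roots are speciations.
* `exact_ume()` enumerates the product of class choices (capped by `budget`,
  default `1e5`, honoring the `5^k` law) and scores each combination by
  joint enumeration of the chosen complex classes' edge rootings while that
  product is within `edge_budget` (default `1e4`). Beyond the cap it
  combines per-tree rooting minima, whose chains meet only in shared
  root-level episodes; the tests never reach that path and arbitrate the
  solver against `naive_ume()` throughout.
* `lower_bound()` discards the plateau duplications of every multi-class
  tree (keeping the rooted subtrees hanging off plateau leaves) and
  incorporates single-class trees fully, minimizing their class rootings
  *jointly*. A sequential greedy rooting of single-class trees can exceed
  the joint optimum and hence the exact score, which would invalidate the
  bound; joint minimization (or, above `edge_budget`, discarding those
  plateau duplications too) is always sound.
* `upper_bound()` commits every tree to its largest class (ties: plain
  first, then lowest class id), roots committed classes greedily against the
  accumulated background, and scores the fully rooted instance — a feasible
  configuration, hence an upper bound.
* `heuristic_ume()` returns the common bound value when the bounds coincide
  (then provably exact), runs the exact solver when the number of
  multi-class trees is within `k_budget` (default 7, about `5^7 = 78k`
  combinations), and otherwise greedily commits the tree/class pair with the
  smallest score against the current background, with deterministic
  tie-breaking by input order then class order.

## The simulator

`simulate_gene_families()` is the package's synthetic data generator, not a
test fixture: gene lineages traverse `S` top-down; entering a branch a
lineage is lost with `loss_prob` or duplicated with `dup_prob` (one trial
per branch per lineage — event chains within one branch are not modeled),
and at an injected episode node every surviving lineage duplicates with the
node's participation probability. Emitted DLS scenarios are grammar-valid by
construction because loss leaves record the full branch cluster; rooted
trees are their `gt()` extraction and unrooted trees dissolve the root.
Families whose gene tree has fewer than three leaves are resampled
(bounded), so all outputs are valid solver inputs. Default rates of 0.1 per
branch give moderately sized families on small species trees; the episode
recovery studies use `dup_prob = loss_prob = 0` with participation 1 so that
the planted episode is the only signal and its location is unambiguous.

The generator emulates the clustered-duplication signature the method is
built to detect. It does not emulate rate heterogeneity across branches or
families, gene tree estimation error, horizontal transfer, or incomplete
lineage sorting — so passing recovery tests show correctness of the
inference machinery on model data, not robustness of episode detection on
reconstructed empirical trees.

## Numerical and design choices

* Node identifiers are deterministic from parse order; `root_at()` preserves
  them (new root `n + 1`) and `unroot(root_at(U, e))` restores `U` exactly.
* Sets of edges are ordered by `(min node id, max node id)`; classes plain
  first, then by defining edge — all enumeration orders, and therefore all
  reported argmins, are reproducible.
* Unrooted trees with fewer than 3 leaves are rejected; rooted inputs pass
  through the unrooted solvers unchanged; an empty input collection scores 0.
* Species-tree nodes are reported as sorted comma-joined cluster strings,
  since newick gives internal nodes no canonical names.
* Problem sizes in the test suite — species trees of 3–8 leaves, gene trees
  of up to 10 leaves, up to 4 trees per instance, oracle enumerations capped
  at a few hundred combinations, 500 instances for the structural laws —
  were chosen so that the exhaustive oracles stay exact and the whole suite
  runs in a few minutes on one core.

## Limitations

* Only the duplication cost's plateau is supported (no duplication-loss or
  deep-coalescence plateaus), and only binary species trees.
* The exact solver is exponential in the number of multi-class trees; the
  heuristic's greedy phase is quadratic and comes with bounds, not a
  guarantee, although the bounds certify exactness whenever they meet.
* `mes_of_scenarios()` scores explicitly given scenarios; the package never
  enumerates a gene tree's full scenario set, and scenarios are produced
  explicitly only by the simulator.
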