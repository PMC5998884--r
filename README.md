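# dupisodes

Infer genomic duplication episodes — clusters of single gene duplications
that plausibly arose in one event, such as a whole-genome duplication — from
collections of gene family trees reconciled with a species tree, when the
gene trees may be **unrooted**.

## The problem

Given a fixed rooted binary species tree *S* and gene family trees with
leaves labeled by species, the classic reconciliation model maps every gene
tree node *g* to the species node M(*g*), the least common ancestor of the
species below *g*; an internal node is a *duplication* when it maps to the
same species node as one of its children. Genomic duplications leave a
signature of many gene families duplicating at the same species-tree
location, so single duplications are clustered into *episodes*: a duplication
*d* may be placed anywhere on its interval I(*d*) = [M(*d*), *s*], where *s*
is bounded by the mapping of the lowest speciation above *d*, and two
duplications may share an episode unless they are comparable (one ancestral
to the other) within one family. The **minimum episodes (ME) score** of a
set of scenarios R is

    MES(R, S) = Σ_{v ∈ S} max_{T ∈ R} duppath(T, v),

the sum over species nodes of the longest comparable-duplication chain any
single family places there; the ME problem minimizes this over all scenarios
with the minimal number of duplications.

Most published gene trees are unrooted. The set of rootings minimizing the
duplication cost forms a connected *plateau* U\* of edges, each typed empty,
single, or double by whether its two directed subtree images reach the
species root. The plateau carries 1, 3 or 5 equivalence classes of rootings
sharing a speciation frontier, and each class decomposes the tree into
detached rooted subtrees Δ(U, X) plus one reduced unrooted tree U^X, which
turns an instance with *n* unrooted trees into at most 5^*k*
rooted-plus-reduced instances (*k* = trees with an S2 star and more than one
class). The package implements:

* plateau computation with edge types, S2 stars and node roles
  (`plateau()`, `classify_edges()`, `edge_maps()`);
* the class decomposition (`equiv_classes()`, `decompose_class()`,
  `frontier()`);
* the rooted solver with duplication intervals and episode reconstruction
  (`intervals()`, `rme_score()`), plus a brute-force oracle
  (`brute_force_rme()`);
* exact, naive, lower-bound, upper-bound, and heuristic solvers for mixed
  rooted/unrooted inputs (`exact_ume()`, `naive_ume()`, `lower_bound()`,
  `upper_bound()`, `heuristic_ume()`, `gnaw()`);
* a DLS scenario grammar with gene-tree extraction and direct scenario
  scoring (`parse_dls()`, `gt()`, `mes_of_scenarios()`);
* a seeded duplication–loss simulator with injected episodes
  (`simulate_gene_families()`), and a runner/CLI (`ume_run()`,
  `inst/cli/ume.R`).

## Worked example

The nine-leaf unrooted tree below, against the species tree
`(((a,b),(c,d)),e)`, has a five-edge plateau with one empty edge, three
equivalence classes of sizes {1, 1, 3}, and an exact ME score of 4:

```r
library(dupisodes)
S <- parse_newick("(((a,b),(c,d)),e);", "species")
U <- parse_newick("(d,e,(c,(((a,b),b),((c,d),d))));", "unrooted")
plateau(U, S)
#> plateau: 5 of 15 edges optimal (duplication cost 4)
#>   empty edge: (2,10)
equiv_classes(U, S)
#> 3 equivalence class(es) on the plateau: sizes {1,1,3}, kinds {plain,complex,complex}
exact_ume(list(U), S)$result
#> minimum episodes score: 4 (4 episode(s))
#>   {a,b,c,d} level 1: 1 duplication(s)
#>   {a,b,c,d} level 2: 1 duplication(s)
#>   {a,b} level 1: 1 duplication(s)
#>   {c,d} level 1: 1 duplication(s)
```

The optimal scenario needs two stacked episodes at the `{a,b,c,d}` ancestor
(the tree retains a chain of two comparable duplications mapping there) and
one each at `{a,b}` and `{c,d}`. A simulated recovery run — 50 families, no
background events, every family duplicating at the `{a,b,c,d}` node —
reports exactly one episode at that node with score 1:

```r
v <- 7L  # the {a,b,c,d} node of S
fams <- simulate_gene_families(S, 50, dup_prob = 0, loss_prob = 0,
                               episodes = list(list(node = v, prob = 1)),
                               seed = 7)
heuristic_ume(lapply(fams, `[[`, "unrooted"), S)
#> ME score: 1 (method: heuristic)
#>   bounds: [0, 1]
```

## Command line

```sh
Rscript inst/cli/ume.R score --species S.nwk --genes trees.nwk --method heuristic
Rscript inst/cli/ume.R plateau --species S.nwk --genes trees.nwk
Rscript inst/cli/ume.R simulate --species S.nwk --families 100 \
    --dup-rate 0.1 --loss-rate 0.1 --episode a,b,c,d:0.9 --seed 1 --out-prefix sim
```

`score` exits 0 when the reported score is provably exact and 3 when it is a
bound/heuristic value.
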