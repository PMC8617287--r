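---
title: "Methods: disease modules, drug ranking and empirical validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease modules, drug ranking and empirical validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmedr)
```

netmedr implements a network-medicine workflow on typed heterogeneous
networks of genes, proteins, drugs and diseases: identify a disease module
on the protein–protein interaction (PPI) layer from a set of seed genes,
prioritize drugs against that module on the combined protein–drug layer,
and attach permutation-based empirical *P* values to both results. This
vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic benchmark does and does not establish.

## The data model

Networks hold four node kinds (`gene`, `protein`, `drug`, `disease`) and
six edge kinds (`ppi`, `drug_target`, `gene_disease`, `drug_indication`,
`gene_protein`, `disease_hierarchy`). Identifiers follow a
`namespace.identifier` convention (`entrez.1017`, `uniprot.P51587`,
`drugbank.DB00945`, `mondo.0005011`); inputs must arrive pre-mapped to
these namespaces, as no identifier-mapping service is included. All edge
kinds are undirected except `disease_hierarchy`, which points child →
parent; undirected edges are stored in a canonical orientation so that
file round-trips and equality tests are orientation-free. Duplicate edges
collapse to the first occurrence with a warning. Algorithms run on the
experimental-evidence PPI layer by default (`evidence == "experimental"`);
predicted interactions can be included with `experimental_only = FALSE`.

Gene seeds are mapped to the protein layer through `gene_protein` edges
before any algorithm runs; the mapping may be many-to-many and takes the
union of encoded proteins, warning about genes that encode nothing.

## Multi-Steiner-Trees modules (`must()`)

A Steiner tree is a minimum-cost subtree connecting the seed proteins
(terminals). `must()` builds `n_trees` (default 10) approximate trees with
the classical shortest-path heuristic — start at one terminal, repeatedly
attach the nearest unconnected terminal via a minimum-weight shortest
path, prune non-terminal leaves — which guarantees cost within
2·(1 − 1/ℓ) of the optimum for ℓ terminals. Because optimal trees are
rarely unique, each tree uses a different random terminal-insertion order
drawn from a per-tree-index seeded stream; the module is the union of the
accepted trees' nodes together with the full induced PPI subgraph.

A tree is accepted if its cost is within `tolerance` (default 0) of the
best cost found *so far*. Filtering against the running best rather than
the final best makes the module monotone in `n_trees` (adding trees can
only add members), which we consider the less surprising behaviour; with
`tolerance = 0` the union still concentrates on best-cost trees.

The hub penalty `lambda` ∈ [0, 1] re-weights each edge as

w(u,v) = (1 − λ) + λ·(deg(u) + deg(v)) / (2·d̄),

with d̄ the mean degree. λ = 0 gives unit weights; λ > 0 makes paths
through promiscuous hub proteins expensive, yielding modules more specific
to the seeds. The affine form was chosen so that the penalty is
scale-free in network size and the λ = 0 limit is exactly the unweighted
problem. The default number of trees (10) is a stability/runtime
compromise and is configurable.

Seeds split across connected components are handled per component with a
warning, producing one connected submodule per component; fewer than two
reachable seeds is an error.

## DIAMOnD expansion (`diamond()`)

DIAMOnD grows a module around the seeds by connectivity significance: at
each iteration, every non-member node adjacent to the module is scored
with the hypergeometric tail probability of having at least its observed
number of links into a module of the current size, and the most
significant node joins. Significances are recomputed from scratch every
iteration (never cached), and the result need not be connected.

The tail is computed with `stats::phyper` in log-stable form. Ties are
broken deterministically: smaller *p*, more links into the module, smaller
degree, lexicographic id. The seed weight `alpha` (default 1 = off) counts
links to seed members and the module's seed content `alpha`-fold before
the tail is evaluated, following the weighting of the original greedy
expansion algorithm; it is exposed but not used by any default.

## Drug ranking (`trustrank()`, `closeness_ranking()`)

Both rankers operate on the union of experimental PPI and drug–target
edges (unit weights); genes and diseases never enter, and
`approved_only = TRUE` drops non-approved drugs before ranking.

**TrustRank** propagates trust from the seeds: the score vector solves
t = d·W·t + (1 − d)·t₀ with W the column-normalized adjacency matrix, t₀
uniform over the seeds, and the mass of dangling (isolated) columns
redistributed to t₀. Power iteration stops when the L1 change drops below
`tolerance` (default 1e-6) or after `max_iterations` (default 100, with a
warning on non-convergence). The damping factor d (default 0.85) controls
how far trust spreads: higher values are more explorative, lower values
concentrate on the seeds' immediate neighbourhood.

**Seed-restricted closeness** scores a drug by its distances to the seeds
alone. The default harmonic form, C(v) = Σ_s 1/d(v, s), handles
unreachable seeds without special-casing (they contribute 0) and
preserves "closer to the module is better" ordering; the classical form
(reachable seeds divided by summed distance) is available via
`variant = "classical"`. Distances are unweighted: the hub penalty is a
module-mining concept and is not applied during ranking.

Candidate drugs come in two modes: *direct* drugs target a seed protein
itself; *indirect* drugs (default) are any drugs connected to the seeds'
component, i.e. everything that can earn a nonzero score. Direct
candidates are always a subset of indirect ones. Drugs with zero score are
dropped, remaining ties break lexicographically, and
`exclude_seed_targeting()` optionally removes drugs all of whose targets
are seeds — useful when one wants candidates acting on the module's
non-seed members.

## Empirical validation

All three validation methods compare an observed statistic against
`n_permutations` (default 1000) null draws and report p = r/n, where r
counts null statistics **strictly greater** than the observed one
(`strict = FALSE` switches to ≥ for a conservative treatment of ties).
When r = 0 the result is reported as "< 1/n" rather than 0 — at the
default 1000 permutations, "< 0.001".

* **Drug lists** (`validate_drug_list()`): null draws are uniform random
  ordered lists of the same length from a drug pool (default: all drug
  nodes). The rank-aware statistic is the discounted cumulative gain,
  DCG = Σᵢ dᵢ/log₂(i + 1) with dᵢ = 1 when the i-th drug is in the
  reference list; the `overlap` mode uses the plain hit count when ranks
  should not matter.
* **Modules** (`validate_module()`): null draws are *mock modules* matched
  to the observed module's size and number of connected components. The
  statistic is precision — reference drugs targeting the module divided by
  all drugs targeting it (0 when nothing targets it) — or the raw
  intersection size.
* **Joint** (`validate_joint()`): re-runs the full ranking pipeline with
  each (observed or mock) module's members as seeds and scores each
  resulting list by its precision (reference drugs in the list / list
  length) or intersection.

Mock modules are grown per component from a uniform start node by
repeatedly adding a uniform boundary neighbour, with components kept at
graph distance ≥ 2 so the induced component structure matches exactly;
dead ends retry (≤ 100 times). This sampler is simple and connected by
construction but is *not* uniform over all connected subgraphs — it
favours sets around high-degree regions, a bias shared by the observed
modules it is matched against and documented here rather than corrected.

Two properties of these conventions deserve emphasis. First, with a
discrete statistic, strict exceedance makes the empirical *P* value exact
only up to the statistic's tie mass; calibration is cleanest when the
statistic takes many values. Second, joint validation with indirect-mode
ranking and no top-k truncation is degenerate on a connected network: the
list *content* is then module-independent (every drug in the component
appears), precision ignores order, and all null draws tie the observed
value. Joint validation should therefore use a top-k cutoff or the
direct-drugs mode, and the package's own calibration checks do exactly
that.

The gene-set overlap test (`hypergeom_overlap_test()`) is the standard
hypergeometric upper tail P(X ≥ |A ∩ B|); the universe size defaults to a
user-supplied count, typically the number of gene nodes in the network.

## The synthetic benchmark

`generate_benchmark()` builds a test world with known ground truth:

* a connected scale-free interactome (preferential attachment, default
  1000 proteins, 2 edges per new node) whose heavy-tailed degrees make
  the hub penalty meaningful, with a one-to-one gene per protein;
* a planted module: a boundary-random-walk node set (default size 20)
  densified with extra intra-module edges (probability `module_density`,
  default 0.1, per non-adjacent pair). The densification is what makes
  the planted set a *module* in the network-medicine sense — a locally
  cohesive subnetwork — rather than an arbitrary connected set no
  algorithm could distinguish from background;
* disease-associated seed genes for half the members
  (`seed_fraction = 0.5`), sampled as a *spread*: members are flagged
  preferring nodes not adjacent to an already flagged seed, emulating the
  scattered way disease genes are discovered. If seeds were clustered,
  Steiner trees would connect them without any connector nodes and the
  module-mining step would be vacuous;
* 10 true drugs (approved, each targeting 3 module proteins, with an
  indication edge to the planted disease) and 50 decoys targeting only
  non-module proteins.

At these defaults, averaged over 20 generator seeds, the disease-gene →
DIAMOnD flow recovers about 85% of planted non-seed members (regression
bound: > 50%), and MuST recovers about 40% — MuST only ever adds
connectors that lie on cheap seed-to-seed paths, so its recovery is
bounded by how many planted members are needed as connectors at all. On
individual benchmark draws the MuST seed set occasionally happens to be
internally connected and no connectors are added; aggregate measurements
over several generator replicates are therefore used when comparing
recovery against degree-matched random node sets.

What passing these tests does *not* show: real interactomes have degree
correlations, community structure and study bias that preferential
attachment does not reproduce; real drug–target data are incomplete and
biased toward well-studied proteins; and real disease modules are not
cleanly densified subsets. The benchmark establishes algorithmic
correctness and end-to-end signal recovery under controlled conditions,
not clinical performance.

## Numerical and testing choices

* Hypergeometric tails via `phyper` (log-space); agreement with direct
  combinatorial summation is checked to 1e-12 for networks up to 60 nodes.
* TrustRank and closeness are checked against dense power-iteration and
  BFS oracles (L∞ ≤ 1e-10) on 200 random graphs of up to 60 nodes;
  Steiner costs against an exhaustive optimum on instances of up to 12
  nodes.
* Monte-Carlo *P* values are checked within three binomial standard errors
  of fully enumerated permutation *P* values on toy pools, and all three
  methods are calibration-checked under a random-reference null (200
  replicates × 200 permutations, Kolmogorov–Smirnov distance < 0.1) on a
  70-protein / 150-drug world sized so the statistics take many values.
* The test suite uses reduced problem sizes (networks of 25–150 nodes for
  oracles, the default 1000-protein benchmark for recovery checks);
  each suite run and the acceptance script complete in minutes on one CPU.
* All RNG flows through explicit seeds; scoped seeding restores the
  caller's RNG state, and identical configurations produce byte-identical
  pipeline artifacts.

## Limitations

No identifier mapping, no activation-vs-inhibition semantics on
drug–target edges, no gene-expression-driven module discovery, and no
false-negative (failed-drug) reference lists. Disease-hierarchy traversal
assumes a DAG of child → parent edges; cycles would not terminate and are
not checked for. The mock-module sampler's growth bias (above) is shared
between observed and null draws but is not a uniform null in the strict
sense.
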