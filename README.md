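# netmedr

Network medicine in R: disease-module identification and drug
repurposing on typed heterogeneous biological networks, with
permutation-based statistical validation.

## Who this is for

Computational biologists and pharmacology researchers who have (a) a
protein–protein interaction network with drug–target, gene–disease and
drug–indication annotations, and (b) a set of disease-associated genes
("seeds"), and who want to extract the disease's mechanistic subnetwork
and a ranked list of repurposable drug candidates — with empirical
*P* values saying how surprising those results are, not just a list.

## What it computes

**Heterogeneous networks.** Nodes are genes, proteins, drugs and diseases
(ids namespaced as `entrez.1017`, `uniprot.P51587`, `drugbank.DB00945`,
`mondo.0005011`); edges are `ppi` (with experimental/predicted evidence),
`drug_target`, `gene_disease`, `drug_indication`, `gene_protein` and a
directed child→parent `disease_hierarchy`. Read/write GraphML or TSV
tables; query disease genes with optional hierarchy descent.

**Disease modules** on the experimental PPI layer:

* `must()` — Multi-Steiner Trees: unions several shortest-path-heuristic
  Steiner trees over the seeds (random insertion orders, seeded). A hub
  penalty λ re-weights edges as
  `w(u,v) = (1 − λ) + λ·(deg u + deg v)/(2·mean deg)` so modules avoid
  promiscuous hubs.
* `diamond()` — DIAMOnD: greedy expansion by hypergeometric connectivity
  significance `p = Σ_{j≥ks} C(s0,j)·C(N−s0,k−j)/C(N,k)`, recomputed
  every iteration; most significant neighbour joins, n_added times.

**Drug ranking** on the combined PPI + drug–target graph:

* `trustrank()` — seed-personalized PageRank variant,
  `t = d·W·t + (1−d)·t0`, damping d (default 0.85), dangling mass
  returned to the seeds.
* `closeness_ranking()` — harmonic closeness restricted to the seeds,
  `C(v) = Σ_s 1/d(v,s)`; direct (seed-targeting only) or indirect
  (whole-component) candidate modes, approved-only filter,
  `exclude_seed_targeting()` post-filter.

**Validation** (`validate_drug_list()`, `validate_module()`,
`validate_joint()`): empirical `p = r/n` against 1000 random drug lists
(statistic: discounted cumulative gain `DCG = Σ d_i/log2(i+1)` or
overlap), or against mock modules matched to the observed module's size
and component count (statistic: precision of targeting drugs), reported
as `< 1/n` when no null draw exceeds the observation. Plus the
hypergeometric gene-set overlap test.

**Synthetic benchmarks** (`generate_benchmark()`): scale-free
interactome, planted locally-dense module, disease-associated seed genes,
true drugs targeting the module and decoys that don't — so the whole
pipeline is testable with known ground truth and no database downloads.

## Worked example

```r
library(netmedr)

bench <- generate_benchmark(benchmark_config(random_seed = 42))
bench
#> <benchmark> 2061 nodes; planted module of 20 proteins (10 seeds), 10 true / 50 decoy drugs

# Step 1: disease genes -> protein seeds
genes <- get_disease_genes(bench$net, bench$disease_id)
seeds <- map_seeds_to_proteins(bench$net, genes)

# Step 2: module identification
module <- diamond(bench$net, seeds, n_added = 10)
module
#> <disease_module> 20 proteins (10 seeds), 36 induced ppi edges, 1 component(s)
#>   algorithm: diamond

# Step 3: drug ranking from the module
ranked <- trustrank(bench$net, module$members)
head(as.data.frame(ranked), 3)
#>   rank              drug       score
#> 1    1 drugbank.SYND0007 0.006084046
#> 2    2 drugbank.SYND0003 0.005165825
#> 3    3 drugbank.SYND0004 0.005090524

# Statistical validation against the indicated (true) drugs
validate_drug_list(ranked, bench$true_drugs, net = bench$net,
                   n_permutations = 1000, random_seed = 42)
#> <empirical_result> mode=dcg  observed=4.533437  P < 0.001  (0/1000 null draws exceed)
validate_module(module, bench$net, bench$true_drugs,
                n_permutations = 1000, random_seed = 42)
#> <empirical_result> mode=precision  observed=0.9090909  P = 0.021  (21/1000 null draws exceed)
```

Reading the output: DIAMOnD recovered 8 of the 10 planted non-seed
module members (9 of the 10 true drugs land in the trustrank top 10); the
ranked list's DCG beats all 1000 random lists (`P < 0.001`), and 90.9% of
the drugs targeting the module are indicated drugs — higher precision
than 97.9% of size- and topology-matched random modules (`P = 0.021`).

The same workflow runs from the shell via the thin CLI,
e.g. `Rscript inst/cli/netmedr.R diamond --network net.graphml
--seeds seeds.txt --n-added 10 --out results/`, with subcommands for each
step (`synth`, `disease-genes`, `must`, `diamond`, `trustrank`,
`closeness`, `validate-drugs`, `validate-module`, `validate-joint`,
`run`).

See `vignettes/netmedr-methods.Rmd` for the models, parameter semantics,
null-model design and known limitations.

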