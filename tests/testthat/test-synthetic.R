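# Synthetic benchmark generator: determinism, planted ground truth,
# scale-free topology.

test_that("interactome growth produces the expected edge counts", {
  net <- generate_interactome(benchmark_config(n_proteins = 5,
                                               attachment = 1,
                                               module_size = 2,
                                               targets_per_drug = 1,
                                               random_seed = 1))
  expect_equal(sum(net$edges$kind == "ppi"), 4L)          # a tree
  expect_equal(sum(net$edges$kind == "gene_protein"), 5L) # one per protein
  expect_true(igraph::is_connected(netmedr:::ppi_igraph(net)))
})

test_that("generation is deterministic in the seed and varies across seeds", {
  a <- generate_interactome(benchmark_config(n_proteins = 50,
                                             random_seed = 7))
  b <- generate_interactome(benchmark_config(n_proteins = 50,
                                             random_seed = 7))
  expect_true(hetnet_equal(a, b))
  modules <- lapply(1:10, function(s)
    sort(generate_benchmark(benchmark_config(
      n_proteins = 80, module_size = 6, n_true_drugs = 3,
      n_decoy_drugs = 5, targets_per_drug = 2,
      random_seed = s))$planted_module$members))
  expect_equal(length(unique(modules)), 10L)
})

test_that("the degree distribution is heavy-tailed at scale", {
  net <- generate_interactome(benchmark_config(n_proteins = 1000,
                                               random_seed = 3))
  deg <- igraph::degree(netmedr:::ppi_igraph(net))
  expect_gt(max(deg), 5 * mean(deg))
})

test_that("planted modules are connected with the requested seed content", {
  for (s in 1:20) {
    cfg <- benchmark_config(n_proteins = 60, module_size = 8,
                            targets_per_drug = 2, n_true_drugs = 3,
                            n_decoy_drugs = 5, random_seed = s)
    p <- plant_module(generate_interactome(cfg), cfg)
    expect_equal(p$module$n_components, 1L)
    expect_equal(length(p$module$members), 8L)
    expect_equal(length(p$module$seeds), 4L)  # ceiling(0.5 * 8)
  }
  # seed_fraction 1: every member gene is disease-associated
  cfg1 <- benchmark_config(n_proteins = 40, module_size = 5,
                           seed_fraction = 1, targets_per_drug = 2,
                           n_true_drugs = 2, n_decoy_drugs = 3,
                           random_seed = 2)
  p1 <- plant_module(generate_interactome(cfg1), cfg1)
  expect_equal(length(p1$seed_genes), 5L)
  # module_size 1: a single gene-disease association
  cfg2 <- benchmark_config(n_proteins = 40, module_size = 1,
                           targets_per_drug = 1, n_true_drugs = 2,
                           n_decoy_drugs = 3, random_seed = 2)
  p2 <- plant_module(generate_interactome(cfg2), cfg2)
  expect_equal(length(p2$module$members), 1L)
  expect_equal(length(p2$seed_genes), 1L)
})

test_that("true drugs hit the module, decoys never do", {
  b <- small_bench()
  dt <- b$net$edges[b$net$edges$kind == "drug_target", ]
  for (d in b$true_drugs)
    expect_true(all(dt$target[dt$source == d] %in%
                      b$planted_module$members))
  for (d in b$decoy_drugs)
    expect_equal(length(intersect(dt$target[dt$source == d],
                                  b$planted_module$members)), 0L)
  # drugs targeting the module include every true drug
  expect_true(all(b$true_drugs %in%
                    drugs_targeting(b$net, b$planted_module$members)))
  # every true drug is indicated for the planted disease, decoys are not
  expect_setequal(indicated_drugs(b$net, b$disease_id), b$true_drugs)
})

test_that("oversized drug target demands are rejected", {
  cfg <- benchmark_config(n_proteins = 30, module_size = 2,
                          targets_per_drug = 5, n_true_drugs = 2,
                          n_decoy_drugs = 2, random_seed = 1)
  p <- plant_module(generate_interactome(cfg), cfg)
  expect_error(attach_drugs(p$net, p$module, p$disease_id, cfg),
               "parameter error")
})

test_that("disease query recovers exactly the planted seed genes", {
  b <- small_bench()
  genes <- get_disease_genes(b$net, b$disease_id)
  expect_setequal(as.character(genes), b$seed_genes)
  prot <- map_seeds_to_proteins(b$net, genes)
  expect_setequal(as.character(prot), b$planted_module$seeds)
})

test_that("a benchmark survives GraphML with identical pipeline results", {
  b <- generate_benchmark(benchmark_config(
    n_proteins = 60, module_size = 6, n_true_drugs = 3, n_decoy_drugs = 6,
    targets_per_drug = 2, random_seed = 5))
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(b$net, f)
  net2 <- read_graphml(f)
  seeds <- b$planted_module$seeds
  d1 <- diamond(b$net, seeds, n_added = 4)
  d2 <- diamond(net2, seeds, n_added = 4)
  expect_equal(d1$members, d2$members)
  r1 <- closeness_ranking(b$net, seeds)
  r2 <- closeness_ranking(net2, seeds)
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("write_benchmark emits network and ground truth files", {
  b <- generate_benchmark(benchmark_config(
    n_proteins = 30, module_size = 4, n_true_drugs = 2, n_decoy_drugs = 3,
    targets_per_drug = 2, random_seed = 4))
  d <- withr::local_tempdir()
  write_benchmark(b, d)
  expect_true(file.exists(file.path(d, "network.graphml")))
  gt <- jsonlite::read_json(file.path(d, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_setequal(gt$true_drugs, b$true_drugs)
  expect_setequal(gt$module_members, b$planted_module$members)
})
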