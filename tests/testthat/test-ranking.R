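# Ranking graph construction, TrustRank, seed-restricted closeness,
# candidate modes, seed-target exclusion.

test_that("ranking graph unions ppi and drug_target layers only", {
  net <- toy_hetnet()
  rg <- ranking_graph(net)
  # 3 experimental ppi + 3 drug_target; predicted ppi excluded
  expect_equal(igraph::ecount(rg), 6)
  expect_setequal(unique(igraph::V(rg)$kind), c("protein", "drug"))
  # approved filter drops D3 and its edges
  rga <- ranking_graph(net, approved_only = TRUE)
  expect_false("drugbank.D3" %in% igraph::V(rga)$name)
  expect_equal(igraph::ecount(rga), 5)
})

test_that("trustrank with no damping keeps all trust on the seeds", {
  net <- toy_hetnet()
  r <- trustrank(net, "uniprot.P1", damping = 0)
  expect_equal(nrow(r), 0L)
})

test_that("drugs symmetric under a seed-fixing automorphism score equally", {
  # D1 and D2 both target P2 only: swapping them is an automorphism
  net <- toy_hetnet()
  r <- trustrank(net, "uniprot.P1", damping = 0.85)
  s <- r$score[match(c("drugbank.D1", "drugbank.D2"), r$drug)]
  expect_equal(s[1], s[2])
  # ties broken lexicographically
  expect_lt(r$rank[r$drug == "drugbank.D1"], r$rank[r$drug == "drugbank.D2"])
})

test_that("trustrank matches a dense power-iteration oracle", {
  for (s in 1:10) {
    b <- generate_benchmark(benchmark_config(
      n_proteins = 25, module_size = 4, n_true_drugs = 3, n_decoy_drugs = 6,
      targets_per_drug = 2, random_seed = 600 + s))
    net <- b$net
    rg <- ranking_graph(net)
    A <- as.matrix(igraph::as_adjacency_matrix(rg))
    seeds <- b$planted_module$seeds
    idx <- match(seeds, igraph::V(rg)$name)
    want <- oracle_trustrank(A, idx, damping = 0.85, tol = 1e-14)
    names(want) <- igraph::V(rg)$name
    got <- trustrank(net, seeds, damping = 0.85, tolerance = 1e-14,
                     max_iterations = 10000)
    expect_gt(nrow(got), 0)
    expect_lt(max(abs(got$score - want[got$drug])), 1e-10)
    # trust is a probability vector when no node dangles
    if (all(igraph::degree(rg) > 0)) {
      full_idx <- igraph::V(rg)$name
      expect_true(all(want >= 0))
    }
  }
})

test_that("trustrank scores are invariant to node insertion order", {
  b <- small_bench()
  net <- b$net
  perm <- netmedr:::with_rng(4, sample(nrow(net$nodes)))
  net2 <- hetnet(net$nodes[perm, ], net$edges)
  r1 <- trustrank(net, b$planted_module$seeds)
  r2 <- trustrank(net2, b$planted_module$seeds)
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("closeness follows the harmonic definition", {
  # drug -> its target -> each of 3 seeds: distance 2 to each, C = 3/2
  edges <- rbind(
    data.frame(source = "drugbank.DX", target = "uniprot.H0",
               kind = "drug_target", evidence = NA),
    data.frame(source = "uniprot.H0",
               target = c("uniprot.S1", "uniprot.S2", "uniprot.S3"),
               kind = "ppi", evidence = "experimental"))
  nodes <- rbind(
    data.frame(id = c("uniprot.H0", "uniprot.S1", "uniprot.S2",
                      "uniprot.S3"), kind = "protein"),
    data.frame(id = "drugbank.DX", kind = "drug"))
  net <- hetnet(nodes, edges)
  r <- closeness_ranking(net, c("uniprot.S1", "uniprot.S2", "uniprot.S3"))
  expect_equal(r$score, 3 / 2)
  # a drug at distance 1 from a seed outranks one at distance 2
  r2 <- closeness_ranking(net, "uniprot.H0")
  expect_equal(r2$score, 1)
})

test_that("closeness matches a BFS oracle on random graphs", {
  for (s in 1:10) {
    b <- generate_benchmark(benchmark_config(
      n_proteins = 30, module_size = 4, n_true_drugs = 4, n_decoy_drugs = 8,
      targets_per_drug = 2, random_seed = 700 + s))
    net <- b$net
    rg <- ranking_graph(net)
    A <- as.matrix(igraph::as_adjacency_matrix(rg))
    nm <- igraph::V(rg)$name
    seeds <- b$planted_module$seeds
    drugs <- nm[igraph::V(rg)$kind == "drug"]
    want <- oracle_closeness(A, match(drugs, nm), match(seeds, nm))
    names(want) <- drugs
    got <- closeness_ranking(net, seeds)
    expect_equal(got$score, unname(want[got$drug]), tolerance = 1e-12)
  }
})

test_that("direct candidates are a subset of indirect candidates", {
  net <- toy_hetnet()
  direct <- candidate_drugs(net, "uniprot.P2", include_indirect = FALSE)
  indirect <- candidate_drugs(net, "uniprot.P2", include_indirect = TRUE)
  expect_true(all(direct %in% indirect))
  expect_setequal(direct, c("drugbank.D1", "drugbank.D2"))
})

test_that("indirect mode retrieves drugs that target only the vicinity", {
  # Gemfibrozil-style 3-hop topology: drug -> T -> X -> seed
  nodes <- rbind(
    data.frame(id = c("uniprot.SEED", "uniprot.X", "uniprot.T"),
               kind = "protein"),
    data.frame(id = "drugbank.GEM", kind = "drug"))
  edges <- rbind(
    data.frame(source = "uniprot.SEED", target = "uniprot.X", kind = "ppi",
               evidence = "experimental"),
    data.frame(source = "uniprot.X", target = "uniprot.T", kind = "ppi",
               evidence = "experimental"),
    data.frame(source = "drugbank.GEM", target = "uniprot.T",
               kind = "drug_target", evidence = NA))
  net <- hetnet(nodes, edges)
  expect_equal(candidate_drugs(net, "uniprot.SEED",
                               include_indirect = FALSE), character(0))
  expect_equal(candidate_drugs(net, "uniprot.SEED",
                               include_indirect = TRUE), "drugbank.GEM")
  rd <- closeness_ranking(net, "uniprot.SEED", include_indirect = FALSE)
  expect_equal(nrow(rd), 0L)
  ri <- closeness_ranking(net, "uniprot.SEED", include_indirect = TRUE)
  expect_equal(ri$drug, "drugbank.GEM")
  expect_equal(ri$score, 1 / 3)  # BFS distance 3 to the seed
})

test_that("exclude_seed_targeting removes drugs targeting only seeds", {
  net <- toy_hetnet()
  ranked <- closeness_ranking(net, "uniprot.P2")
  # D1 and D2 target only P2 (a seed); both must go
  out <- exclude_seed_targeting(ranked, net, "uniprot.P2")
  expect_false(any(c("drugbank.D1", "drugbank.D2") %in% out$drug))
  if (nrow(out)) expect_equal(out$rank, seq_len(nrow(out)))
  # empty exclusion set is the identity
  expect_equal(exclude_seed_targeting(ranked, net, character(0)), ranked)
  # a drug with one target outside the exclusion set survives
  nodes2 <- rbind(net$nodes,
                  data.frame(id = "drugbank.D9", kind = "drug",
                             label = "wide", groups = "approved",
                             evidence = NA))
  edges2 <- rbind(net$edges,
                  data.frame(source = c("drugbank.D9", "drugbank.D9"),
                             target = c("uniprot.P2", "uniprot.P3"),
                             kind = "drug_target", evidence = NA))
  net2 <- hetnet(nodes2, edges2)
  ranked2 <- closeness_ranking(net2, "uniprot.P2")
  out2 <- exclude_seed_targeting(ranked2, net2, "uniprot.P2")
  expect_true("drugbank.D9" %in% out2$drug)
})

test_that("ranked lists are sorted, 1-based and free of zero scores", {
  b <- small_bench()
  for (r in list(trustrank(b$net, b$planted_module$seeds),
                 closeness_ranking(b$net, b$planted_module$seeds))) {
    expect_true(all(diff(r$score) <= 0))
    expect_equal(r$rank, seq_len(nrow(r)))
    expect_true(all(r$score > 0))
  }
})
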