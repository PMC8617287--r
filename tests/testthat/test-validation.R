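# DCG, empirical p-values, mock modules, hypergeometric overlap.

test_that("dcg reproduces its defining formula", {
  expect_equal(dcg(c("A", "B", "C"), "A"), 1)
  expect_equal(dcg(c("A", "B", "C", "D"), c("A", "C")), 1.5)
  expect_equal(dcg(c("B", "C"), "A"), 0)
  expect_equal(dcg(c("X", "B"), "B"), 1 / log2(3))
  expect_error(dcg(c("A", "A"), "A"), "duplicates")
})

test_that("dcg rewards earlier hits and ignores tail shuffles", {
  ref <- c("A", "B")
  base <- dcg(c("X", "A", "Y", "B", "Z"), ref)
  # moving a hit up strictly increases the gain
  expect_gt(dcg(c("A", "X", "Y", "B", "Z"), ref), base)
  # permuting non-reference items below the last hit changes nothing
  expect_equal(dcg(c("X", "A", "Y", "B", "W", "Z"), ref),
               dcg(c("X", "A", "Y", "B", "Z", "W"), ref))
})

test_that("an unbeatable list reports the p-value floor", {
  pool <- paste0("drugbank.Z", 1:10)
  ref <- pool[1:3]
  # observed list: all reference drugs at the top
  res <- validate_drug_list(c(ref, pool[4]), ref, pool = pool,
                            n_permutations = 1000, random_seed = 3)
  expect_equal(res$n_exceeding, 0L)
  expect_equal(res$p, 0)
  expect_equal(res$reported, "< 0.001")
})

test_that("monte-carlo drug-list p agrees with exhaustive enumeration", {
  pool <- paste0("drugbank.Q", 1:4)
  ref <- pool[c(1, 3)]
  obs <- pool[c(2, 1)]  # one hit at rank 2
  # exact p over all ordered pairs from the pool
  perms <- expand.grid(a = pool, b = pool, stringsAsFactors = FALSE)
  perms <- perms[perms$a != perms$b, ]
  for (mode in c("dcg", "overlap")) {
    stat <- function(x) if (mode == "dcg") dcg(x, ref) else sum(x %in% ref)
    s_obs <- stat(obs)
    exact <- mean(apply(perms, 1, function(r) stat(r) > s_obs))
    got <- validate_drug_list(obs, ref, pool = pool, n_permutations = 4000,
                              mode = mode, random_seed = 17)
    se <- sqrt(exact * (1 - exact) / 4000)
    expect_lt(abs(got$p - exact), 3 * se + 1e-12)
  }
})

test_that("validate_drug_list is deterministic and validates inputs", {
  pool <- paste0("drugbank.R", 1:8)
  a <- validate_drug_list(pool[1:3], pool[1:2], pool = pool,
                          n_permutations = 50, random_seed = 9)
  b <- validate_drug_list(pool[1:3], pool[1:2], pool = pool,
                          n_permutations = 50, random_seed = 9)
  expect_identical(a, b)
  expect_error(validate_drug_list(pool, pool[1:2], pool = pool[1:3]),
               "sampling error")
  expect_error(validate_drug_list(pool[c(1, 1)], pool[1:2], pool = pool),
               "duplicates")
})

test_that("mock modules match the requested component structure exactly", {
  # forced cases
  g3 <- igraph::make_graph(~ a - b, b - c)
  m <- sample_mock_module(g3, 3, random_seed = 1)
  expect_setequal(m$members, c("a", "b", "c"))
  m1 <- sample_mock_module(g3, 1, random_seed = 2)
  expect_equal(length(m1$members), 1L)
  expect_equal(m1$n_components, 1L)
  # fidelity sweep on a random graph, including two-component specs
  g <- random_ppi(60, 0.06, seed = 88)
  for (i in 1:50) {
    m <- sample_mock_module(g, c(4, 3), random_seed = 100 + i)
    expect_equal(module_component_sizes(m), c(4, 3))
  }
  # unsatisfiable: component larger than the graph allows
  tiny <- igraph::make_graph(~ a - b)
  expect_error(sample_mock_module(tiny, 3, random_seed = 1),
               "sampling error")
})

test_that("module precision follows its definition and conventions", {
  net <- toy_hetnet()
  mod <- disease_module(c("uniprot.P2", "uniprot.P5"), ppi = net)
  # targeting drugs: D1, D2 (P2) and D3 (P5)
  expect_equal(module_precision(mod, net, "drugbank.D1"), 1 / 3)
  expect_equal(module_precision(mod, net, "drugbank.D1",
                                mode = "intersection"), 1)
  # nothing targets P1
  mod1 <- disease_module("uniprot.P1", ppi = net)
  expect_equal(module_precision(mod1, net, "drugbank.D1"), 0)
  # full containment
  expect_equal(module_precision(mod, net,
                                paste0("drugbank.D", 1:3)), 1)
})

test_that("module validation p matches exhaustive enumeration on a cycle", {
  # C10 with one drug per node: boundary growth is uniform over the 10
  # paths of length 3, so the sampler's p equals the enumeration p
  n <- 10
  prot <- sprintf("uniprot.Y%02d", 1:n)
  drugs <- sprintf("drugbank.Y%02d", 1:n)
  nodes <- rbind(data.frame(id = prot, kind = "protein"),
                 data.frame(id = drugs, kind = "drug"))
  edges <- rbind(
    data.frame(source = prot, target = prot[c(2:n, 1)], kind = "ppi",
               evidence = "experimental"),
    data.frame(source = drugs, target = prot, kind = "drug_target",
               evidence = NA))
  net <- hetnet(nodes, edges)
  ref <- drugs[c(1, 2, 6)]
  mod <- disease_module(prot[5:7], ppi = net)  # targeted by drugs 5-7
  obs <- module_precision(mod, net, ref, mode = "intersection")
  expect_equal(obs, 1)
  # enumerate all connected 3-sets of a cycle: the n contiguous arcs
  arcs <- lapply(1:n, function(i) prot[((i:(i + 2) - 1) %% n) + 1])
  stats <- vapply(arcs, function(a)
    length(intersect(drugs[match(a, prot)], ref)), numeric(1))
  exact <- mean(stats > obs)
  got <- validate_module(mod, net, ref, n_permutations = 4000,
                         mode = "intersection", random_seed = 23)
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(got$p - exact), 3 * se + 1e-12)
})

test_that("a maximal-precision module reports the floor", {
  net <- toy_hetnet()
  mod <- disease_module("uniprot.P2", ppi = net)
  res <- validate_module(mod, net, c("drugbank.D1", "drugbank.D2"),
                         n_permutations = 100, random_seed = 2)
  expect_equal(res$statistic_observed, 1)
  expect_equal(res$n_exceeding, 0L)
  expect_match(res$reported, "^< ")
})

test_that("joint validation scores the ranked list's precision", {
  b <- small_bench()
  rank_fun <- function(net, seeds)
    closeness_ranking(net, seeds, include_indirect = FALSE)
  res <- validate_joint(b$planted_module, b$net, b$true_drugs,
                        ranking = rank_fun, n_permutations = 30,
                        random_seed = 6)
  expect_true(res$statistic_observed >= 0 && res$statistic_observed <= 1)
  expect_true(res$p >= 0 && res$p <= 1)
  expect_error(validate_joint(b$planted_module, b$net, b$true_drugs,
                              ranking = rank_fun, n_permutations = 0),
               "n_permutations")
})

test_that("the reported string follows the r = 0 convention", {
  pool <- paste0("drugbank.S", 1:6)
  # r > 0 case: observed list with no hits, any random list ties or beats
  res <- validate_drug_list(pool[4:6], pool[1], pool = pool,
                            n_permutations = 200, random_seed = 11)
  expect_gt(res$n_exceeding, 0)
  expect_match(res$reported, "^= ")
  expect_equal(res$p, res$n_exceeding / res$n_permutations)
})

test_that("hypergeometric overlap test matches exact combinatorics", {
  genes <- paste0("entrez.", 1:10)
  # disjoint sets: P(X >= 0) = 1
  expect_equal(hypergeom_overlap_test(genes[1:3], genes[4:6], 10), 1)
  # complete overlap of two 5-sets in a 10-universe: 1 / C(10,5)
  expect_equal(hypergeom_overlap_test(genes[1:5], genes[1:5], 10),
               1 / choose(10, 5))
  # |A| = 3, |B| = 2, overlap 1: 1 - C(7,2)/C(10,2) = 8/15
  expect_equal(hypergeom_overlap_test(genes[1:3], genes[c(3, 8)], 10),
               8 / 15)
  expect_error(hypergeom_overlap_test(genes, genes[1:2], 5), "universe")
})

test_that("validation JSON serializes all fields", {
  pool <- paste0("drugbank.T", 1:5)
  res <- validate_drug_list(pool[1:2], pool[1], pool = pool,
                            n_permutations = 20, random_seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_validation_json(list(drugs = res), f)
  back <- jsonlite::read_json(f)
  expect_equal(back$drugs$n_permutations, 20L)
  expect_equal(back$drugs$p, res$p)
})
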