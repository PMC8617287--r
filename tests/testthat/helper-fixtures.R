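# Fixtures and independent oracles shared across test files. All fixtures
# are built in code; the oracles deliberately avoid the code paths they
# check (igraph shortcuts, phyper, the package's own samplers).

# A small heterogeneous net touching every node and edge kind:
# proteins P1-P5 (ppi chain P1-P2-P3-P4 experimental, P4-P5 predicted),
# genes G1-G5 encoding P1-P5 (G5 also encodes P4: many-to-many),
# drugs D1-D3 targeting P2/P2/P5 (D3 unapproved), disease hierarchy
# root <- childA <- leaf and root <- childB <- leaf (diamond shape),
# gene-disease and drug-indication edges.
toy_hetnet <- function() {
  nodes <- rbind(
    data.frame(id = paste0("uniprot.P", 1:5), kind = "protein",
               label = paste0("P", 1:5), groups = NA, evidence = NA),
    data.frame(id = paste0("entrez.", 1:5), kind = "gene",
               label = paste0("G", 1:5), groups = NA, evidence = NA),
    data.frame(id = paste0("drugbank.D", 1:3), kind = "drug",
               label = c("DrugOne", "DrugTwo", "DrugThrée"),
               groups = c("approved", "approved", "other"), evidence = NA),
    data.frame(id = paste0("mondo.000", 1:4), kind = "disease",
               label = c("root", "childA", "childB", "leaf"),
               groups = NA, evidence = NA))
  edges <- rbind(
    data.frame(source = paste0("uniprot.P", 1:3),
               target = paste0("uniprot.P", 2:4), kind = "ppi",
               evidence = "experimental"),
    data.frame(source = "uniprot.P4", target = "uniprot.P5", kind = "ppi",
               evidence = "predicted"),
    data.frame(source = paste0("entrez.", c(1:5, 5)),
               target = paste0("uniprot.P", c(1:5, 4)),
               kind = "gene_protein", evidence = NA),
    data.frame(source = paste0("drugbank.D", c(1, 2, 3)),
               target = paste0("uniprot.P", c(2, 2, 5)),
               kind = "drug_target", evidence = NA),
    data.frame(source = c("mondo.0002", "mondo.0003", "mondo.0004",
                          "mondo.0004"),
               target = c("mondo.0001", "mondo.0001", "mondo.0002",
                          "mondo.0003"),
               kind = "disease_hierarchy", evidence = NA),
    data.frame(source = paste0("entrez.", c(1, 2, 3)),
               target = c("mondo.0001", "mondo.0002", "mondo.0004"),
               kind = "gene_disease", evidence = NA),
    data.frame(source = "drugbank.D1", target = "mondo.0001",
               kind = "drug_indication", evidence = NA))
  hetnet(nodes, edges)
}

# random labelled PPI igraph (Erdos-Renyi), names in package id style
random_ppi <- function(n, p, seed) {
  g <- netmedr:::with_rng(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- sprintf("uniprot.T%03d", seq_len(n))
  g
}

# --- independent oracles -------------------------------------------------

# hypergeometric upper tail by direct summation of binomial coefficients
oracle_hyper_tail <- function(N, s0, k, ks) {
  if (ks == 0) return(1)
  j <- ks:min(k, s0)
  sum(choose(s0, j) * choose(N - s0, k - j)) / choose(N, k)
}

# single-source shortest-path lengths by level-synchronous BFS on an
# adjacency list (no igraph)
oracle_bfs <- function(adj, from) {
  n <- length(adj)
  d <- rep(Inf, n); d[from] <- 0
  frontier <- from; lev <- 0
  while (length(frontier)) {
    lev <- lev + 1
    nxt <- setdiff(unique(unlist(adj[frontier])), which(is.finite(d)))
    d[nxt] <- lev
    frontier <- nxt
  }
  d
}

# seed-restricted harmonic closeness from a dense adjacency matrix
oracle_closeness <- function(A, drug_idx, seed_idx) {
  adj <- apply(A, 1, function(r) which(r > 0), simplify = FALSE)
  vapply(drug_idx, function(v) {
    d <- oracle_bfs(adj, v)
    sum(1 / d[seed_idx])
  }, numeric(1))
}

# dense power-iteration TrustRank oracle (plain matrix arithmetic)
oracle_trustrank <- function(A, seed_idx, damping, tol = 1e-12,
                             max_iter = 100000) {
  n <- nrow(A)
  t0 <- rep(0, n); t0[seed_idx] <- 1 / length(seed_idx)
  cs <- colSums(A)
  W <- A
  W[, cs > 0] <- sweep(A[, cs > 0, drop = FALSE], 2, cs[cs > 0], "/")
  t <- t0
  for (i in seq_len(max_iter)) {
    t_new <- damping * (W %*% t + sum(t[cs == 0]) * t0) + (1 - damping) * t0
    if (sum(abs(t_new - t)) < tol) return(as.numeric(t_new))
    t <- t_new
  }
  as.numeric(t)
}

# exact optimal Steiner tree cost: minimum, over all vertex supersets of
# the terminals, of the MST weight of the induced connected subgraph
oracle_steiner_opt <- function(g, terminals, weights) {
  nm <- igraph::V(g)$name
  others <- setdiff(nm, terminals)
  best <- Inf
  for (k in 0:length(others)) {
    sets <- if (k == 0) list(character(0)) else
      utils::combn(others, k, simplify = FALSE)
    for (s in sets) {
      vs <- c(terminals, s)
      sub <- igraph::induced_subgraph(g, vs)
      if (!igraph::is_connected(sub)) next
      w <- weights[igraph::get_edge_ids(
        g, t(igraph::as_edgelist(sub, names = TRUE)))]
      mst <- igraph::mst(sub, weights = w)
      wm <- sum(weights[igraph::get_edge_ids(
        g, t(igraph::as_edgelist(mst, names = TRUE)))])
      best <- min(best, wm)
    }
    # supersets cannot beat a connected subgraph found at smaller k only
    # when all weights are positive; keep scanning all k for correctness
  }
  best
}

# calibration world: a 70-protein interactome with dense drug coverage
# (150 drugs with 1-2 targets each), sized so the validation statistics
# take many distinct values under a random reference
calibration_world <- function(seed = 2024) {
  netmedr:::with_rng(seed, {
    g <- igraph::sample_pa(70, m = 2, directed = FALSE)
    prot <- sprintf("uniprot.C%03d", 1:70)
    drugs <- sprintf("drugbank.C%04d", 1:150)
    igraph::V(g)$name <- prot
    el <- igraph::as_edgelist(g)
    ntarg <- sample(1:2, 150, replace = TRUE)
    dt <- data.frame(source = rep(drugs, ntarg),
                     target = unlist(lapply(ntarg, function(k)
                       sample(prot, k))),
                     kind = "drug_target")
    dt <- dt[!duplicated(dt[, 1:2]), ]
    nodes <- rbind(data.frame(id = prot, kind = "protein", label = prot,
                              groups = NA),
                   data.frame(id = drugs, kind = "drug", label = drugs,
                              groups = "approved"))
    edges <- rbind(data.frame(source = el[, 1], target = el[, 2],
                              kind = "ppi", evidence = "experimental"),
                   transform(dt, evidence = NA))
    list(net = hetnet(nodes, edges), proteins = prot, drugs = drugs)
  })
}

# degree-matched random node sets: for each node in `like`, draw a node of
# similar degree (within a +-5 window of its degree rank), avoiding `avoid`
sample_degree_matched <- function(deg, like, avoid) {
  pool <- setdiff(names(deg), avoid)
  deg <- deg[pool]
  ord <- names(sort(deg))
  picks <- character(0)
  for (v in like) {
    target <- deg[[v]] %||% deg[[sample(names(deg), 1)]]
    ranks <- order(abs(deg[ord] - target))
    window <- ord[ranks[seq_len(min(11, length(ord)))]]
    window <- setdiff(window, picks)
    picks <- c(picks, sample(window, 1))
  }
  picks
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small benchmark used by several test files (kept light)
small_bench <- function(seed = 11) {
  generate_benchmark(benchmark_config(
    n_proteins = 150, attachment = 2, module_size = 10,
    n_true_drugs = 6, n_decoy_drugs = 20, targets_per_drug = 2,
    random_seed = seed))
}
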