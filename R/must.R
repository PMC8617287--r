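# Multi-Steiner Trees (MuST) disease-module identification.
#
# A module is the union of several approximate Steiner trees connecting the
# seed proteins on the PPI layer. Hubs can be penalized through the edge
# weights so trees route around promiscuous proteins.

#' Hub-penalized edge weight
#'
#' Weight of edge (u, v): `(1 - lambda) + lambda * (deg(u) + deg(v)) / (2 * dbar)`
#' where `dbar` is the mean degree of the PPI layer. `lambda = 0` gives unit
#' weights (penalty off); for `lambda > 0` the weight grows with the summed
#' endpoint degrees, so minimum-cost trees avoid hubs.
#'
#' @param net a [hetnet()] or a PPI igraph.
#' @param u,v protein ids of an existing ppi edge.
#' @param lambda hub penalty in `[0, 1]`.
#' @return numeric edge weight.
#' @export
hub_penalized_weight <- function(net, u, v, lambda) {
  g <- ppi_igraph(net)
  eid <- igraph::get_edge_ids(g, c(u, v))
  if (any(eid == 0)) stop("edge not present: ", u, " -- ", v, call. = FALSE)
  check_lambda(lambda)
  deg <- igraph::degree(g)
  dbar <- mean(deg)
  unname((1 - lambda) + lambda * (deg[u] + deg[v]) / (2 * dbar))
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("hub penalty lambda must be a number in [0, 1]", call. = FALSE)
  invisible(lambda)
}

# internal: vector of hub-penalized weights over all edges of g
hub_weights <- function(g, lambda) {
  check_lambda(lambda)
  if (igraph::ecount(g) == 0L) return(numeric(0))
  deg <- igraph::degree(g)
  el <- igraph::ends(g, igraph::E(g), names = TRUE)
  (1 - lambda) + lambda * (deg[el[, 1L]] + deg[el[, 2L]]) / (2 * mean(deg))
}

#' Approximate Steiner tree by the shortest-path heuristic
#'
#' Starting from the first terminal, repeatedly connects the nearest
#' not-yet-connected terminal to the growing tree via a minimum-weight
#' shortest path, then prunes non-terminal leaves. The classical heuristic
#' guarantees cost at most `2 * (1 - 1/l)` times the optimum for `l`
#' terminals.
#'
#' @param g undirected igraph (PPI layer).
#' @param terminals character vector of terminal (seed) protein ids.
#' @param order permutation of `terminals` controlling insertion order
#'   (default: as given).
#' @param weights numeric edge weights aligned with `E(g)` (default: unit).
#' @return list with `nodes` (character), `edges` (data frame
#'   source/target), `cost` (sum of tree edge weights).
#' @export
steiner_tree_approx <- function(g, terminals, order = terminals,
                                weights = NULL) {
  terminals <- unique(as.character(terminals))
  stopifnot(setequal(order, terminals))
  order <- as.character(order)
  missing <- setdiff(terminals, igraph::V(g)$name)
  if (length(missing))
    stop("terminal(s) not in graph: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(weights)) weights <- rep(1, igraph::ecount(g))

  comp <- igraph::components(g)$membership
  unreachable <- terminals[comp[terminals] != comp[order[1L]]]
  if (length(unreachable))
    stop("connectivity error: terminal(s) unreachable from ", order[1L],
         ": ", paste(unreachable, collapse = ", "), call. = FALSE)

  tree_nodes <- order[1L]
  tree_edges <- data.frame(source = character(), target = character(),
                           stringsAsFactors = FALSE)
  remaining <- setdiff(order, tree_nodes)
  while (length(remaining)) {
    d <- igraph::distances(g, v = tree_nodes, to = remaining,
                           weights = weights)
    # nearest terminal; ties resolved by insertion order, then by sorted
    # tree-node id
    dmin <- apply(d, 2L, min)
    term <- remaining[dmin == min(dmin)][1L]  # ties: earliest in order
    srcs <- tree_nodes[d[, term] == min(d[, term])]
    src <- sort(srcs)[1L]
    vp <- igraph::shortest_paths(g, from = src, to = term,
                                 weights = weights, output = "vpath")$vpath[[1L]]
    path <- igraph::V(g)$name[vp]
    # attach only the suffix beyond the last tree node on the path
    idx <- max(which(path %in% tree_nodes))
    for (j in seq(idx, length(path) - 1L)) {
      tree_edges <- rbind(tree_edges,
                          data.frame(source = path[j], target = path[j + 1L],
                                     stringsAsFactors = FALSE))
    }
    tree_nodes <- union(tree_nodes, path[idx:length(path)])
    remaining <- setdiff(remaining, term)
  }

  # prune non-terminal leaves
  repeat {
    if (!nrow(tree_edges)) break
    degs <- table(c(tree_edges$source, tree_edges$target))
    leaves <- names(degs)[degs == 1L]
    drop <- setdiff(leaves, terminals)
    if (!length(drop)) break
    keep <- !(tree_edges$source %in% drop | tree_edges$target %in% drop)
    tree_edges <- tree_edges[keep, , drop = FALSE]
    tree_nodes <- setdiff(tree_nodes, drop)
  }
  rownames(tree_edges) <- NULL

  cost <- if (nrow(tree_edges)) {
    eid <- igraph::get_edge_ids(g, t(as.matrix(tree_edges)))
    sum(weights[eid])
  } else 0
  list(nodes = sort(tree_nodes), edges = tree_edges, cost = cost)
}

#' Multi-Steiner-Trees disease module
#'
#' Builds `n_trees` approximate Steiner trees over the seed proteins, each
#' under a distinct random terminal-insertion order drawn from a seeded,
#' per-tree-index RNG stream, keeps every tree whose cost is within
#' `tolerance` of the best cost found so far, and returns the union of
#' their nodes together with the full induced PPI subgraph.
#'
#' Seeds falling in different connected components are handled
#' per-component with a warning; the result then has one submodule per
#' component (`n_components > 1`).
#'
#' @param net a [hetnet()] (gene seeds are mapped to proteins first) or a
#'   PPI igraph.
#' @param seeds a [seed_set()] or character vector (at least 2 after
#'   mapping).
#' @param n_trees number of trees to aggregate (default 10).
#' @param hub_penalty lambda in `[0, 1]` (default 0 = off); see
#'   [hub_penalized_weight()].
#' @param tolerance extra cost allowed for accepted alternative trees
#'   (default 0).
#' @param random_seed RNG seed for terminal orders (default 1).
#' @param experimental_only restrict the PPI layer to experimental evidence
#'   (default `TRUE`).
#' @return a [disease_module()]; `provenance$tree_costs` records the cost
#'   of every constructed tree.
#' @export
must <- function(net, seeds, n_trees = 10, hub_penalty = 0, tolerance = 0,
                 random_seed = 1, experimental_only = TRUE) {
  stopifnot(n_trees >= 1)
  check_lambda(hub_penalty)
  if (inherits(net, "hetnet")) {
    kinds <- node_kind(net, check_seeds(net, seeds))
    if (any(kinds == "gene")) seeds <- map_seeds_to_proteins(net, seeds)
    g <- ppi_igraph(net, experimental_only)
  } else g <- net
  seeds <- unique(as.character(seeds))
  missing <- setdiff(seeds, igraph::V(g)$name)
  if (length(missing))
    stop("seed protein(s) not on the PPI layer: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(seeds) < 2L)
    stop("seed error: MuST needs at least 2 seed proteins", call. = FALSE)

  w <- hub_weights(g, hub_penalty)
  comp <- igraph::components(g)$membership
  groups <- split(seeds, comp[seeds])
  if (length(groups) > 1L)
    warning("seeds span ", length(groups),
            " connected components; building per-component submodules",
            call. = FALSE)

  tree_seeds <- with_rng(random_seed,
                         sample.int(.Machine$integer.max, n_trees))
  members <- character(0)
  costs <- numeric(n_trees)
  best <- Inf
  for (i in seq_len(n_trees)) {
    forest_nodes <- character(0)
    cost <- 0
    with_rng(tree_seeds[i], {
      for (terms in groups) {
        if (length(terms) < 2L) {
          forest_nodes <- union(forest_nodes, terms)
          next
        }
        ord <- sample(sort(terms))
        tr <- steiner_tree_approx(g, terms, order = ord, weights = w)
        forest_nodes <- union(forest_nodes, tr$nodes)
        cost <- cost + tr$cost
      }
    })
    costs[i] <- cost
    best <- min(best, cost)
    if (cost <= best + tolerance) members <- union(members, forest_nodes)
  }

  disease_module(sort(members), seeds = seeds, ppi = g,
                 provenance = list(algorithm = "must",
                                   n_trees = n_trees,
                                   hub_penalty = hub_penalty,
                                   tolerance = tolerance,
                                   random_seed = random_seed,
                                   tree_costs = costs))
}
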