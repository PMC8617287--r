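# DIAMOnD: greedy module expansion by hypergeometric connectivity
# significance.

#' Connectivity significance of a candidate node
#'
#' Hypergeometric tail probability that a node of degree `k` has at least
#' `ks` of its neighbors inside a module of size `s0` drawn from a network
#' of `N` nodes:
#' `p = sum_{j = ks..min(k, s0)} C(s0, j) C(N - s0, k - j) / C(N, k)`.
#'
#' With a seed weight `alpha > 1`, links to seed members (`k_seed`) and the
#' seed content of the module are counted `alpha`-fold before the tail is
#' evaluated, following the weighting of the original greedy-expansion
#' algorithm.
#'
#' @param N network node count.
#' @param s0 current module size.
#' @param k candidate degree.
#' @param ks candidate links into the module.
#' @param alpha integer seed weight (default 1 = unweighted).
#' @param k_seed candidate links to seed members (used only when
#'   `alpha > 1`).
#' @param n_seeds seed members currently in the module (used only when
#'   `alpha > 1`).
#' @return tail probability in `(0, 1]`; `ks = 0` gives exactly 1. Computed
#'   via [stats::phyper()] in stable log-tail form.
#' @export
connectivity_pvalue <- function(N, s0, k, ks, alpha = 1, k_seed = 0,
                                n_seeds = 0) {
  if (any(ks > k))
    stop("parameter error: ks cannot exceed the candidate degree k",
         call. = FALSE)
  if (any(ks < 0 | k < 0 | s0 < 0 | N < 1))
    stop("parameter error: negative counts", call. = FALSE)
  if (alpha != 1) {
    k <- k + (alpha - 1) * k_seed
    ks <- ks + (alpha - 1) * k_seed
    s0 <- s0 + (alpha - 1) * n_seeds
    N <- N + (alpha - 1) * n_seeds
  }
  if (any(ks > pmin(k, s0)))
    stop("parameter error: ks exceeds min(k, s0) after weighting",
         call. = FALSE)
  p <- stats::phyper(ks - 1, s0, N - s0, k, lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' DIAMOnD greedy disease-module expansion
#'
#' Iteratively evaluates every non-member node adjacent to the current
#' module, adds the node with the smallest connectivity significance
#' ([connectivity_pvalue()]), and repeats with the enlarged module until
#' `n_added` nodes were added or no candidate remains. Significances are
#' recomputed from scratch at every iteration. The returned module is not
#' necessarily connected.
#'
#' Ties are broken deterministically: smaller p, then more links into the
#' module (`ks`), then smaller degree (`k`), then lexicographic id.
#'
#' @param net a [hetnet()] (gene seeds are mapped to proteins) or a PPI
#'   igraph.
#' @param seeds a [seed_set()] or character vector of seed proteins.
#' @param n_added number of nodes to add (>= 0).
#' @param alpha integer seed weight (default 1).
#' @param experimental_only restrict the PPI layer to experimental evidence
#'   (default `TRUE`).
#' @return a [disease_module()] whose `added` field is a data frame
#'   (`node`, `k`, `ks`, `p`) in addition order.
#' @export
diamond <- function(net, seeds, n_added, alpha = 1,
                    experimental_only = TRUE) {
  stopifnot(n_added >= 0, alpha >= 1)
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
  if (all(igraph::degree(g, seeds) == 0))
    stop("isolation error: no seed has any PPI edge", call. = FALSE)

  N <- igraph::vcount(g)
  deg <- igraph::degree(g)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  nm <- igraph::V(g)$name
  adj <- lapply(adj, function(v) nm[as.integer(v)])
  names(adj) <- nm

  members <- seeds
  added <- data.frame(node = character(), k = numeric(), ks = numeric(),
                      p = numeric(), stringsAsFactors = FALSE)
  for (iter in seq_len(n_added)) {
    cand <- setdiff(unique(unlist(adj[members], use.names = FALSE)), members)
    if (!length(cand)) break
    ks <- vapply(adj[cand], function(nb) sum(nb %in% members), numeric(1))
    k <- deg[cand]
    if (alpha == 1) {
      p <- connectivity_pvalue(N, length(members), k, ks)
    } else {
      kseed <- vapply(adj[cand], function(nb) sum(nb %in% seeds), numeric(1))
      p <- connectivity_pvalue(N, length(members), k, ks, alpha = alpha,
                               k_seed = kseed,
                               n_seeds = sum(seeds %in% members))
    }
    ord <- order(p, -ks, k, cand)[1L]
    added <- rbind(added, data.frame(node = cand[ord], k = unname(k[ord]),
                                     ks = unname(ks[ord]), p = unname(p[ord]),
                                     stringsAsFactors = FALSE))
    members <- c(members, cand[ord])
  }
  rownames(added) <- NULL

  disease_module(members, seeds = seeds, ppi = g,
                 provenance = list(algorithm = "diamond", n_added = n_added,
                                   alpha = alpha),
                 added = added)
}
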