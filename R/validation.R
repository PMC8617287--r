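# Permutation-based empirical p-values for ranked drug lists (DCG /
# overlap), disease modules (precision / intersection against
# topology-matched mock modules), joint module + ranking validation, and
# the hypergeometric gene-set overlap test.

#' Discounted cumulative gain of a ranked drug list
#'
#' `DCG = sum_i d_i / log2(i + 1)` where `d_i = 1` if the i-th drug is in
#' the reference set, 0 otherwise.
#'
#' @param ranked_ids ordered, duplicate-free character vector of drug ids.
#' @param reference character vector of reference (e.g. indicated) drugs.
#' @return the DCG (numeric scalar).
#' @export
dcg <- function(ranked_ids, reference) {
  ranked_ids <- as.character(ranked_ids)
  if (anyDuplicated(ranked_ids))
    stop("input error: ranked list contains duplicates", call. = FALSE)
  if (!length(ranked_ids)) return(0)
  hits <- ranked_ids %in% reference
  sum(hits / log2(seq_along(ranked_ids) + 1))
}

# internal: empirical result container
empirical_result <- function(observed, n, r, mode, random_seed) {
  p <- r / n
  reported <- if (r == 0) paste0("< ", format(1 / n, scientific = FALSE))
  else paste0("= ", format(p, scientific = FALSE))
  structure(list(statistic_observed = observed, n_permutations = n,
                 n_exceeding = r, p = p, reported = reported, mode = mode,
                 random_seed = random_seed),
            class = "empirical_result")
}

#' @export
print.empirical_result <- function(x, ...) {
  cat("<empirical_result> mode=", x$mode,
      "  observed=", format(x$statistic_observed),
      "  P ", x$reported, "  (", x$n_exceeding, "/", x$n_permutations,
      " null draws exceed)\n", sep = "")
  invisible(x)
}

#' Empirical validation of a ranked drug list
#'
#' Draws `n_permutations` random ordered drug lists of the same length
#' from `pool` and counts how many achieve a statistic (DCG or overlap with
#' the reference) strictly greater than the observed list's.
#'
#' @param ranked a `ranked_drugs` data frame or ordered character vector.
#' @param reference character vector of reference drugs (non-empty).
#' @param pool drug ids to sample null lists from; defaults to all drug
#'   nodes of `net` if given.
#' @param net optional [hetnet()] supplying the default pool.
#' @param n_permutations number of null lists (default 1000).
#' @param mode `"dcg"` (rank-aware, default) or `"overlap"`.
#' @param random_seed RNG seed (default 1).
#' @param strict count only strictly greater null statistics (default
#'   `TRUE`, the literal exceedance rule); `FALSE` counts ties too.
#' @return an `empirical_result`: observed statistic, `n_exceeding` (r),
#'   `p = r/n`, and the reporting string (`"< 1/n"` when r = 0).
#' @export
validate_drug_list <- function(ranked, reference, pool = NULL, net = NULL,
                               n_permutations = 1000,
                               mode = c("dcg", "overlap"), random_seed = 1,
                               strict = TRUE) {
  mode <- match.arg(mode)
  ids <- if (inherits(ranked, "data.frame")) ranked$drug else
    as.character(ranked)
  if (anyDuplicated(ids))
    stop("input error: ranked list contains duplicates", call. = FALSE)
  reference <- unique(as.character(reference))
  if (!length(reference)) stop("reference drug list is empty", call. = FALSE)
  if (is.null(pool)) {
    if (is.null(net)) stop("supply either pool or net", call. = FALSE)
    pool <- net$nodes$id[net$nodes$kind == "drug"]
  }
  pool <- unique(as.character(pool))
  if (length(ids) > length(pool))
    stop("sampling error: pool (", length(pool),
         ") smaller than ranked list (", length(ids), ")", call. = FALSE)
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)

  stat <- function(x) if (mode == "dcg") dcg(x, reference) else
    sum(x %in% reference)
  observed <- stat(ids)
  m <- length(ids)
  r <- with_rng(random_seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      s <- stat(sample(pool, m))
      if (strict) s > observed else s >= observed
    }, logical(1)))
  })
  empirical_result(observed, n_permutations, r, mode, random_seed)
}

#' Sample a mock module matched to component sizes
#'
#' Draws a random module whose component sizes match `component_sizes`
#' exactly: each component grows from a uniformly chosen start node by
#' repeatedly adding a uniformly chosen boundary neighbor; grown components
#' are kept at graph distance >= 2 from one another so the induced
#' subgraph's component structure matches the request. Dead ends trigger a
#' retry (up to `max_retries` per component).
#'
#' @param net a [hetnet()] or PPI igraph.
#' @param component_sizes positive integers, e.g.
#'   [module_component_sizes()] of an observed module.
#' @param random_seed optional RNG seed; `NULL` uses the current stream.
#' @param max_retries retries per component (default 100).
#' @return a [disease_module()] with empty seed set.
#' @export
sample_mock_module <- function(net, component_sizes, random_seed = NULL,
                               max_retries = 100) {
  g <- ppi_igraph(net)
  sizes <- as.integer(component_sizes)
  if (any(sizes < 1)) stop("component sizes must be >= 1", call. = FALSE)
  adj <- adj_list(g)
  members <- if (is.null(random_seed)) draw_mock(adj, sizes, max_retries)
  else with_rng(random_seed, draw_mock(adj, sizes, max_retries))
  disease_module(members, seeds = character(0), ppi = g,
                 provenance = list(algorithm = "mock",
                                   component_sizes = sizes,
                                   random_seed = random_seed))
}

# internal: named adjacency list of an igraph
adj_list <- function(g) {
  nm <- igraph::V(g)$name
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  adj <- lapply(adj, function(v) nm[as.integer(v)])
  names(adj) <- nm
  adj
}

# internal: one mock-module member draw from a precomputed adjacency list
draw_mock <- function(adj, sizes, max_retries = 100) {
  nm <- names(adj)
  blocked <- character(0)
  comps <- vector("list", length(sizes))
  for (ci in seq_along(sizes)) {
    size <- sizes[ci]
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      avail <- setdiff(nm, blocked)
      if (!length(avail)) break
      s <- sample(avail, 1L)
      grown <- s
      while (length(grown) < size) {
        boundary <- setdiff(unique(unlist(adj[grown], use.names = FALSE)),
                            c(grown, blocked))
        if (!length(boundary)) break
        grown <- c(grown, sample(boundary, 1L))
      }
      if (length(grown) == size) { ok <- TRUE; break }
    }
    if (!ok)
      stop("sampling error: could not grow a connected component of size ",
           size, " after ", max_retries, " retries", call. = FALSE)
    comps[[ci]] <- grown
    # block the component and its neighborhood so later components cannot
    # attach to it
    blocked <- union(blocked,
                     union(grown, unlist(adj[grown], use.names = FALSE)))
  }
  unlist(comps)
}

#' Precision or intersection of a module against reference drugs
#'
#' `precision` = (reference drugs targeting the module) / (all drugs
#' targeting the module), 0 when nothing targets it; `intersection` = the
#' raw count of reference drugs targeting the module.
#'
#' @param module a [disease_module()].
#' @param net the [hetnet()].
#' @param reference character vector of reference drugs.
#' @param mode `"precision"` (default) or `"intersection"`.
#' @return numeric scalar.
#' @export
module_precision <- function(module, net, reference,
                             mode = c("precision", "intersection")) {
  mode <- match.arg(mode)
  targeting <- drugs_targeting(net, module$members)
  hits <- length(intersect(targeting, reference))
  if (mode == "intersection") return(hits)
  if (!length(targeting)) return(0)
  hits / length(targeting)
}

#' Empirical validation of a disease module
#'
#' Samples `n_permutations` mock modules matched to the observed module's
#' size and component count ([sample_mock_module()]) and counts mock
#' modules whose precision (or intersection) strictly exceeds the observed
#' one.
#'
#' @inheritParams module_precision
#' @param n_permutations number of mock modules (default 1000).
#' @param random_seed RNG seed (default 1).
#' @param strict strictly-greater exceedance (default `TRUE`).
#' @return an `empirical_result`.
#' @export
validate_module <- function(module, net, reference,
                            n_permutations = 1000,
                            mode = c("precision", "intersection"),
                            random_seed = 1, strict = TRUE) {
  mode <- match.arg(mode)
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  observed <- module_precision(module, net, reference, mode)
  sizes <- module_component_sizes(module)
  adj <- adj_list(ppi_igraph(net))
  stat_members <- function(members) {
    targeting <- drugs_targeting(net, members)
    hits <- length(intersect(targeting, reference))
    if (mode == "intersection") hits
    else if (!length(targeting)) 0 else hits / length(targeting)
  }
  r <- with_rng(random_seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      s <- stat_members(draw_mock(adj, sizes))
      if (strict) s > observed else s >= observed
    }, logical(1)))
  })
  empirical_result(observed, n_permutations, r, mode, random_seed)
}

#' Joint empirical validation of a module and its drug ranking
#'
#' Runs the full ranking step with the observed module's members as seeds,
#' scores the resulting list by its precision (reference drugs in the list
#' / list length) or intersection, and compares against the same pipeline
#' applied to topology-matched mock modules.
#'
#' @inheritParams validate_module
#' @param ranking a function `(net, seeds) -> ranked_drugs` (e.g. a wrapper
#'   around [trustrank()] or [closeness_ranking()]).
#' @param top_k optionally truncate every ranked list to its first `top_k`
#'   entries before scoring.
#' @return an `empirical_result`.
#' @export
validate_joint <- function(module, net, reference, ranking,
                           n_permutations = 1000,
                           mode = c("precision", "intersection"),
                           random_seed = 1, top_k = NULL, strict = TRUE) {
  mode <- match.arg(mode)
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  score_list <- function(members) {
    lst <- ranking(net, members)
    ids <- if (inherits(lst, "data.frame")) lst$drug else as.character(lst)
    if (!is.null(top_k)) ids <- utils::head(ids, top_k)
    hits <- length(intersect(ids, reference))
    if (mode == "intersection") hits
    else if (!length(ids)) 0 else hits / length(ids)
  }
  observed <- score_list(module$members)
  sizes <- module_component_sizes(module)
  adj <- adj_list(ppi_igraph(net))
  r <- with_rng(random_seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      s <- score_list(draw_mock(adj, sizes))
      if (strict) s > observed else s >= observed
    }, logical(1)))
  })
  empirical_result(observed, n_permutations, r, paste0("joint_", mode),
                   random_seed)
}

#' Hypergeometric test for the overlap of two gene sets
#'
#' Upper tail `P(X >= |A intersect B|)` for `X` hypergeometric with
#' population `universe`, `|A|` successes and `|B|` draws.
#'
#' @param setA,setB character vectors of gene ids from a common universe.
#' @param universe universe size `N` (e.g. number of gene nodes in the
#'   network); must be at least `|A union B|`.
#' @return the overlap p-value.
#' @export
hypergeom_overlap_test <- function(setA, setB, universe) {
  setA <- unique(as.character(setA)); setB <- unique(as.character(setB))
  if (universe < length(setA) || universe < length(setB))
    stop("universe smaller than a gene set", call. = FALSE)
  ov <- length(intersect(setA, setB))
  stats::phyper(ov - 1, length(setA), universe - length(setA), length(setB),
                lower.tail = FALSE)
}

#' Write an empirical validation result as JSON
#'
#' @param result an `empirical_result` (or named list of them).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(result, path) {
  unpack <- function(x) x[c("statistic_observed", "n_permutations",
                            "n_exceeding", "p", "reported", "mode",
                            "random_seed")]
  payload <- if (inherits(result, "empirical_result")) unpack(result)
  else lapply(result, unpack)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
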