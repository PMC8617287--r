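# Drug prioritization on the combined protein-protein + drug-target graph:
# TrustRank (seed-personalized PageRank variant) and seed-restricted
# closeness.

#' Build the drug-ranking graph
#'
#' Undirected, unit-weight union of the experimental ppi edges and the
#' drug_target edges; genes and diseases never enter.
#'
#' @param net a [hetnet()].
#' @param approved_only drop drugs whose `groups` attribute lacks
#'   `"approved"` (default `FALSE`).
#' @return an undirected igraph over protein and drug nodes, with vertex
#'   attribute `kind`.
#' @export
ranking_graph <- function(net, approved_only = FALSE) {
  keep_drugs <- net$nodes$id[net$nodes$kind == "drug"]
  if (approved_only) keep_drugs <- approved_drugs(net)
  nodes <- net$nodes[net$nodes$kind == "protein" |
                       net$nodes$id %in% keep_drugs, , drop = FALSE]
  ppi <- net$edges[net$edges$kind == "ppi", , drop = FALSE]
  if (nrow(ppi)) {
    ev <- if ("evidence" %in% names(ppi)) ppi$evidence else
      rep(NA_character_, nrow(ppi))
    ppi <- ppi[!is.na(ev) & ev == "experimental", , drop = FALSE]
  }
  dt <- net$edges[net$edges$kind == "drug_target" &
                    net$edges$source %in% nodes$id, , drop = FALSE]
  edf <- rbind(ppi[, c("source", "target")], dt[, c("source", "target")])
  igraph::graph_from_data_frame(
    data.frame(from = edf$source, to = edf$target, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes$id, kind = nodes$kind,
                          stringsAsFactors = FALSE))
}

# internal: assemble a ranked_drugs object from named scores
ranked_drugs <- function(scores, algorithm, params, seeds) {
  scores <- scores[scores > 0]
  if (length(scores)) {
    ord <- order(-scores, names(scores))
    scores <- scores[ord]
  }
  structure(data.frame(rank = seq_along(scores),
                       drug = names(scores) %||% character(0),
                       score = unname(scores),
                       stringsAsFactors = FALSE),
            algorithm = algorithm, params = params,
            seeds_used = as.character(seeds),
            class = c("ranked_drugs", "data.frame"))
}

#' Candidate drugs for ranking
#'
#' Direct mode (`include_indirect = FALSE`): drugs with at least one
#' `drug_target` edge to a seed protein. Indirect mode: every drug in the
#' same connected component of the ranking graph as some seed — exactly the
#' drugs that can receive a nonzero ranking score.
#'
#' @param net a [hetnet()].
#' @param seeds character vector of seed protein ids.
#' @param include_indirect flag (default `FALSE`).
#' @param approved_only restrict to approved drugs (default `FALSE`).
#' @return sorted character vector of drug ids.
#' @export
candidate_drugs <- function(net, seeds, include_indirect = FALSE,
                            approved_only = FALSE) {
  seeds <- as.character(seeds)
  if (!include_indirect) {
    dt <- net$edges[net$edges$kind == "drug_target" &
                      net$edges$target %in% seeds, , drop = FALSE]
    drugs <- unique(dt$source)
    if (approved_only) drugs <- intersect(drugs, approved_drugs(net))
    return(sort(drugs))
  }
  rg <- ranking_graph(net, approved_only)
  seeds_in <- intersect(seeds, igraph::V(rg)$name)
  if (!length(seeds_in)) return(character(0))
  comp <- igraph::components(rg)$membership
  reach <- names(comp)[comp %in% unique(comp[seeds_in])]
  sort(intersect(reach, igraph::V(rg)$name[igraph::V(rg)$kind == "drug"]))
}

#' TrustRank drug prioritization
#'
#' Trust starts uniformly on the seed proteins and is propagated through
#' the ranking graph: the trust vector solves
#' `t = d * W %*% t + (1 - d) * t0`, with `W` the column-normalized
#' adjacency matrix, `t0` uniform over seeds, and the mass of dangling
#' (isolated) columns redistributed to `t0`. Solved by power iteration.
#'
#' @param net a [hetnet()].
#' @param seeds seed proteins (a [seed_set()] or character vector; gene ids
#'   are mapped to proteins first).
#' @param damping d in `[0, 1]` (default 0.85); higher values propagate
#'   trust further from the seeds.
#' @param tolerance L1 convergence threshold (default 1e-6).
#' @param max_iterations iteration cap (default 100); non-convergence
#'   yields a warning and the best iterate.
#' @param approved_only rank approved drugs only (default `FALSE`).
#' @param include_indirect keep drugs that do not directly target a seed
#'   (default `TRUE`).
#' @return a `ranked_drugs` data frame (`rank`, `drug`, `score`), scores
#'   non-increasing, zero-score drugs excluded, ties broken by id.
#' @export
trustrank <- function(net, seeds, damping = 0.85, tolerance = 1e-6,
                      max_iterations = 100, approved_only = FALSE,
                      include_indirect = TRUE) {
  if (damping < 0 || damping > 1)
    stop("damping must lie in [0, 1]", call. = FALSE)
  seeds <- resolve_protein_seeds(net, seeds)
  rg <- ranking_graph(net, approved_only)
  nm <- igraph::V(rg)$name
  seeds_in <- intersect(seeds, nm)
  if (!length(seeds_in))
    stop("seed error: no seed maps into the ranking graph", call. = FALSE)

  A <- igraph::as_adjacency_matrix(rg, sparse = TRUE)
  colsum <- Matrix::colSums(A)
  dangling <- colsum == 0
  inv <- ifelse(dangling, 0, 1 / colsum)
  t0 <- numeric(length(nm)); names(t0) <- nm
  t0[seeds_in] <- 1 / length(seeds_in)

  t <- t0
  converged <- FALSE
  for (i in seq_len(max_iterations)) {
    spread <- as.numeric(A %*% (t * inv))
    lost <- sum(t[dangling])
    t_new <- damping * (spread + lost * t0) + (1 - damping) * t0
    names(t_new) <- nm
    if (sum(abs(t_new - t)) < tolerance) {
      t <- t_new; converged <- TRUE; break
    }
    t <- t_new
  }
  if (!converged && max_iterations > 0 && tolerance > 0)
    warning("TrustRank did not converge in ", max_iterations,
            " iterations; returning last iterate", call. = FALSE)

  drugs <- nm[igraph::V(rg)$kind == "drug"]
  scores <- t[drugs]
  if (!include_indirect) {
    direct <- candidate_drugs(net, seeds, include_indirect = FALSE,
                              approved_only = approved_only)
    scores <- scores[names(scores) %in% direct]
  }
  ranked_drugs(scores, "trustrank",
               list(damping = damping, tolerance = tolerance,
                    max_iterations = max_iterations,
                    approved_only = approved_only,
                    include_indirect = include_indirect),
               seeds_in)
}

#' Seed-restricted closeness drug prioritization
#'
#' Scores each candidate drug by its closeness to the seed proteins alone.
#' The default harmonic variant sums reciprocal unweighted shortest-path
#' distances, `C(v) = sum_s 1 / d(v, s)`, with unreachable seeds
#' contributing 0; the classical variant scores
#' `(number of reachable seeds) / (sum of distances to them)`.
#'
#' @inheritParams trustrank
#' @param include_indirect keep drugs that do not directly target a seed
#'   (default `TRUE`).
#' @param variant `"harmonic"` (default) or `"classical"`.
#' @return a `ranked_drugs` data frame; see [trustrank()].
#' @export
closeness_ranking <- function(net, seeds, approved_only = FALSE,
                              include_indirect = TRUE,
                              variant = c("harmonic", "classical")) {
  variant <- match.arg(variant)
  seeds <- resolve_protein_seeds(net, seeds)
  rg <- ranking_graph(net, approved_only)
  nm <- igraph::V(rg)$name
  seeds_in <- intersect(seeds, nm)
  if (!length(seeds_in))
    stop("seed error: no seed maps into the ranking graph", call. = FALSE)

  drugs <- nm[igraph::V(rg)$kind == "drug"]
  if (!length(drugs))
    return(ranked_drugs(numeric(0), paste0("closeness_", variant),
                        list(approved_only = approved_only,
                             include_indirect = include_indirect,
                             variant = variant), seeds_in))
  d <- igraph::distances(rg, v = drugs, to = seeds_in)
  scores <- if (variant == "harmonic") {
    rowSums(1 / d)  # unreachable seeds: 1/Inf = 0
  } else {
    reach <- rowSums(is.finite(d))
    tot <- rowSums(ifelse(is.finite(d), d, 0))
    ifelse(reach > 0 & tot > 0, reach / tot, 0)
  }
  names(scores) <- drugs
  if (!include_indirect) {
    direct <- candidate_drugs(net, seeds, include_indirect = FALSE,
                              approved_only = approved_only)
    scores <- scores[names(scores) %in% direct]
  }
  ranked_drugs(scores, paste0("closeness_", variant),
               list(approved_only = approved_only,
                    include_indirect = include_indirect, variant = variant),
               seeds_in)
}

# internal: accept seed_set/character of genes or proteins, return proteins
resolve_protein_seeds <- function(net, seeds) {
  if (!inherits(net, "hetnet")) return(unique(as.character(seeds)))
  ids <- check_seeds(net, seeds)
  kinds <- node_kind(net, ids)
  if (any(kinds == "gene")) ids <- map_seeds_to_proteins(net, ids)
  unique(as.character(ids))
}

#' Drop drugs that only target excluded proteins
#'
#' Removes from a ranked list every drug all of whose targets lie inside
#' `exclude` (typically the initial seeds), then renumbers ranks.
#'
#' @param ranked a `ranked_drugs` data frame.
#' @param net the [hetnet()] the ranking was computed on.
#' @param exclude character vector of protein ids.
#' @return the filtered `ranked_drugs`.
#' @export
exclude_seed_targeting <- function(ranked, net, exclude) {
  exclude <- as.character(exclude)
  if (!length(exclude) || !nrow(ranked)) return(ranked)
  dt <- net$edges[net$edges$kind == "drug_target", , drop = FALSE]
  targets <- split(dt$target, dt$source)
  only_excluded <- vapply(ranked$drug, function(d) {
    tg <- targets[[d]]
    length(tg) > 0 && all(tg %in% exclude)
  }, logical(1))
  out <- ranked[!only_excluded, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attributes(out)[c("algorithm", "params", "seeds_used")] <-
    attributes(ranked)[c("algorithm", "params", "seeds_used")]
  class(out) <- class(ranked)
  out
}

#' Write a ranked drug list as TSV
#'
#' Columns: rank, drug, label, score, targets_in_seeds (count of the
#' drug's targets among the seeds used for ranking).
#'
#' @param ranked a `ranked_drugs` data frame.
#' @param net the [hetnet()] (labels and targets).
#' @param path output path.
#' @param top_k optionally truncate to the first `top_k` rows.
#' @return `path`, invisibly.
#' @export
write_ranked_tsv <- function(ranked, net, path, top_k = NULL) {
  tab <- as.data.frame(ranked)
  if (!is.null(top_k)) tab <- utils::head(tab, top_k)
  lab <- stats::setNames(net$nodes$label, net$nodes$id)
  seeds <- attr(ranked, "seeds_used")
  dt <- net$edges[net$edges$kind == "drug_target", , drop = FALSE]
  tab$label <- unname(lab[tab$drug])
  tab$targets_in_seeds <- vapply(tab$drug, function(d)
    sum(dt$target[dt$source == d] %in% seeds), integer(1))
  tab <- tab[, c("rank", "drug", "label", "score", "targets_in_seeds")]
  tab$score <- formatC(tab$score, digits = 12, format = "g")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
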