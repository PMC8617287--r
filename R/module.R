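# DiseaseModule container shared by the module-mining algorithms and the
# validation machinery.

#' Construct a disease module
#'
#' A disease module is a set of proteins on the PPI layer, together with
#' the ppi edges it induces and the seeds it grew from.
#'
#' @param members character vector of protein ids (non-empty).
#' @param seeds subset of `members` flagged as input seeds (may be empty
#'   for mock modules).
#' @param ppi an undirected igraph of the PPI layer (or a [hetnet()]); used
#'   to compute induced edges and component count.
#' @param provenance named list: algorithm name and parameters.
#' @param added optional data frame of nodes added by an iterative
#'   algorithm, in addition order.
#' @return object of class `disease_module` with fields `members`, `seeds`,
#'   `induced_edges`, `n_components`, `provenance`, `added`.
#' @export
disease_module <- function(members, seeds = character(0), ppi,
                           provenance = list(algorithm = "manual"),
                           added = NULL) {
  members <- unique(as.character(members))
  if (!length(members)) stop("module has no members", call. = FALSE)
  seeds <- unique(as.character(seeds))
  if (!all(seeds %in% members))
    stop("seeds must be a subset of module members", call. = FALSE)
  g <- ppi_igraph(ppi)
  present <- intersect(members, igraph::V(g)$name)
  sub <- igraph::induced_subgraph(g, present)
  el <- igraph::as_data_frame(sub, what = "edges")
  induced <- data.frame(source = pmin(el$from, el$to),
                        target = pmax(el$from, el$to),
                        stringsAsFactors = FALSE)
  induced <- induced[order(induced$source, induced$target), , drop = FALSE]
  rownames(induced) <- NULL
  # members absent from the PPI layer count as isolated components
  ncomp <- igraph::count_components(sub) + length(setdiff(members, present))
  structure(list(members = members, seeds = seeds,
                 induced_edges = induced, n_components = ncomp,
                 provenance = provenance, added = added),
            class = "disease_module")
}

#' @export
print.disease_module <- function(x, ...) {
  cat("<disease_module> ", length(x$members), " proteins (",
      length(x$seeds), " seeds), ", nrow(x$induced_edges),
      " induced ppi edges, ", x$n_components, " component(s)\n", sep = "")
  cat("  algorithm:", x$provenance$algorithm %||% "?", "\n")
  invisible(x)
}

#' Sizes of a module's connected components
#'
#' @param module a [disease_module()].
#' @return integer vector of component sizes (decreasing), summing to the
#'   module size.
#' @export
module_component_sizes <- function(module) {
  g <- igraph::graph_from_data_frame(
    module$induced_edges[, c("source", "target")], directed = FALSE,
    vertices = data.frame(name = module$members))
  sort(as.integer(igraph::components(g)$csize), decreasing = TRUE)
}

#' Write a module as TSV
#'
#' Columns: `node`, `is_seed`, `added_rank` (iteration at which an
#' expansion algorithm added the node, `NA` for seeds), `p_value`
#' (connectivity significance at addition, `NA` where not applicable).
#'
#' @param module a [disease_module()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_module_tsv <- function(module, path) {
  tab <- data.frame(node = module$members,
                    is_seed = module$members %in% module$seeds,
                    added_rank = NA_integer_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(module$added) && nrow(module$added)) {
    m <- match(module$added$node, tab$node)
    tab$added_rank[m] <- seq_len(nrow(module$added))
    if ("p" %in% names(module$added)) tab$p_value[m] <- module$added$p
  }
  utils::write.table(format(tab, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a module's induced subnetwork as GraphML
#'
#' @param module a [disease_module()].
#' @param net the [hetnet()] the module was mined from (for node labels).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_module_graphml <- function(module, net, path) {
  nodes <- net$nodes[net$nodes$id %in% module$members, , drop = FALSE]
  nodes$is_seed <- ifelse(nodes$id %in% module$seeds, "true", "false")
  edges <- cbind(module$induced_edges,
                 kind = rep("ppi", nrow(module$induced_edges)))
  write_graphml(hetnet(nodes, edges, validate = FALSE), path)
}

# internal: deterministic scoped RNG — evaluates `code` under set.seed(seed)
# and restores the caller's RNG state afterwards
with_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
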