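# Disease-centric queries and layer projections on a hetnet.

#' Genes associated with a disease
#'
#' Returns all genes with a `gene_disease` edge to the disease, optionally
#' including genes of every descendant disease reached by walking
#' `disease_hierarchy` edges against their child-to-parent direction.
#'
#' @param net a [hetnet()].
#' @param disease a disease node id.
#' @param include_descendants also collect genes of all descendant diseases
#'   (default `FALSE`).
#' @return a [seed_set()] of gene ids, deduplicated and sorted.
#' @export
get_disease_genes <- function(net, disease, include_descendants = FALSE) {
  stopifnot(length(disease) == 1L)
  i <- match(disease, net$nodes$id)
  if (is.na(i) || net$nodes$kind[i] != "disease")
    stop("unknown disease id: ", disease, call. = FALSE)

  targets <- disease
  if (include_descendants) {
    h <- net$edges[net$edges$kind == "disease_hierarchy", , drop = FALSE]
    # child -> parent edges; descendants are reached walking parent -> child
    frontier <- disease
    seen <- disease
    while (length(frontier)) {
      kids <- h$source[h$target %in% frontier]
      frontier <- setdiff(kids, seen)
      seen <- c(seen, frontier)
    }
    targets <- seen
  }
  gd <- net$edges[net$edges$kind == "gene_disease", , drop = FALSE]
  genes <- gd$source[gd$target %in% targets]
  genes <- sort(unique(genes))
  if (!length(genes))
    return(structure(character(0), origin = "disease query",
                     class = c("seed_set", "character")))
  seed_set(genes, origin = "disease query")
}

#' Map gene seeds onto the protein layer
#'
#' Protein ids pass through; gene ids are replaced by all proteins they
#' encode (`gene_protein` edges, possibly many-to-many). Genes encoding no
#' protein are reported via the `dropped` attribute and a warning.
#'
#' @param net a [hetnet()].
#' @param seeds a [seed_set()] or character vector of gene/protein ids.
#' @return a [seed_set()] of protein ids with attribute `dropped` (gene ids
#'   that mapped to nothing).
#' @export
map_seeds_to_proteins <- function(net, seeds) {
  ids <- check_seeds(net, seeds)
  kinds <- node_kind(net, ids)
  if (any(!kinds %in% c("gene", "protein")))
    stop("seeds must be genes or proteins; offending id(s): ",
         paste(ids[!kinds %in% c("gene", "protein")], collapse = ", "),
         call. = FALSE)
  prot <- ids[kinds == "protein"]
  genes <- ids[kinds == "gene"]
  gp <- net$edges[net$edges$kind == "gene_protein", , drop = FALSE]
  mapped <- gp$target[gp$source %in% genes]
  dropped <- setdiff(genes, gp$source)
  if (length(dropped))
    warning(length(dropped), " gene seed(s) encode no protein and were dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "), call. = FALSE)
  out <- unique(c(prot, mapped))
  if (!length(out)) stop("no seeds map to the protein layer", call. = FALSE)
  structure(out, origin = attr(seeds, "origin") %||% "mapped",
            dropped = dropped, class = c("seed_set", "character"))
}

#' Project the protein-protein interaction layer
#'
#' @param net a [hetnet()].
#' @param experimental_only keep only ppi edges with
#'   `evidence == "experimental"` (default `TRUE`, the setting used for all
#'   module-mining and ranking runs). Isolated proteins are retained.
#' @return a [hetnet()] of protein nodes and ppi edges.
#' @export
project_ppi <- function(net, experimental_only = TRUE) {
  nodes <- net$nodes[net$nodes$kind == "protein", , drop = FALSE]
  edges <- net$edges[net$edges$kind == "ppi", , drop = FALSE]
  if (experimental_only && nrow(edges)) {
    ev <- if ("evidence" %in% names(edges)) edges$evidence else
      rep(NA_character_, nrow(edges))
    edges <- edges[!is.na(ev) & ev == "experimental", , drop = FALSE]
  }
  hetnet(nodes, edges, validate = FALSE)
}

# internal: PPI layer as an undirected igraph (all protein nodes, ppi edges)
ppi_igraph <- function(net, experimental_only = TRUE) {
  p <- if (inherits(net, "hetnet")) project_ppi(net, experimental_only) else net
  if (inherits(p, "igraph")) return(p)
  vdf <- data.frame(name = p$nodes$id, stringsAsFactors = FALSE)
  edf <- data.frame(from = p$edges$source, to = p$edges$target,
                    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' Drugs targeting a set of proteins
#'
#' @param net a [hetnet()].
#' @param proteins character vector of protein ids (e.g. module members).
#' @param approved_only keep only drugs whose `groups` attribute contains
#'   `"approved"` (default `FALSE`).
#' @return sorted character vector of drug ids with at least one
#'   `drug_target` edge to a member protein (possibly empty).
#' @export
drugs_targeting <- function(net, proteins, approved_only = FALSE) {
  proteins <- as.character(proteins)
  if (!length(proteins)) stop("protein set is empty", call. = FALSE)
  dt <- net$edges[net$edges$kind == "drug_target", , drop = FALSE]
  drugs <- unique(dt$source[dt$target %in% proteins])
  if (approved_only) drugs <- intersect(drugs, approved_drugs(net))
  sort(drugs)
}

#' Drugs indicated for a disease
#'
#' Reference (indicated) drugs read off the network's `drug_indication`
#' edges, for use as the ground-truth list in validation.
#'
#' @param net a [hetnet()].
#' @param disease a disease node id.
#' @return sorted character vector of drug ids.
#' @export
indicated_drugs <- function(net, disease) {
  i <- match(disease, net$nodes$id)
  if (is.na(i) || net$nodes$kind[i] != "disease")
    stop("unknown disease id: ", disease, call. = FALSE)
  di <- net$edges[net$edges$kind == "drug_indication", , drop = FALSE]
  sort(unique(di$source[di$target == disease]))
}

# internal: ids of approved drugs ("approved" within the comma/;-separated
# groups attribute)
approved_drugs <- function(net) {
  d <- net$nodes[net$nodes$kind == "drug", , drop = FALSE]
  if (!nrow(d)) return(character(0))
  g <- if ("groups" %in% names(d)) d$groups else rep(NA_character_, nrow(d))
  g[is.na(g)] <- ""
  d$id[vapply(strsplit(g, "[,;|[:space:]]+"),
              function(x) "approved" %in% x, logical(1))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
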