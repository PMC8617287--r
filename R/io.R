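# Readers and writers: GraphML (via igraph), TSV node/edge tables, id lists.
#
# GraphML dialect: node/edge attributes as <data> elements keyed by declared
# <key> elements; reserved attribute names "kind", "label", "groups",
# "evidence". Node identity is the "name" vertex attribute when present
# (files written by this package), else the XML node id. Missing attribute
# values and empty strings are interchangeable.

#' Read a heterogeneous network from GraphML
#'
#' @param path path to a GraphML file with a `kind` attribute on every node
#'   and edge.
#' @return a validated [hetnet()]. Unknown attribute keys are preserved
#'   verbatim as extra columns.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # xml2 reports malformed XML with the offending line number
  tryCatch(xml2::read_xml(path),
           error = function(e) stop("GraphML parse error in '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  g <- igraph::read_graph(path, format = "graphml")
  dfs <- igraph::as_data_frame(g, what = "both")
  v <- dfs$vertices; e <- dfs$edges

  if (nrow(v) == 0L) return(hetnet())

  id <- if ("name" %in% names(v)) v$name else v$id
  xmlid <- if ("id" %in% names(v)) v$id else id
  if (!"kind" %in% names(v)) {
    stop("schema error: node(s) missing 'kind' attribute: ",
         paste(utils::head(xmlid, 5L), collapse = ", "), call. = FALSE)
  }
  kind <- as.character(v$kind)
  if (anyNA(kind) || any(kind == ""))
    stop("schema error: node(s) missing 'kind' attribute: ",
         paste(utils::head(xmlid[is.na(kind) | kind == ""], 5L),
               collapse = ", "), call. = FALSE)

  drop_v <- intersect(c("name", "id"), names(v))
  attrs_v <- v[, setdiff(names(v), c(drop_v, "kind")), drop = FALSE]
  nodes <- data.frame(id = id, kind = kind, stringsAsFactors = FALSE)
  for (cl in names(attrs_v)) nodes[[cl]] <- as.character(attrs_v[[cl]])

  if (nrow(e)) {
    if (!"kind" %in% names(e) || anyNA(e$kind) || any(e$kind == ""))
      stop("schema error: edge(s) missing 'kind' attribute", call. = FALSE)
    # igraph resolves endpoints to vertex names already
    name_of <- stats::setNames(id, rownames(v))
    src <- if ("name" %in% names(v)) e$from else name_of[e$from]
    tgt <- if ("name" %in% names(v)) e$to else name_of[e$to]
    edges <- data.frame(source = as.character(src), target = as.character(tgt),
                        kind = as.character(e$kind), stringsAsFactors = FALSE)
    for (cl in setdiff(names(e), c("from", "to", "kind")))
      edges[[cl]] <- as.character(e[[cl]])
  } else {
    edges <- NULL
  }
  hetnet(nodes, edges)
}

#' Write a heterogeneous network to GraphML
#'
#' The output round-trips losslessly through [read_graphml()].
#'
#' @param net a [hetnet()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- hetnet_igraph(net)
  tryCatch(igraph::write_graph(g, path, format = "graphml"),
           error = function(e) stop("cannot write GraphML to '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

# internal: full hetnet as a directed igraph (stored orientation), all
# attributes as character, NA -> ""
hetnet_igraph <- function(net) {
  nodes <- net$nodes; edges <- net$edges
  if (nrow(nodes) == 0L) return(igraph::make_empty_graph(0, directed = TRUE))
  vdf <- data.frame(name = nodes$id, stringsAsFactors = FALSE)
  for (cl in setdiff(names(nodes), "id")) {
    v <- nodes[[cl]]; v[is.na(v)] <- ""
    vdf[[cl]] <- v
  }
  edf <- data.frame(from = edges$source, to = edges$target,
                    stringsAsFactors = FALSE)
  for (cl in setdiff(names(edges), c("source", "target"))) {
    v <- edges[[cl]]; v[is.na(v)] <- ""
    edf[[cl]] <- v
  }
  if (nrow(edf) == 0L)
    igraph::graph_from_data_frame(
      data.frame(from = character(), to = character()),
      directed = TRUE, vertices = vdf)
  else
    igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}

#' Read a heterogeneous network from TSV node and edge tables
#'
#' Tables are UTF-8, tab-separated, with a header row. The node table needs
#' columns `id`, `kind`, and optionally `label` plus attribute columns; the
#' edge table needs `source`, `target`, `kind` plus attribute columns.
#'
#' @param node_table,edge_table file paths.
#' @return a validated [hetnet()], identical to the GraphML representation
#'   of the same content.
#' @export
read_edge_tables <- function(node_table, edge_table) {
  for (p in c(node_table, edge_table))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  nodes <- utils::read.delim(node_table, colClasses = "character",
                             check.names = FALSE, na.strings = NULL)
  edges <- utils::read.delim(edge_table, colClasses = "character",
                             check.names = FALSE, na.strings = NULL)
  hetnet(nodes, edges)
}

#' Write a heterogeneous network as TSV node and edge tables
#'
#' @param net a [hetnet()].
#' @param node_table,edge_table output file paths.
#' @return invisibly, the two paths.
#' @export
write_edge_tables <- function(net, node_table, edge_table) {
  wr <- function(tab, path) {
    for (cl in names(tab)) tab[[cl]][is.na(tab[[cl]])] <- ""
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  wr(net$nodes, node_table)
  wr(net$edges, edge_table)
  invisible(c(node_table, edge_table))
}

#' Read a plain-text id list (seeds or reference drugs)
#'
#' One id per line; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return character vector of ids, in file order, deduplicated.
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  unique(x[x != ""])
}
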