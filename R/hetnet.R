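# Typed heterogeneous network data model.
#
# A hetnet is a pair of data frames: nodes (id, kind, label, attribute
# columns) and edges (source, target, kind, attribute columns). Node kinds
# are gene / protein / drug / disease; edge kinds tie specific endpoint
# kinds together. All edge kinds are undirected except disease_hierarchy,
# which points child -> parent.

NODE_KINDS <- c("gene", "protein", "drug", "disease")

# endpoint kinds per edge kind; first/second give the canonical orientation
# used for storage (undirected kinds are re-oriented on construction)
EDGE_SCHEMA <- list(
  ppi               = c("protein", "protein"),
  drug_target       = c("drug", "protein"),
  gene_disease      = c("gene", "disease"),
  drug_indication   = c("drug", "disease"),
  gene_protein      = c("gene", "protein"),
  disease_hierarchy = c("disease", "disease")
)
EDGE_KINDS <- names(EDGE_SCHEMA)

#' Construct a typed heterogeneous network
#'
#' @param nodes data frame with at least columns `id`, `kind`, `label`
#'   (missing `label` defaults to the id). Extra character columns are kept
#'   as node attributes (e.g. `groups` for drugs, `evidence` never applies
#'   to nodes).
#' @param edges data frame with at least columns `source`, `target`,
#'   `kind`. Extra character columns are kept as edge attributes (e.g.
#'   `evidence` for ppi edges).
#' @param validate check all schema invariants (default `TRUE`).
#'
#' @details Node ids follow the `namespace.identifier` convention
#'   (`entrez.1017`, `uniprot.P51587`, `drugbank.DB00945`, `mondo.0005011`).
#'   Undirected edges are stored in a canonical orientation
#'   (drug→protein, gene→protein, gene→disease, drug→disease; ppi edges
#'   ordered lexicographically); `disease_hierarchy` edges are directed
#'   child→parent and stored as given. Duplicate edges of the same kind on
#'   the same unordered pair collapse to the first occurrence with a
#'   warning.
#'
#' @return an object of class `hetnet`.
#' @export
hetnet <- function(nodes = NULL, edges = NULL, validate = TRUE) {
  nodes <- normalize_node_table(nodes)
  edges <- normalize_edge_table(edges)
  net <- structure(list(nodes = nodes, edges = edges), class = "hetnet")
  if (validate) net <- validate_hetnet(net)
  net
}

normalize_node_table <- function(nodes) {
  if (is.null(nodes) || nrow(as.data.frame(nodes)) == 0L) {
    return(data.frame(id = character(), kind = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  missing <- setdiff(c("id", "kind"), names(nodes))
  if (length(missing))
    stop("node table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"label" %in% names(nodes)) nodes$label <- nodes$id
  nodes$label[is.na(nodes$label) | nodes$label == ""] <- nodes$id[is.na(nodes$label) | nodes$label == ""]
  for (cl in names(nodes)) nodes[[cl]] <- as.character(nodes[[cl]])
  front <- c("id", "kind", "label")
  nodes <- nodes[, c(front, setdiff(names(nodes), front)), drop = FALSE]
  rownames(nodes) <- NULL
  nodes
}

normalize_edge_table <- function(edges) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    return(data.frame(source = character(), target = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  missing <- setdiff(c("source", "target", "kind"), names(edges))
  if (length(missing))
    stop("edge table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (cl in names(edges)) edges[[cl]] <- as.character(edges[[cl]])
  front <- c("source", "target", "kind")
  edges <- edges[, c(front, setdiff(names(edges), front)), drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Validate a hetnet against the schema invariants
#'
#' Checks id uniqueness and namespacing, node kinds, endpoint existence and
#' kind compatibility per edge kind, self-loops, and duplicate edges
#' (collapsed with a warning, first occurrence wins). Undirected edges are
#' re-oriented into canonical form.
#'
#' @param net a [hetnet()].
#' @return the validated (canonicalized) hetnet.
#' @export
validate_hetnet <- function(net) {
  nodes <- net$nodes; edges <- net$edges

  if (anyDuplicated(nodes$id))
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "),
         call. = FALSE)
  bad_ns <- nodes$id[!grepl("^[a-z][a-z0-9]*\\..+$", nodes$id)]
  if (length(bad_ns))
    stop("node id(s) lack a lowercase 'namespace.identifier' form: ",
         paste(utils::head(bad_ns, 5L), collapse = ", "), call. = FALSE)
  bad_kind <- nodes$id[!nodes$kind %in% NODE_KINDS]
  if (length(bad_kind))
    stop("schema error: node(s) with illegal kind: ",
         paste(utils::head(bad_kind, 5L), collapse = ", "), call. = FALSE)

  if (nrow(edges)) {
    bad_ek <- !edges$kind %in% EDGE_KINDS
    if (any(bad_ek))
      stop("schema error: illegal edge kind(s): ",
           paste(unique(edges$kind[bad_ek]), collapse = ", "), call. = FALSE)
    missing_ep <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(missing_ep))
      stop("referential error: edge endpoint(s) not in node table: ",
           paste(missing_ep, collapse = ", "), call. = FALSE)
    if (any(edges$source == edges$target))
      stop("schema error: self-loop on node ",
           edges$source[edges$source == edges$target][1L], call. = FALSE)

    kind_of <- stats::setNames(nodes$kind, nodes$id)
    sk <- kind_of[edges$source]; tk <- kind_of[edges$target]
    for (i in seq_len(nrow(edges))) {
      want <- EDGE_SCHEMA[[edges$kind[i]]]
      ok <- if (edges$kind[i] == "disease_hierarchy") {
        sk[i] == want[1L] && tk[i] == want[2L]
      } else {
        (sk[i] == want[1L] && tk[i] == want[2L]) ||
          (sk[i] == want[2L] && tk[i] == want[1L])
      }
      if (!ok)
        stop("schema error: edge ", edges$source[i], " -- ", edges$target[i],
             " of kind '", edges$kind[i], "' joins ", sk[i], " and ", tk[i],
             call. = FALSE)
    }

    # canonical orientation for undirected kinds
    flip <- logical(nrow(edges))
    for (i in seq_len(nrow(edges))) {
      k <- edges$kind[i]
      if (k == "disease_hierarchy") next
      want <- EDGE_SCHEMA[[k]]
      if (k == "ppi") {
        flip[i] <- edges$source[i] > edges$target[i]
      } else if (sk[i] != want[1L]) {
        flip[i] <- TRUE
      }
    }
    if (any(flip)) {
      tmp <- edges$source[flip]
      edges$source[flip] <- edges$target[flip]
      edges$target[flip] <- tmp
    }

    key <- paste(edges$kind,
                 pmin(edges$source, edges$target),
                 pmax(edges$source, edges$target), sep = "\r")
    # directed hierarchy edges: the unordered pair still keys uniqueness
    dup <- duplicated(key)
    if (any(dup)) {
      warning(sum(dup), " duplicate edge(s) collapsed (first occurrence kept)",
              call. = FALSE)
      edges <- edges[!dup, , drop = FALSE]
      rownames(edges) <- NULL
    }
  }

  structure(list(nodes = nodes, edges = edges), class = "hetnet")
}

#' @export
print.hetnet <- function(x, ...) {
  cat("<hetnet> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges\n",
      sep = "")
  if (nrow(x$nodes)) {
    nk <- table(x$nodes$kind)
    cat("  nodes:", paste(names(nk), nk, sep = "=", collapse = ", "), "\n")
  }
  if (nrow(x$edges)) {
    ek <- table(x$edges$kind)
    cat("  edges:", paste(names(ek), ek, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare two hetnets for semantic equality
#'
#' Node and edge multisets (including all attribute columns) must agree;
#' row order and column order are ignored. Missing attributes (`NA`) and
#' empty strings are treated as equal, matching the GraphML dialect.
#'
#' @param a,b hetnets.
#' @return `TRUE` or `FALSE`.
#' @export
hetnet_equal <- function(a, b) {
  norm_tab <- function(tab, keycols) {
    for (cl in names(tab)) {
      v <- tab[[cl]]
      v[is.na(v)] <- ""
      tab[[cl]] <- v
    }
    tab <- tab[, order(names(tab)), drop = FALSE]
    # drop attribute columns that are entirely empty
    keep <- vapply(names(tab), function(cl)
      cl %in% keycols || any(tab[[cl]] != ""), logical(1))
    tab <- tab[, keep, drop = FALSE]
    if (nrow(tab))
      tab <- tab[do.call(order, tab), , drop = FALSE]
    rownames(tab) <- NULL
    tab
  }
  identical(norm_tab(a$nodes, c("id", "kind", "label")),
            norm_tab(b$nodes, c("id", "kind", "label"))) &&
    identical(norm_tab(a$edges, c("source", "target", "kind")),
              norm_tab(b$edges, c("source", "target", "kind")))
}

#' Seed set constructor
#'
#' A seed set is an ordered, deduplicated character vector of node ids with
#' a provenance tag.
#'
#' @param ids character vector of node ids (genes and/or proteins).
#' @param origin free-text provenance, e.g. `"disease query"`,
#'   `"user file"`, `"module"`.
#' @return character vector of class `seed_set` with attribute `origin`.
#' @export
seed_set <- function(ids, origin = "user") {
  ids <- unique(as.character(ids))
  if (!length(ids)) stop("seed set is empty", call. = FALSE)
  structure(ids, origin = origin, class = c("seed_set", "character"))
}

#' @export
print.seed_set <- function(x, ...) {
  cat("<seed_set> ", length(x), " ids (origin: ", attr(x, "origin"), ")\n",
      sep = "")
  print(unclass(x)[seq_len(min(10L, length(x)))])
  invisible(x)
}

# internal: check seeds exist in a network, return plain character
check_seeds <- function(net, seeds) {
  ids <- unique(as.character(seeds))
  missing <- setdiff(ids, net$nodes$id)
  if (length(missing))
    stop("seed id(s) not present in network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ids
}

# internal: node kinds lookup
node_kind <- function(net, ids) {
  stats::setNames(net$nodes$kind, net$nodes$id)[ids]
}
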