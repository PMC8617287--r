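# Synthetic benchmark networks with planted ground truth: a scale-free
# interactome, a planted (locally densified) connected disease module with
# disease-associated seed genes, true drugs targeting the module and
# decoy drugs targeting the rest of the network.

#' Benchmark generator configuration
#'
#' @param n_proteins proteins in the interactome (default 1000).
#' @param attachment edges each new node brings during preferential
#'   attachment growth (default 2).
#' @param module_size planted module size (default 20).
#' @param module_density probability of adding an extra intra-module ppi
#'   edge between each non-adjacent member pair (default 0.1); gives the
#'   planted module the local cohesion that defines a disease module.
#' @param seed_fraction fraction of module genes flagged as
#'   disease-associated (default 0.5). Seeds are sampled as a spread
#'   within the module (preferring members not adjacent to an already
#'   chosen seed), emulating disease genes scattered across their module.
#' @param n_true_drugs approved drugs targeting the module, with an
#'   indication edge to the disease (default 10).
#' @param n_decoy_drugs approved drugs targeting proteins outside the
#'   module (default 50).
#' @param targets_per_drug protein targets per drug (default 3).
#' @param random_seed RNG seed (default 1).
#' @return a list of class `benchmark_config`.
#' @export
benchmark_config <- function(n_proteins = 1000, attachment = 2,
                             module_size = 20, module_density = 0.1,
                             seed_fraction = 0.5, n_true_drugs = 10,
                             n_decoy_drugs = 50, targets_per_drug = 3,
                             random_seed = 1) {
  stopifnot(module_size <= n_proteins, seed_fraction > 0, seed_fraction <= 1,
            attachment >= 1, module_density >= 0, module_density <= 1)
  structure(as.list(environment()), class = "benchmark_config")
}

protein_id <- function(i) sprintf("uniprot.SYNP%05d", i)
gene_id <- function(i) sprintf("entrez.9%06d", i)
drug_id <- function(i) sprintf("drugbank.SYND%04d", i)

#' Generate a synthetic interactome
#'
#' Connected scale-free protein graph (preferential attachment growth, so
#' the degree distribution is heavy-tailed like a real interactome), with
#' experimental ppi edges and a one-to-one gene for every protein linked by
#' `gene_protein` edges.
#'
#' @param config a [benchmark_config()].
#' @return a [hetnet()].
#' @export
generate_interactome <- function(config = benchmark_config()) {
  n <- config$n_proteins
  g <- with_rng(config$random_seed,
                igraph::sample_pa(n, m = config$attachment,
                                  directed = FALSE))
  el <- igraph::as_edgelist(g, names = FALSE)
  prot <- protein_id(seq_len(n)); gene <- gene_id(seq_len(n))
  nodes <- rbind(
    data.frame(id = prot, kind = "protein",
               label = sprintf("PROT%d", seq_len(n)),
               stringsAsFactors = FALSE),
    data.frame(id = gene, kind = "gene",
               label = sprintf("GENE%d", seq_len(n)),
               stringsAsFactors = FALSE))
  edges <- rbind(
    data.frame(source = prot[el[, 1L]], target = prot[el[, 2L]],
               kind = "ppi", evidence = "experimental",
               stringsAsFactors = FALSE),
    data.frame(source = gene, target = prot, kind = "gene_protein",
               evidence = NA_character_, stringsAsFactors = FALSE))
  hetnet(nodes, edges)
}

#' Plant a disease module into an interactome
#'
#' Grows a connected member set by a boundary random walk, densifies it
#' with extra intra-module ppi edges (probability `module_density` per
#' non-adjacent pair), adds a disease node, and attaches `gene_disease`
#' edges from the genes of a `seed_fraction` sample of members.
#'
#' @param net interactome [hetnet()] from [generate_interactome()].
#' @param config a [benchmark_config()].
#' @return list: `net` (augmented hetnet), `module` ([disease_module()]
#'   whose seeds are the disease-associated member proteins), `disease_id`,
#'   `seed_genes`.
#' @export
plant_module <- function(net, config = benchmark_config()) {
  size <- config$module_size
  res <- with_rng(config$random_seed + 1L, {
    g <- ppi_igraph(net)
    nm <- igraph::V(g)$name
    adj <- igraph::adjacent_vertices(g, igraph::V(g))
    adj <- lapply(adj, function(v) nm[as.integer(v)])
    names(adj) <- nm
    members <- sample(nm, 1L)
    while (length(members) < size) {
      boundary <- setdiff(unique(unlist(adj[members], use.names = FALSE)),
                          members)
      if (!length(boundary)) stop("module growth dead end", call. = FALSE)
      members <- c(members, sample(boundary, 1L))
    }
    extra <- NULL
    if (size >= 2 && config$module_density > 0) {
      pairs <- utils::combn(sort(members), 2L)
      eid <- igraph::get_edge_ids(g, as.vector(pairs))
      absent <- which(eid == 0)
      add <- absent[stats::runif(length(absent)) < config$module_density]
      if (length(add))
        extra <- data.frame(source = pairs[1L, add], target = pairs[2L, add],
                            kind = "ppi", evidence = "experimental",
                            stringsAsFactors = FALSE)
    }
    n_seed <- ceiling(config$seed_fraction * size)
    # spread seed selection: walk the members in random order, flagging a
    # member only if no already-flagged seed is adjacent to it (within the
    # densified module); top up arbitrarily if the spread runs short
    medges <- igraph::as_data_frame(igraph::induced_subgraph(g, members),
                                    what = "edges")
    if (!is.null(extra))
      medges <- rbind(medges,
                      data.frame(from = extra$source, to = extra$target))
    nbr <- split(c(medges$to, medges$from), c(medges$from, medges$to))
    ord <- sample(members)
    seed_prot <- character(0)
    for (m in ord) {
      if (length(seed_prot) >= n_seed) break
      if (!any(nbr[[m]] %in% seed_prot)) seed_prot <- c(seed_prot, m)
    }
    if (length(seed_prot) < n_seed)
      seed_prot <- c(seed_prot,
                     setdiff(ord, seed_prot)[seq_len(n_seed -
                                                       length(seed_prot))])
    seed_prot <- sort(seed_prot)
    list(members = members, extra = extra, seed_prot = seed_prot)
  })

  disease <- "mondo.9000001"
  gp <- net$edges[net$edges$kind == "gene_protein", , drop = FALSE]
  gene_of <- stats::setNames(gp$source, gp$target)
  seed_genes <- unname(gene_of[res$seed_prot])

  dnode <- data.frame(id = disease, kind = "disease",
                      label = "synthetic disease", stringsAsFactors = FALSE)
  dnode <- add_missing_cols(dnode, names(net$nodes))[, names(net$nodes)]
  nodes <- rbind(net$nodes, dnode)
  gd <- data.frame(source = seed_genes, target = disease,
                   kind = "gene_disease", stringsAsFactors = FALSE)
  for (cl in setdiff(names(net$edges), names(gd))) gd[[cl]] <- NA_character_
  edges <- rbind(net$edges, gd[, names(net$edges)])
  if (!is.null(res$extra)) {
    ex <- res$extra
    for (cl in setdiff(names(net$edges), names(ex))) ex[[cl]] <- NA_character_
    edges <- rbind(edges, ex[, names(net$edges)])
  }
  out <- hetnet(nodes, edges)
  module <- disease_module(sort(res$members), seeds = res$seed_prot,
                           ppi = out,
                           provenance = list(algorithm = "planted",
                                             config = unclass(config)))
  list(net = out, module = module, disease_id = disease,
       seed_genes = seed_genes)
}

#' Attach true and decoy drugs to a planted module
#'
#' True drugs are approved, each targets `targets_per_drug` proteins
#' sampled from the module and carries a `drug_indication` edge to the
#' disease; decoys are approved drugs targeting proteins sampled from
#' outside the module only.
#'
#' @param net hetnet with a planted module (from [plant_module()]).
#' @param module the planted [disease_module()].
#' @param disease_id the planted disease node id.
#' @param config a [benchmark_config()].
#' @return list: `net` (augmented), `true_drugs`, `decoy_drugs` (character
#'   vectors of drug ids).
#' @export
attach_drugs <- function(net, module, disease_id,
                         config = benchmark_config()) {
  tpd <- config$targets_per_drug
  if (tpd > length(module$members))
    stop("parameter error: targets_per_drug exceeds module size",
         call. = FALSE)
  outside <- setdiff(net$nodes$id[net$nodes$kind == "protein"],
                     module$members)
  if (tpd > length(outside))
    stop("parameter error: targets_per_drug exceeds non-module proteins",
         call. = FALSE)
  n_true <- config$n_true_drugs; n_decoy <- config$n_decoy_drugs
  ids <- drug_id(seq_len(n_true + n_decoy))
  true_ids <- ids[seq_len(n_true)]
  decoy_ids <- setdiff(ids, true_ids)

  targets <- with_rng(config$random_seed + 2L, {
    c(lapply(seq_len(n_true), function(i) sample(module$members, tpd)),
      lapply(seq_len(n_decoy), function(i) sample(outside, tpd)))
  })

  dn <- data.frame(id = ids, kind = "drug",
                   label = sprintf("DRUG%d", seq_along(ids)),
                   groups = "approved", stringsAsFactors = FALSE)
  for (cl in setdiff(names(net$nodes), names(dn))) dn[[cl]] <- NA_character_
  nodes <- rbind(net$nodes |> add_missing_cols("groups"),
                 dn[, union(names(net$nodes), "groups")])

  dt <- data.frame(source = rep(ids, each = tpd),
                   target = unlist(targets), kind = "drug_target",
                   stringsAsFactors = FALSE)
  di <- data.frame(source = true_ids, target = disease_id,
                   kind = "drug_indication", stringsAsFactors = FALSE)
  de <- rbind(dt, di)
  for (cl in setdiff(names(net$edges), names(de))) de[[cl]] <- NA_character_
  edges <- rbind(net$edges, de[, names(net$edges)])
  list(net = hetnet(nodes, edges), true_drugs = true_ids,
       decoy_drugs = decoy_ids)
}

add_missing_cols <- function(tab, cols) {
  for (cl in setdiff(cols, names(tab))) tab[[cl]] <- NA_character_
  tab
}

#' Generate a full synthetic benchmark
#'
#' Composes [generate_interactome()], [plant_module()] and
#' [attach_drugs()]. Deterministic given `config$random_seed`.
#'
#' @param config a [benchmark_config()].
#' @return a list of class `benchmark`: `net`, `planted_module`,
#'   `disease_id`, `seed_genes`, `true_drugs`, `decoy_drugs`, `config`.
#' @export
generate_benchmark <- function(config = benchmark_config()) {
  inter <- generate_interactome(config)
  planted <- plant_module(inter, config)
  drugged <- attach_drugs(planted$net, planted$module, planted$disease_id,
                          config)
  # recompute induced edges on the final (densified) network
  module <- disease_module(planted$module$members,
                           seeds = planted$module$seeds,
                           ppi = drugged$net,
                           provenance = planted$module$provenance)
  structure(list(net = drugged$net, planted_module = module,
                 disease_id = planted$disease_id,
                 seed_genes = planted$seed_genes,
                 true_drugs = drugged$true_drugs,
                 decoy_drugs = drugged$decoy_drugs,
                 config = config),
            class = "benchmark")
}

#' @export
print.benchmark <- function(x, ...) {
  cat("<benchmark> ", nrow(x$net$nodes), " nodes; planted module of ",
      length(x$planted_module$members), " proteins (",
      length(x$planted_module$seeds), " seeds), ",
      length(x$true_drugs), " true / ", length(x$decoy_drugs),
      " decoy drugs\n", sep = "")
  invisible(x)
}

#' Write a benchmark to disk
#'
#' Emits the network as GraphML plus a ground-truth JSON (module members,
#' seed proteins and genes, disease id, true and decoy drugs).
#'
#' @param bench a `benchmark`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_graphml(bench$net, file.path(dir, "network.graphml"))
  jsonlite::write_json(
    list(disease_id = bench$disease_id,
         module_members = bench$planted_module$members,
         seed_proteins = bench$planted_module$seeds,
         seed_genes = bench$seed_genes,
         true_drugs = bench$true_drugs,
         decoy_drugs = bench$decoy_drugs),
    file.path(dir, "ground_truth.json"), pretty = TRUE)
  invisible(dir)
}
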