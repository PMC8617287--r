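# End-to-end workflow: seed acquisition -> module identification -> drug
# ranking -> statistical validation, driven by a single declarative
# configuration. All randomness flows from one configured seed, so
# identical configurations yield byte-identical artifacts.

#' Run the full repurposing pipeline
#'
#' Executes, in order: seed acquisition (disease query via
#' [get_disease_genes()] or a user seed file), optional module
#' identification ([must()] or [diamond()]; `"none"` ranks directly from
#' the seeds), drug ranking ([trustrank()] or [closeness_ranking()], with
#' optional [exclude_seed_targeting()]), and the requested validations.
#' Artifacts written to `out_dir`: `module.graphml`, `module.tsv`,
#' `drugs.tsv`, `validation.json`, `run.log`.
#'
#' @param config named list (or path to a YAML file) with blocks:
#'   \describe{
#'     \item{network}{path to a GraphML file, or list
#'       `(node_table, edge_table)`, or a [hetnet()] object.}
#'     \item{seeds}{path to a seed id file; or use `disease` (+ optional
#'       `include_descendants`) to query the network.}
#'     \item{module}{list: `algorithm` ("must", "diamond" or "none") plus
#'       the algorithm's parameters (`n_trees`, `hub_penalty`, `tolerance`,
#'       `n_added`, `alpha`).}
#'     \item{ranking}{list: `algorithm` ("trustrank" or "closeness"),
#'       `damping`, `tolerance`, `max_iterations`, `approved_only`,
#'       `include_indirect`, `exclude_seed_targeting`, `top_k`.}
#'     \item{validation}{list: `run` (subset of "drugs", "module",
#'       "joint"), `n_permutations`, `mode`, `reference` (path; defaults to
#'       the network's indicated drugs for `disease`).}
#'     \item{out_dir}{output directory.}
#'     \item{random_seed}{master seed (default 1).}
#'   }
#' @return invisibly, a list with `seeds`, `module`, `ranked`,
#'   `validation`, and the artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(paste0("[", ..., "]\n"),
                            file = log_path, append = TRUE)
  unlink(log_path)
  master_seed <- as.integer(config$random_seed %||% 1L)

  stage <- "load-network"
  result <- tryCatch({
    net <- load_network_config(config$network)
    logf("load-network: ", nrow(net$nodes), " nodes, ",
         nrow(net$edges), " edges")

    stage <- "seeds"
    seeds <- if (!is.null(config$seeds)) {
      seed_set(read_id_list(config$seeds), origin = "user file")
    } else if (!is.null(config$disease)) {
      get_disease_genes(net, config$disease,
                        include_descendants =
                          isTRUE(config$include_descendants))
    } else stop("config needs either 'seeds' or 'disease'", call. = FALSE)
    if (!length(seeds)) stop("seed acquisition yielded no genes",
                             call. = FALSE)
    prot_seeds <- map_seeds_to_proteins(net, seeds)
    logf("seeds: ", length(seeds), " input, ", length(prot_seeds),
         " on protein layer")

    stage <- "module"
    mcfg <- config$module %||% list(algorithm = "none")
    module <- switch(mcfg$algorithm %||% "none",
      must = must(net, prot_seeds,
                  n_trees = mcfg$n_trees %||% 10,
                  hub_penalty = mcfg$hub_penalty %||% 0,
                  tolerance = mcfg$tolerance %||% 0,
                  random_seed = master_seed),
      diamond = diamond(net, prot_seeds,
                        n_added = mcfg$n_added %||% 20,
                        alpha = mcfg$alpha %||% 1),
      none = NULL,
      stop("unknown module algorithm: ", mcfg$algorithm, call. = FALSE))
    rank_seeds <- if (is.null(module)) prot_seeds else module$members
    if (!is.null(module)) {
      write_module_graphml(module, net, file.path(out_dir, "module.graphml"))
      write_module_tsv(module, file.path(out_dir, "module.tsv"))
      logf("module: ", mcfg$algorithm, ", ", length(module$members),
           " members, ", module$n_components, " component(s)")
    } else logf("module: skipped (ranking directly from seeds)")

    stage <- "ranking"
    rcfg <- config$ranking %||% list(algorithm = "closeness")
    ralgo <- rcfg$algorithm %||% "closeness"
    rank_fun <- make_ranking_fun(ralgo, rcfg)
    ranked <- rank_fun(net, rank_seeds)
    if (isTRUE(rcfg$exclude_seed_targeting))
      ranked <- exclude_seed_targeting(ranked, net, prot_seeds)
    write_ranked_tsv(ranked, net, file.path(out_dir, "drugs.tsv"),
                     top_k = rcfg$top_k)
    logf("ranking: ", ralgo, ", ", nrow(ranked), " drugs scored")

    stage <- "validation"
    vcfg <- config$validation %||% list(run = character(0))
    vres <- list()
    runs <- vcfg$run %||% character(0)
    if (length(runs)) {
      reference <- if (!is.null(vcfg$reference)) {
        read_id_list(vcfg$reference)
      } else if (!is.null(config$disease)) {
        indicated_drugs(net, config$disease)
      } else stop("validation needs 'reference' or a disease id",
                  call. = FALSE)
      nperm <- vcfg$n_permutations %||% 1000
      if ("drugs" %in% runs)
        vres$drugs <- validate_drug_list(
          ranked, reference, net = net, n_permutations = nperm,
          mode = vcfg$mode %||% "dcg", random_seed = master_seed + 1L)
      if ("module" %in% runs && !is.null(module))
        vres$module <- validate_module(
          module, net, reference, n_permutations = nperm,
          random_seed = master_seed + 2L)
      if ("joint" %in% runs && !is.null(module))
        vres$joint <- validate_joint(
          module, net, reference, ranking = rank_fun,
          n_permutations = nperm, random_seed = master_seed + 3L,
          top_k = rcfg$top_k)
      write_validation_json(vres, file.path(out_dir, "validation.json"))
      for (nmv in names(vres))
        logf("validation ", nmv, ": P ", vres[[nmv]]$reported)
    }

    list(seeds = prot_seeds, module = module, ranked = ranked,
         validation = vres, out_dir = out_dir)
  }, error = function(e) {
    logf("ERROR at stage ", stage, ": ", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

load_network_config <- function(network) {
  if (inherits(network, "hetnet")) return(network)
  if (is.character(network) && length(network) == 1L)
    return(read_graphml(network))
  if (is.list(network) && !is.null(network$node_table))
    return(read_edge_tables(network$node_table, network$edge_table))
  stop("cannot interpret 'network' configuration", call. = FALSE)
}

make_ranking_fun <- function(algorithm, rcfg = list()) {
  switch(algorithm,
    trustrank = function(net, seeds) trustrank(
      net, seeds,
      damping = rcfg$damping %||% 0.85,
      tolerance = rcfg$tolerance %||% 1e-6,
      max_iterations = rcfg$max_iterations %||% 100,
      approved_only = isTRUE(rcfg$approved_only),
      include_indirect = rcfg$include_indirect %||% TRUE),
    closeness = function(net, seeds) closeness_ranking(
      net, seeds,
      approved_only = isTRUE(rcfg$approved_only),
      include_indirect = rcfg$include_indirect %||% TRUE,
      variant = rcfg$variant %||% "harmonic"),
    stop("unknown ranking algorithm: ", algorithm, call. = FALSE))
}
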