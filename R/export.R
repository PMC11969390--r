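# Plain-text export of simulation state: node/edge tables, event ledger,
# per-round trace, run manifest, and GraphML for the network.

#' Export a simulation result to a directory
#'
#' Writes `nodes.csv` (id, group, family, role, final toolkit size,
#' lineage of the most evolved tool), `edges.csv` (source, target, kin
#' label, round of creation; round 0 for the initial within-group ties),
#' the three ledger tables (`creations.csv`, `transmissions.csv`,
#' `evictions.csv`), the per-round `trace.csv`, `network.graphml`, and a
#' `manifest.json` recording the configuration and seed. Tools appear in
#' their label form, e.g. `"A_2.1"`.
#'
#' @param result a `ratchetr_result`.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_result <- function(result, dir) {
  stopifnot(inherits(result, "ratchetr_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pop <- result$population
  nodes <- pop$nodes
  nodes$toolkit_size <- lengths(pop$toolkits)
  nodes$lineage <- vapply(pop$toolkits, lineage_of_agent, character(1))
  g <- as_igraph(result$network, pop)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(source = el[, 1L], target = el[, 2L],
                      kin = igraph::E(g)$kin,
                      round_created = igraph::E(g)$round_created)
  files <- c(nodes = "nodes.csv", edges = "edges.csv",
             creations = "creations.csv", transmissions = "transmissions.csv",
             evictions = "evictions.csv", trace = "trace.csv")
  utils::write.csv(nodes, file.path(dir, files["nodes"]), row.names = FALSE)
  utils::write.csv(edges, file.path(dir, files["edges"]), row.names = FALSE)
  utils::write.csv(result$ledger$creations, file.path(dir, files["creations"]),
                   row.names = FALSE)
  utils::write.csv(result$ledger$transmissions,
                   file.path(dir, files["transmissions"]), row.names = FALSE)
  utils::write.csv(result$ledger$evictions, file.path(dir, files["evictions"]),
                   row.names = FALSE)
  utils::write.csv(result$trace, file.path(dir, files["trace"]),
                   row.names = FALSE)
  igraph::write_graph(g, file.path(dir, "network.graphml"), format = "graphml")
  cfg <- result$config
  manifest <- list(
    scenario = cfg$scenario, n_agents = cfg$n_agents, n_groups = cfg$n_groups,
    group_size = cfg$group_size,
    memory_cap = if (is.infinite(cfg$memory_cap)) "unlimited" else cfg$memory_cap,
    transmission = cfg$transmission, rounds = cfg$rounds,
    eviction = cfg$eviction, partner_sampling = cfg$partner_sampling,
    ps = as.list(cfg$ps), seed = result$seed
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(dir, c(files, "network.graphml", "manifest.json")))
}

#' Export the toolkits of a population as a long CSV
#'
#' One row per (agent, tool) pair of the current state.
#'
#' @param population a `ratchetr_population`.
#' @param file path of the CSV to write.
#' @return invisibly, `file`.
#' @export
write_toolkits <- function(population, file) {
  stopifnot(inherits(population, "ratchetr_population"))
  sizes <- lengths(population$toolkits)
  df <- data.frame(id = rep.int(population$nodes$id, sizes),
                   tool = unlist(population$toolkits, use.names = FALSE))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
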