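# Measurement suite: entropy-based specialization, Jaccard differentiation
# at agent and group level, network interconnectivity, ego-network
# interdependence, and ledger summaries.

#' Shannon entropy of a toolkit over lineages
#'
#' Entropy (natural log) of the distribution of a toolkit across the four
#' lineages, `H = -sum p(x) log p(x)` with `0 log 0 := 0`. Unweighted
#' shares are tool counts per lineage over toolkit size; fitness-weighted
#' shares divide each lineage's summed tool fitness by the toolkit's total
#' fitness. Entropy 0 means all tools come from a single lineage (a
#' maximally specialized agent); the maximum `log(4)` means equal shares.
#'
#' @param toolkit non-empty character vector of tool labels.
#' @param weighted logical; weight tools by fitness.
#' @return entropy in nats, a number in `[0, log(4)]`.
#' @examples
#' toolkit_entropy(initial_toolkit())          # log(4)
#' toolkit_entropy(c("A_1.1", "A_1.2"))        # 0
#' @export
toolkit_entropy <- function(toolkit, weighted = FALSE) {
  if (length(toolkit) == 0L) stop("toolkit must be non-empty")
  ids <- unique(.labels_to_ids(toolkit))
  lin <- .id_lin(ids)
  w <- if (weighted) .id_fitness(ids) else rep(1, length(ids))
  mass <- vapply(1:4, function(l) sum(w[lin == l]), numeric(1))
  p <- mass / sum(mass)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mean toolkit entropy of a group of agents
#'
#' @param toolkits list of character toolkit vectors (the group members).
#' @param weighted logical; weight tools by fitness.
#' @return mean of the members' toolkit entropies (nats).
#' @export
group_entropy <- function(toolkits, weighted = FALSE) {
  stopifnot(is.list(toolkits), length(toolkits) >= 1L)
  mean(vapply(toolkits, toolkit_entropy, numeric(1), weighted = weighted))
}

#' Pairwise Jaccard differentiation among units
#'
#' Jaccard distances over all unordered pairs of units (agents' toolkits,
#' or group toolkits formed as the union of member toolkits), with mean and
#' standard error.
#'
#' @param toolkits list of >= 2 character toolkit vectors.
#' @return list with `distances` (numeric vector, one value per unordered
#'   pair, in `combn` order), `mean` and `se`.
#' @export
pairwise_differentiation <- function(toolkits) {
  stopifnot(is.list(toolkits), length(toolkits) >= 2L)
  jm <- jaccard_matrix(toolkits)
  d <- jm[lower.tri(jm)]
  list(distances = d, mean = mean(d), se = stats::sd(d) / sqrt(length(d)))
}

#' Convert the social network to an igraph graph
#'
#' Within-group complete graphs plus accumulated between-group partner
#' edges. Edges carry a `kin` label (`spouse`, `parent-child`, `sibling`,
#' `unrelated-in-group`, `between-group`) and, for between-group edges, the
#' round of creation; nodes carry `group`, `family` and `role` when a
#' population is supplied.
#'
#' @param network a `ratchetr_network`.
#' @param population optional `ratchetr_population` for kin edge labels and
#'   node attributes.
#' @return an igraph graph.
#' @export
as_igraph <- function(network, population = NULL) {
  stopifnot(inherits(network, "ratchetr_network"))
  n <- network$n
  group <- network$group
  within <- do.call(rbind, lapply(split(seq_len(n), group), function(m) {
    t(utils::combn(m, 2L))
  }))
  b <- network$between
  edges <- rbind(within, cbind(b$from, b$to))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::V(g)$group <- group
  igraph::E(g)$round_created <- c(rep(0L, nrow(within)), b$round_created)
  if (!is.null(population)) {
    nodes <- population$nodes
    igraph::V(g)$family <- nodes$family
    igraph::V(g)$role <- nodes$role
    kin <- c(apply(within, 1L, function(e) relation(population, e[1L], e[2L])),
             rep("between-group", nrow(b)))
    igraph::E(g)$kin <- kin
  }
  g
}

#' Network interconnectivity metrics
#'
#' Between-group link count, characteristic path length (mean shortest-path
#' length over connected ordered pairs) and global efficiency
#' (`mean of 1/d_ij` over all ordered pairs, with `1/Inf := 0`, so
#' disconnection needs no special-casing).
#'
#' @param network a `ratchetr_network`.
#' @return list with `between_group_links`, `path_length`,
#'   `global_efficiency`.
#' @examples
#' pop <- build_population(scenario_config(n_groups = 2, group_size = 20))
#' network_metrics(pop$network)  # efficiency 19/39, no between links
#' @export
network_metrics <- function(network) {
  g <- as_igraph(network)
  list(
    between_group_links = nrow(network$between),
    path_length = igraph::mean_distance(g, directed = FALSE, unconnected = TRUE),
    global_efficiency = igraph::global_efficiency(g, directed = FALSE)
  )
}

# neighbour ids of one agent: in-group others plus between-group partners
.neighbour_ids <- function(network, agent) {
  ing <- setdiff(which(network$group == network$group[agent]), agent)
  b <- network$between
  c(ing, b$to[b$from == agent], b$from[b$to == agent])
}

#' Ego-network interdependence statistics
#'
#' For each agent, over the ego set (the agent plus all its network
#' neighbours: group members and accumulated between-group partners):
#' `ego_tools`, the number of distinct tools in the union of ego-set
#' toolkits; `own_frac`, the agent's toolkit size as a fraction of
#' `ego_tools`; `pool_frac`, `ego_tools` as a fraction of the distinct
#' tools in the whole population; and `mean_jaccard`, the mean Jaccard
#' distance from the agent's toolkit to each neighbour's toolkit
#' (`mode = "star"`, the default) or over all pairs within the ego set
#' (`mode = "allpairs"`).
#'
#' @param population a `ratchetr_population` (final state of a run).
#' @param mode `"star"` or `"allpairs"` for the ego Jaccard statistic.
#' @return data.frame with one row per agent: `id`, `ego_tools`,
#'   `own_frac`, `pool_frac`, `mean_jaccard`.
#' @export
ego_network_stats <- function(population, mode = c("star", "allpairs")) {
  stopifnot(inherits(population, "ratchetr_population"))
  mode <- match.arg(mode)
  network <- population$network
  ids <- lapply(population$toolkits, function(t) unique(.labels_to_ids(t)))
  pool <- length(unique(unlist(ids, use.names = FALSE)))
  n <- length(ids)
  out <- matrix(0, n, 4L)
  for (a in seq_len(n)) {
    nbv <- .neighbour_ids(network, a)
    ego_union <- unique(unlist(ids[c(a, nbv)], use.names = FALSE))
    mj <- if (length(nbv) == 0L) {
      0
    } else if (mode == "star") {
      mean(vapply(nbv, function(j) {
        inter <- sum(ids[[a]] %in% ids[[j]])
        1 - inter / (length(ids[[a]]) + length(ids[[j]]) - inter)
      }, numeric(1)))
    } else {
      jm <- .jaccard_matrix_ids(ids[c(a, nbv)])
      mean(jm[lower.tri(jm)])
    }
    out[a, ] <- c(length(ego_union), length(ids[[a]]) / length(ego_union),
                  length(ego_union) / pool, mj)
  }
  data.frame(id = seq_len(n), ego_tools = out[, 1L], own_frac = out[, 2L],
             pool_frac = out[, 3L], mean_jaccard = out[, 4L])
}

#' Summaries of a run's event ledger
#'
#' @param result a `ratchetr_result`.
#' @param log_base base for the mean log tool fitness statistic (default
#'   natural log).
#' @return list with `tools_ever` (distinct tools over the initial
#'   endowment and all creation events, including tools later forgotten),
#'   `tools_final` (distinct tools in final toolkits), `max_stage`
#'   (highest stage of any tool ever present), `crossover_levels`
#'   (distinct stage transitions achieved, `max_stage - 1`),
#'   `crossover_events` (crossover creation events), `creation_events`,
#'   and `mean_log_fitness` (mean over agents of the mean log fitness of
#'   their final toolkit).
#' @export
ledger_summaries <- function(result, log_base = exp(1)) {
  stopifnot(inherits(result, "ratchetr_result"))
  created <- unique(result$ledger$creations$tool)
  ever <- union(initial_toolkit(), created)
  final_tools <- unique(unlist(result$population$toolkits, use.names = FALSE))
  stages <- parse_tools(ever)$stage
  mlf <- mean(vapply(result$population$toolkits, function(t) {
    mean(log(toolkit_fitness(t), base = log_base))
  }, numeric(1)))
  list(
    tools_ever = length(ever),
    tools_final = length(final_tools),
    max_stage = max(stages),
    crossover_levels = max(stages) - 1L,
    crossover_events = sum(result$ledger$creations$kind == "crossover"),
    creation_events = nrow(result$ledger$creations),
    mean_log_fitness = mlf
  )
}

#' Full per-run metrics record
#'
#' Computes every measurement for one finished run: per-agent entropies
#' (weighted and unweighted) and ego-network statistics, per-group mean
#' entropies, agent- and group-level Jaccard differentiation, network
#' interconnectivity, and ledger summaries.
#'
#' @param result a `ratchetr_result`.
#' @return list with components `agents` (data.frame, one row per agent),
#'   `groups` (data.frame, one row per group), `summary` (named numeric
#'   vector of scalar metrics).
#' @export
metrics_record <- function(result) {
  stopifnot(inherits(result, "ratchetr_result"))
  pop <- result$population
  toolkits <- pop$toolkits
  group <- pop$nodes$group
  ent_u <- vapply(toolkits, toolkit_entropy, numeric(1), weighted = FALSE)
  ent_w <- vapply(toolkits, toolkit_entropy, numeric(1), weighted = TRUE)
  ego <- ego_network_stats(pop)
  mlfa <- vapply(toolkits, function(t) mean(log(toolkit_fitness(t))), numeric(1))
  agents <- cbind(pop$nodes,
                  data.frame(entropy = ent_u, entropy_weighted = ent_w,
                             mean_log_fitness = mlfa,
                             toolkit_size = lengths(toolkits)),
                  ego[, -1L])
  groups <- data.frame(
    group = sort(unique(group)),
    mean_entropy = as.numeric(tapply(ent_u, group, mean)),
    mean_entropy_weighted = as.numeric(tapply(ent_w, group, mean))
  )
  group_toolkits <- lapply(split(toolkits, group),
                           function(tl) unique(unlist(tl, use.names = FALSE)))
  agent_diff <- pairwise_differentiation(toolkits)
  group_diff <- pairwise_differentiation(group_toolkits)
  nm <- network_metrics(pop$network)
  ls <- ledger_summaries(result)
  summary <- c(
    mean_entropy = mean(ent_u),
    mean_entropy_weighted = mean(ent_w),
    mean_group_entropy = mean(groups$mean_entropy),
    mean_group_entropy_weighted = mean(groups$mean_entropy_weighted),
    agent_jaccard = agent_diff$mean,
    group_jaccard = group_diff$mean,
    between_group_links = nm$between_group_links,
    path_length = nm$path_length,
    global_efficiency = nm$global_efficiency,
    ego_tools = mean(ego$ego_tools),
    ego_own_frac = mean(ego$own_frac),
    ego_pool_frac = mean(ego$pool_frac),
    ego_mean_jaccard = mean(ego$mean_jaccard),
    tools_ever = ls$tools_ever,
    tools_final = ls$tools_final,
    max_stage = ls$max_stage,
    crossover_levels = ls$crossover_levels,
    crossover_events = ls$crossover_events,
    mean_log_fitness = ls$mean_log_fitness,
    mean_toolkit_size = mean(lengths(toolkits))
  )
  list(agents = agents, groups = groups, summary = summary)
}
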