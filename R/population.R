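# Kin-structured population and the initial social network: M disconnected,
# fully connected groups, each split into families of five (two parents,
# three offspring).

#' Scenario configuration
#'
#' Builds a validated configuration for one simulation scenario. The four
#' canonical scenarios cross agent memory (unlimited vs. capped at 8 items)
#' with social transmission of new tools (off vs. on):
#' `"i"` unlimited/no transmission, `"ii"` limited/no transmission,
#' `"iii"` unlimited/transmission, `"iv"` limited/transmission.
#' Named arguments override the preset.
#'
#' @param scenario optional scenario id, one of `"i"`, `"ii"`, `"iii"`, `"iv"`.
#' @param n_groups number of groups M (default 15).
#' @param group_size agents per group (default 20); must be a multiple of 5,
#'   split into families of 2 parents + 3 offspring.
#' @param memory_cap maximum toolkit size, `Inf` for unlimited. A finite cap
#'   must be at least 8, the size of the initial endowment.
#' @param transmission logical; share newly created tools with network
#'   neighbours at kin-dependent probabilities.
#' @param rounds number of simulation rounds (default 150).
#' @param replicates default replicate count for batch runs (default 50).
#' @param eviction `"monotone"` (default) inserts the new tool and then
#'   evicts the minimum-fitness tool among the cap+1, so an incoming tool
#'   weaker than the whole toolkit is itself discarded; `"literal"` always
#'   replaces the current minimum-fitness tool with the incoming one.
#' @param partner_sampling `"agent"` (default) draws an out-group partner
#'   uniformly over all out-group agents; `"group"` first draws a group,
#'   then an agent within it.
#' @param link_rule when a cross-group dyad leaves a persistent
#'   between-group edge: `"creation"` (default) only when the dyad
#'   successfully creates a tool, `"interaction"` on any cross-group
#'   partnership. Registered edges count as network neighbours for
#'   transmission and ego-network metrics.
#' @param ps named numeric vector of per-neighbour transmission
#'   probabilities by kin tie. Defaults: spouse/parent-child 0.5,
#'   sibling 0.25, unrelated group members and between-group partner
#'   links 0.05.
#' @return an object of class `ratchetr_config`.
#' @examples
#' scenario_config("iv")
#' scenario_config(n_groups = 2, group_size = 10, rounds = 20)
#' @export
scenario_config <- function(scenario = NULL,
                            n_groups = 15L,
                            group_size = 20L,
                            memory_cap = Inf,
                            transmission = FALSE,
                            rounds = 150L,
                            replicates = 50L,
                            eviction = c("monotone", "literal"),
                            partner_sampling = c("agent", "group"),
                            link_rule = c("creation", "interaction"),
                            ps = c(spouse = 0.5, `parent-child` = 0.5,
                                   sibling = 0.25, `unrelated-in-group` = 0.05,
                                   `between-group` = 0.05)) {
  if (!is.null(scenario)) {
    scenario <- match.arg(scenario, c("i", "ii", "iii", "iv"))
    preset <- switch(scenario,
      i = list(memory_cap = Inf, transmission = FALSE),
      ii = list(memory_cap = 8L, transmission = FALSE),
      iii = list(memory_cap = Inf, transmission = TRUE),
      iv = list(memory_cap = 8L, transmission = TRUE))
    if (missing(memory_cap)) memory_cap <- preset$memory_cap
    if (missing(transmission)) transmission <- preset$transmission
  }
  n_groups <- as.integer(n_groups)
  group_size <- as.integer(group_size)
  if (n_groups < 2L) stop("'n_groups' must be >= 2 (partner choice needs out-groups)")
  if (group_size < 5L || group_size %% 5L != 0L)
    stop("'group_size' must be a positive multiple of 5 (families of 2 parents + 3 offspring)")
  if (!is.infinite(memory_cap)) {
    memory_cap <- as.integer(memory_cap)
    if (is.na(memory_cap) || memory_cap < 8L)
      stop("'memory_cap' must be Inf or an integer >= 8 (the initial endowment size)")
  }
  if (rounds < 0L) stop("'rounds' must be >= 0")
  required_ps <- c("spouse", "parent-child", "sibling", "unrelated-in-group", "between-group")
  if (!all(required_ps %in% names(ps)))
    stop("'ps' must name all of: ", paste(required_ps, collapse = ", "))
  structure(list(
    scenario = if (is.null(scenario)) NA_character_ else scenario,
    n_groups = n_groups,
    group_size = group_size,
    n_agents = n_groups * group_size,
    memory_cap = memory_cap,
    transmission = isTRUE(transmission),
    rounds = as.integer(rounds),
    replicates = as.integer(replicates),
    eviction = match.arg(eviction),
    partner_sampling = match.arg(partner_sampling),
    link_rule = match.arg(link_rule),
    ps = ps[required_ps]
  ), class = "ratchetr_config")
}

#' @export
print.ratchetr_config <- function(x, ...) {
  cat("ratchetr scenario configuration\n")
  cat(sprintf("  scenario:     %s\n", x$scenario))
  cat(sprintf("  population:   %d agents = %d groups x %d\n",
              x$n_agents, x$n_groups, x$group_size))
  cat(sprintf("  memory cap:   %s (%s eviction)\n",
              if (is.infinite(x$memory_cap)) "unlimited" else x$memory_cap,
              x$eviction))
  cat(sprintf("  transmission: %s\n", if (x$transmission) "on" else "off"))
  cat(sprintf("  rounds:       %d, replicates: %d\n", x$rounds, x$replicates))
  invisible(x)
}

#' Build the kin-structured population
#'
#' Creates `n_groups * group_size` agents, every one endowed with the same
#' initial toolkit of 8 tools. Agent ids are assigned group-major then
#' family-major so that runs are reproducible given a seed. Each family has
#' two parents and three offspring; within a group every pair of agents is
#' connected (a complete graph), and at round 0 no edges exist between
#' groups.
#'
#' @param config a [scenario_config()].
#' @return an object of class `ratchetr_population`: list with `nodes`
#'   (data.frame: `id`, `group`, `family`, `role`), `toolkits` (list of
#'   character toolkit vectors), `network` (a `ratchetr_network`) and
#'   `config`.
#' @examples
#' pop <- build_population(scenario_config(n_groups = 2, group_size = 10))
#' table(pop$nodes$role)
#' @export
build_population <- function(config) {
  stopifnot(inherits(config, "ratchetr_config"))
  n <- config$n_agents
  fam_per_group <- config$group_size %/% 5L
  group <- rep(seq_len(config$n_groups), each = config$group_size)
  family <- rep(rep(seq_len(fam_per_group), each = 5L), times = config$n_groups)
  role <- rep(rep(c("parent", "parent", "offspring", "offspring", "offspring"),
                  times = fam_per_group), times = config$n_groups)
  nodes <- data.frame(id = seq_len(n), group = group, family = family,
                      role = role, stringsAsFactors = FALSE)
  toolkits <- rep(list(initial_toolkit()), n)
  network <- structure(list(
    n = n,
    group = group,
    between = data.frame(from = integer(0), to = integer(0),
                         round_created = integer(0))
  ), class = "ratchetr_network")
  structure(list(nodes = nodes, toolkits = toolkits, network = network,
                 config = config),
            class = "ratchetr_population")
}

#' @export
print.ratchetr_population <- function(x, ...) {
  cat(sprintf("ratchetr population: %d agents in %d groups (%d between-group links)\n",
              nrow(x$nodes), x$config$n_groups, nrow(x$network$between)))
  invisible(x)
}

#' Kin relation between two agents
#'
#' Classifies the tie between two distinct agents: `"spouse"` (the two
#' parents of one family), `"parent-child"`, `"sibling"` (two offspring of
#' one family), `"unrelated-in-group"` (same group, different families),
#' `"between-group"` (different groups joined by an accumulated partner
#' edge) or `"none"` (different groups, no edge). Symmetric in its
#' arguments.
#'
#' @param population a `ratchetr_population`.
#' @param i,j agent ids.
#' @return a single kin label.
#' @export
relation <- function(population, i, j) {
  stopifnot(inherits(population, "ratchetr_population"))
  nodes <- population$nodes
  i <- as.integer(i); j <- as.integer(j)
  if (i == j) stop("'i' and 'j' must be distinct agents")
  if (nodes$group[i] != nodes$group[j]) {
    b <- population$network$between
    hit <- any((b$from == i & b$to == j) | (b$from == j & b$to == i))
    return(if (hit) "between-group" else "none")
  }
  if (nodes$family[i] != nodes$family[j]) return("unrelated-in-group")
  ri <- nodes$role[i]; rj <- nodes$role[j]
  if (ri == "parent" && rj == "parent") return("spouse")
  if (ri == "offspring" && rj == "offspring") return("sibling")
  "parent-child"
}

#' Current lineage assignment of a toolkit
#'
#' An agent is classified as belonging to the lineage of its most evolved
#' tool, ordering tools by (stage, level); ties between lineages are broken
#' uniformly at random on every call (the assignment is momentary, never
#' cached).
#'
#' @param toolkit character vector of tool labels.
#' @return one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @examples
#' lineage_of_agent(c("A_1.3", "B_1.1"))  # "A"
#' @export
lineage_of_agent <- function(toolkit) {
  if (length(toolkit) == 0L) stop("toolkit must be non-empty")
  ids <- .labels_to_ids(toolkit)
  LINEAGES[.lineage_of_ids(ids)]
}

.lineage_of_ids <- function(ids) {
  pos <- .id_pos(ids)
  top <- which(pos == max(pos))
  lins <- unique(.id_lin(ids[top]))
  if (length(lins) == 1L) lins else lins[sample.int(length(lins), 1L)]
}
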