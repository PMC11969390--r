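# Partner selection: toolkit dissimilarity (Jaccard distance) and the
# dynamic within/between-group partner choice rule.

#' Jaccard distance between two toolkits
#'
#' `J = 1 - |intersection| / |union|` on the tool sets; 0 iff the sets are
#' identical, 1 iff disjoint.
#'
#' @param toolkit_a,toolkit_b non-empty character vectors of tool labels.
#' @return a number in \[0, 1\].
#' @examples
#' jaccard(c("A_1.1", "A_1.2", "B_1.1"), c("A_1.2", "B_1.1", "B_1.2"))  # 0.5
#' @export
jaccard <- function(toolkit_a, toolkit_b) {
  if (length(toolkit_a) == 0L || length(toolkit_b) == 0L)
    stop("toolkits must be non-empty")
  a <- unique(.labels_to_ids(toolkit_a))
  b <- unique(.labels_to_ids(toolkit_b))
  inter <- sum(a %in% b)
  1 - inter / (length(a) + length(b) - inter)
}

# All-pairs Jaccard distance matrix over a list of id toolkits, via a dense
# agent x tool incidence matrix (tools are bounded by the grammar, so the
# matrix stays small even late in a run).
.jaccard_matrix_ids <- function(toolkits) {
  n <- length(toolkits)
  lens <- lengths(toolkits)
  k <- max(unlist(toolkits, use.names = FALSE))
  b <- matrix(0, n, k)
  b[cbind(rep.int(seq_len(n), lens), unlist(toolkits, use.names = FALSE))] <- 1
  inter <- tcrossprod(b)
  un <- outer(lens, lens, "+") - inter
  j <- 1 - inter / un
  diag(j) <- 0
  j
}

#' Pairwise Jaccard distance matrix
#'
#' @param toolkits list of character toolkit vectors.
#' @return symmetric numeric matrix of Jaccard distances.
#' @export
jaccard_matrix <- function(toolkits) {
  stopifnot(is.list(toolkits), length(toolkits) >= 1L)
  if (any(lengths(toolkits) == 0L)) stop("toolkits must be non-empty")
  .jaccard_matrix_ids(lapply(toolkits, function(t) unique(.labels_to_ids(t))))
}

# Per-agent distance summary from a precomputed Jaccard matrix: D_w = mean
# distance to in-group others, D_b = mean distance to all out-group agents,
# P = (D_b - D_w) / 2.
.distance_summary_from_matrix <- function(jmat, group) {
  n <- nrow(jmat)
  gsz <- tabulate(group)
  gind <- matrix(0, n, max(group))
  gind[cbind(seq_len(n), group)] <- 1
  sg <- jmat %*% gind                       # per-agent sum of distances by group
  own <- sg[cbind(seq_len(n), group)]
  dw <- own / (gsz[group] - 1L)
  db <- (rowSums(jmat) - own) / (n - gsz[group])
  data.frame(d_within = dw, d_between = db, p = (db - dw) / 2)
}

#' Within/between-group toolkit distance summary
#'
#' For each agent: `d_within`, the mean Jaccard distance to the other
#' members of its group; `d_between`, the mean Jaccard distance to all
#' agents of other groups; and the partner-choice parameter
#' `p = (d_between - d_within) / 2`. When `p > 0` the agent is more similar
#' to its own group than to outsiders and seeks a partner from another
#' group with probability `p`.
#'
#' @param population a `ratchetr_population` (current toolkits are used).
#' @return data.frame with one row per agent: `id`, `d_within`,
#'   `d_between`, `p`.
#' @export
toolkit_distances <- function(population) {
  stopifnot(inherits(population, "ratchetr_population"))
  ids <- lapply(population$toolkits, .labels_to_ids)
  out <- .distance_summary_from_matrix(.jaccard_matrix_ids(ids),
                                       population$nodes$group)
  cbind(id = population$nodes$id, out)
}

#' Choose a recombination partner for one agent
#'
#' Implements the dynamic partner rule: when the agent's toolkit is more
#' similar to its own group than to other groups (`p > 0`), a partner is
#' drawn uniformly from the out-group agents with probability `p`,
#' otherwise (and always when `p <= 0`) uniformly from the other members
#' of its own group. `p` is recomputed from the current toolkits.
#'
#' @param population a `ratchetr_population`.
#' @param agent focal agent id.
#' @return list with `partner` (agent id) and `between_group` (logical).
#' @export
choose_partner <- function(population, agent) {
  stopifnot(inherits(population, "ratchetr_population"))
  d <- toolkit_distances(population)
  group <- population$nodes$group
  n <- length(group)
  p <- d$p[agent]
  between <- p > 0 && stats::runif(1) < p
  pool <- if (between) which(group != group[agent])
          else setdiff(which(group == group[agent]), agent)
  list(partner = pool[sample.int(length(pool), 1L)], between_group = between)
}

#' Register a between-group partner edge
#'
#' A dyad spanning two groups adds a persistent between-group edge to the
#' social network, stamped with the round of creation, unless the edge
#' already exists; within-group dyads add nothing (groups are complete
#' graphs from the start). Between-group edges count as network neighbours
#' for transmission and ego-network metrics.
#'
#' @param network a `ratchetr_network`.
#' @param i,j agent ids of the dyad.
#' @param round round index in which the dyad formed.
#' @return the updated network.
#' @export
register_partner_link <- function(network, i, j, round) {
  stopifnot(inherits(network, "ratchetr_network"))
  if (network$group[i] == network$group[j]) return(network)
  b <- network$between
  if (any((b$from == i & b$to == j) | (b$from == j & b$to == i))) return(network)
  network$between <- rbind(b, data.frame(from = as.integer(i), to = as.integer(j),
                                         round_created = as.integer(round)))
  network
}
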