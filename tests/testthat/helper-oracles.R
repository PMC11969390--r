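# Independent brute-force oracles used to check the package implementations.

# fitness by iterating the two stated multipliers from (1,1): x1.05 per
# incremental level, x2 at each stage transition
oracle_fitness <- function(stage, level) {
  target <- 3 * (stage - 1) + level
  f <- 1
  p <- 1
  while (p < target) {
    f <- if (p %% 3 == 0) 2 * f else 1.05 * f
    p <- p + 1
  }
  f
}

# Shannon entropy over lineage shares by explicit loop
oracle_entropy <- function(toolkit, weighted = FALSE) {
  toolkit <- unique(toolkit)
  info <- parse_tools(toolkit)
  h <- 0
  tot <- if (weighted) sum(info$fitness) else nrow(info)
  for (lin in c("A", "B", "C", "D")) {
    m <- if (weighted) sum(info$fitness[info$lineage == lin])
         else sum(info$lineage == lin)
    p <- m / tot
    if (p > 0) h <- h - p * log(p)
  }
  h
}

oracle_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  1 - length(intersect(a, b)) / length(union(a, b))
}

# BFS all-pairs shortest paths on an adjacency matrix
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    dist <- 0
    while (length(frontier) > 0) {
      dist <- dist + 1
      reach <- which(colSums(adj[frontier, , drop = FALSE]) > 0)
      nxt <- reach[is.infinite(d[s, reach])]
      d[s, nxt] <- dist
      frontier <- nxt
    }
  }
  d
}

oracle_path_length <- function(adj) {
  d <- oracle_distances(adj)
  v <- d[upper.tri(d) | lower.tri(d)]
  mean(v[is.finite(v)])
}

oracle_efficiency <- function(adj) {
  d <- oracle_distances(adj)
  v <- 1 / d[upper.tri(d) | lower.tri(d)]
  mean(v)
}

# adjacency matrix of a ratchetr network (complete groups + between edges)
network_adjacency <- function(network) {
  n <- network$n
  adj <- outer(network$group, network$group, "==")
  diag(adj) <- FALSE
  b <- network$between
  if (nrow(b) > 0) {
    adj[cbind(b$from, b$to)] <- TRUE
    adj[cbind(b$to, b$from)] <- TRUE
  }
  adj
}

# fabricate a bare network object (groups of given sizes, optional edges)
make_network <- function(group, between = NULL) {
  if (is.null(between))
    between <- data.frame(from = integer(0), to = integer(0),
                          round_created = integer(0))
  structure(list(n = length(group), group = group, between = between),
            class = "ratchetr_network")
}

# random toolkit of labels up to a given stage
random_toolkit <- function(size, max_stage = 4) {
  grid <- expand.grid(lin = c("A", "B", "C", "D"), stage = seq_len(max_stage),
                      level = 1:3)
  labs <- paste0(grid$lin, "_", grid$stage, ".", grid$level)
  sample(labs, size)
}

# all tool labels up to a stage
all_tools <- function(max_stage) {
  grid <- expand.grid(level = 1:3, stage = seq_len(max_stage),
                      lin = c("A", "B", "C", "D"))
  paste0(grid$lin, "_", grid$stage, ".", grid$level)
}
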