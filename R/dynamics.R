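# Simulation dynamics: rounds of partner choice, fitness-proportional tool
# draws, recombination, adoption (with optional memory eviction), and
# kin-weighted one-hop transmission of new tools.

# growing event log: integer matrix with row doubling
.new_log <- function(ncol) {
  e <- new.env(parent = emptyenv())
  e$m <- matrix(0L, 256L, ncol)
  e$k <- 0L
  e
}
.log_add <- function(log, row) {
  k <- log$k + 1L
  if (k > nrow(log$m)) log$m <- rbind(log$m, matrix(0L, nrow(log$m), ncol(log$m)))
  log$m[k, ] <- row
  log$k <- k
}
.log_mat <- function(log) log$m[seq_len(log$k), , drop = FALSE]

# fitness-proportional draw of one tool id from an id toolkit
.draw_id <- function(tkv, ladder) {
  if (length(tkv) == 1L) return(tkv)
  w <- ladder[(tkv - 1L) %/% 4L + 1L]
  cw <- cumsum(w)
  tkv[findInterval(stats::runif(1) * cw[length(cw)], cw) + 1L]
}

# Adoption of a tool id into an id toolkit under the memory regime.
# Returns list(tk = new toolkit, evicted = evicted id or NA). A tool
# already present is a no-op (set semantics). Under a finite cap:
#  - monotone (default): insert, then evict the minimum-fitness tool among
#    the cap+1 (ties uniform), so a weak incoming tool evicts itself;
#  - literal: the incoming tool always replaces the current minimum.
.adopt_id <- function(tkv, id, cap, literal, ladder) {
  if (id %in% tkv) return(list(tk = tkv, evicted = NA_integer_))
  if (length(tkv) < cap) return(list(tk = c(tkv, id), evicted = NA_integer_))
  if (literal) {
    f <- ladder[(tkv - 1L) %/% 4L + 1L]
    mn <- which(f == min(f))
    ev <- if (length(mn) > 1L) mn[sample.int(length(mn), 1L)] else mn
    evicted <- tkv[ev]
    tkv[ev] <- id
    list(tk = tkv, evicted = evicted)
  } else {
    tk2 <- c(tkv, id)
    f <- ladder[(tk2 - 1L) %/% 4L + 1L]
    mn <- which(f == min(f))
    ev <- if (length(mn) > 1L) mn[sample.int(length(mn), 1L)] else mn
    evicted <- tk2[ev]
    list(tk = tk2[-ev], evicted = evicted)
  }
}

# within-group kin transmission probability for an ordered pair of nodes
.kin_prob <- function(nodes, i, j, ps) {
  if (nodes$family[i] != nodes$family[j]) return(ps[["unrelated-in-group"]])
  ri <- nodes$role[i]; rj <- nodes$role[j]
  if (ri == "parent" && rj == "parent") return(ps[["spouse"]])
  if (ri == "offspring" && rj == "offspring") return(ps[["sibling"]])
  ps[["parent-child"]]
}

# The engine: advances a population by `rounds` rounds, mutating toolkits
# and the network, and returns the updated population together with the
# event ledger and per-round trace for the simulated span. Uses the current
# RNG state; callers that need reproducibility set the seed.
.simulate_rounds <- function(population, rounds, start_round = 1L) {
  cfg <- population$config
  nodes <- population$nodes
  n <- nrow(nodes)
  group <- nodes$group
  cap <- if (is.infinite(cfg$memory_cap)) .Machine$integer.max else cfg$memory_cap
  literal <- identical(cfg$eviction, "literal")
  trans <- cfg$transmission
  link_on_creation <- identical(cfg$link_rule, "creation")
  ps <- cfg$ps
  by_group <- cfg$partner_sampling == "group"
  ladder <- .fitness_ladder(600L)

  tk <- lapply(population$toolkits, .labels_to_ids)

  gm <- split(seq_len(n), group)             # group members
  om <- lapply(seq_along(gm), function(g) which(group != g))  # out-group agents
  groups <- seq_along(gm)

  # neighbour lists + transmission probabilities (within-group kin ties,
  # plus accumulated between-group links at the background rate)
  nb <- vector("list", n)
  nbp <- vector("list", n)
  for (i in seq_len(n)) {
    others <- setdiff(gm[[group[i]]], i)
    nb[[i]] <- others
    nbp[[i]] <- vapply(others, function(j) .kin_prob(nodes, i, j, ps), numeric(1))
  }
  b0 <- population$network$between
  badj <- matrix(FALSE, n, n)
  if (nrow(b0)) {
    badj[cbind(b0$from, b0$to)] <- TRUE
    badj[cbind(b0$to, b0$from)] <- TRUE
    for (k in seq_len(nrow(b0))) {
      i <- b0$from[k]; j <- b0$to[k]
      nb[[i]] <- c(nb[[i]], j); nbp[[i]] <- c(nbp[[i]], ps[["between-group"]])
      nb[[j]] <- c(nb[[j]], i); nbp[[j]] <- c(nbp[[j]], ps[["between-group"]])
    }
  }
  bet_from <- b0$from; bet_to <- b0$to; bet_round <- b0$round_created

  creations <- .new_log(5L)     # round, tool, creator, partner, kind(1=incr,2=cross)
  transmissions <- .new_log(4L) # round, tool, from, to
  evictions <- .new_log(3L)     # round, tool, agent

  max_pos <- max(vapply(tk, function(v) max((v - 1L) %/% 4L + 1L), integer(1)))
  trace <- matrix(0, nrow = rounds, ncol = 6L,
                  dimnames = list(NULL, c("round", "creations", "max_stage",
                                          "between_links", "mean_toolkit_size",
                                          "mean_p")))

  deliver <- function(receiver, id, round) {
    res <- .adopt_id(tk[[receiver]], id, cap, literal, ladder)
    tk[[receiver]] <<- res$tk
    if (!is.na(res$evicted)) .log_add(evictions, c(round, res$evicted, receiver))
    invisible(NULL)
  }

  for (r in seq_len(rounds)) {
    round <- start_round + r - 1L
    # partner-choice parameter from round-start toolkits
    p <- .distance_summary_from_matrix(.jaccard_matrix_ids(tk), group)$p
    n_created <- 0L
    for (i in sample.int(n)) {
      gi <- group[i]
      if (p[i] > 0 && stats::runif(1) < p[i]) {
        between <- TRUE
        if (by_group) {
          g2 <- groups[-gi][sample.int(length(groups) - 1L, 1L)]
          pool <- gm[[g2]]
          j <- pool[sample.int(length(pool), 1L)]
        } else {
          pool <- om[[gi]]
          j <- pool[sample.int(length(pool), 1L)]
        }
      } else {
        between <- FALSE
        pool <- gm[[gi]]
        repeat {
          j <- pool[sample.int(length(pool), 1L)]
          if (j != i) break
        }
      }
      ta <- .draw_id(tk[[i]], ladder)
      tb <- .draw_id(tk[[j]], ladder)
      new_id <- .recombine_ids(ta, tb, (ta - 1L) %% 4L + 1L)
      if (!is.na(new_id)) {
        kind <- if ((new_id - 1L) %/% 4L %% 3L == 0L) 2L else 1L
        .log_add(creations, c(round, new_id, i, j, kind))
        n_created <- n_created + 1L
        pos_new <- (new_id - 1L) %/% 4L + 1L
        if (pos_new > max_pos) max_pos <- pos_new
        deliver(i, new_id, round)
        deliver(j, new_id, round)
        if (trans) {
          for (o in c(i, j)) {
            nbv <- nb[[o]]
            hits <- nbv[stats::runif(length(nbv)) < nbp[[o]]]
            for (rcv in hits) {
              .log_add(transmissions, c(round, new_id, o, rcv))
              deliver(rcv, new_id, round)
            }
          }
        }
      }
      if (between && (!link_on_creation || !is.na(new_id)) && !badj[i, j]) {
        badj[i, j] <- TRUE; badj[j, i] <- TRUE
        bet_from <- c(bet_from, i); bet_to <- c(bet_to, j)
        bet_round <- c(bet_round, round)
        nb[[i]] <- c(nb[[i]], j); nbp[[i]] <- c(nbp[[i]], ps[["between-group"]])
        nb[[j]] <- c(nb[[j]], i); nbp[[j]] <- c(nbp[[j]], ps[["between-group"]])
      }
    }
    trace[r, ] <- c(round, n_created, (max_pos - 1L) %/% 3L + 1L,
                    length(bet_from), mean(lengths(tk)), mean(p))
  }

  population$toolkits <- lapply(tk, .ids_to_labels)
  population$network$between <- data.frame(from = as.integer(bet_from),
                                           to = as.integer(bet_to),
                                           round_created = as.integer(bet_round))
  cre <- .log_mat(creations)
  trm <- .log_mat(transmissions)
  evi <- .log_mat(evictions)
  ledger <- list(
    creations = data.frame(
      round = cre[, 1L], tool = .ids_to_labels(cre[, 2L]),
      creator = cre[, 3L], partner = cre[, 4L],
      kind = c("incremental", "crossover")[cre[, 5L]],
      stringsAsFactors = FALSE),
    transmissions = data.frame(
      round = trm[, 1L], tool = .ids_to_labels(trm[, 2L]),
      from = trm[, 3L], to = trm[, 4L], stringsAsFactors = FALSE),
    evictions = data.frame(
      round = evi[, 1L], tool = .ids_to_labels(evi[, 2L]),
      agent = evi[, 3L], stringsAsFactors = FALSE)
  )
  if (nrow(ledger$creations) == 0L) ledger$creations$tool <- character(0)
  if (nrow(ledger$transmissions) == 0L) ledger$transmissions$tool <- character(0)
  if (nrow(ledger$evictions) == 0L) ledger$evictions$tool <- character(0)
  list(population = population, ledger = ledger,
       trace = as.data.frame(trace))
}

#' Fitness-proportional tool draw
#'
#' Draws one tool from a toolkit with probability proportional to tool
#' fitness.
#'
#' @param toolkit non-empty character vector of tool labels.
#' @return a single tool label.
#' @export
draw_tool <- function(toolkit) {
  if (length(toolkit) == 0L) stop("toolkit must be non-empty")
  .ids_to_labels(.draw_id(.labels_to_ids(toolkit), .fitness_ladder(600L)))
}

#' Adopt a tool into a toolkit
#'
#' Set semantics: a tool already present changes nothing. With unlimited
#' memory the tool is added. At a finite memory cap the default
#' (`eviction = "monotone"`) inserts the tool and then evicts the
#' minimum-fitness tool among the cap+1 candidates (ties broken uniformly
#' at random), so an incoming tool weaker than everything already held is
#' itself discarded and minimum toolkit fitness never decreases;
#' `eviction = "literal"` always replaces the current minimum-fitness tool.
#'
#' @param toolkit character vector of tool labels.
#' @param tool tool label to adopt.
#' @param memory_cap maximum toolkit size (`Inf` for unlimited).
#' @param eviction `"monotone"` or `"literal"`.
#' @return list with `toolkit` (updated character vector) and `evicted`
#'   (evicted tool label or `NA`).
#' @export
adopt <- function(toolkit, tool, memory_cap = Inf,
                  eviction = c("monotone", "literal")) {
  eviction <- match.arg(eviction)
  cap <- if (is.infinite(memory_cap)) .Machine$integer.max else as.integer(memory_cap)
  res <- .adopt_id(.labels_to_ids(toolkit), .labels_to_ids(tool)[1L], cap,
                   eviction == "literal", .fitness_ladder(600L))
  list(toolkit = .ids_to_labels(res$tk),
       evicted = if (is.na(res$evicted)) NA_character_ else .ids_to_labels(res$evicted))
}

#' One-hop kin-weighted transmission of a tool
#'
#' Performs one independent Bernoulli trial per network neighbour of the
#' owner (group members plus accumulated between-group partner links), with
#' success probability set by the kin tie: 0.5 for spouse and parent-child,
#' 0.25 for sibling, 0.05 for unrelated group members and between-group
#' links (configurable via `scenario_config(ps = ...)`). Returns the ids of
#' the neighbours the tool reaches; receivers adopt it via [adopt()]
#' semantics in the simulation loop.
#'
#' @param population a `ratchetr_population` whose config has
#'   `transmission = TRUE`.
#' @param owner agent id sharing the tool.
#' @return integer vector of receiving agent ids (possibly empty).
#' @export
transmit <- function(population, owner) {
  stopifnot(inherits(population, "ratchetr_population"))
  cfg <- population$config
  if (!cfg$transmission)
    stop("transmission is disabled in this scenario configuration")
  nodes <- population$nodes
  others <- setdiff(which(nodes$group == nodes$group[owner]), owner)
  pr <- vapply(others, function(j) .kin_prob(nodes, owner, j, cfg$ps), numeric(1))
  b <- population$network$between
  bn <- c(b$to[b$from == owner], b$from[b$to == owner])
  nbv <- c(others, bn)
  pr <- c(pr, rep(cfg$ps[["between-group"]], length(bn)))
  nbv[stats::runif(length(nbv)) < pr]
}

#' Advance a population by one or more rounds
#'
#' In each round every agent, in a fresh uniform random order, chooses a
#' partner ([choose_partner()] rule), both members of the dyad draw one
#' tool fitness-proportionally from their current toolkits, and the pair is
#' recombined with the focal agent as initiator. On a successful recipe both
#' agents adopt the new tool, and in transmission scenarios both share it
#' one hop with their network neighbours at kin-dependent probabilities.
#' Cross-group dyads add a persistent between-group edge.
#'
#' @param population a `ratchetr_population`.
#' @param rounds number of rounds to simulate.
#' @param start_round index of the first simulated round (for ledger and
#'   edge timestamps).
#' @return list with the updated `population`, the `ledger` (data frames
#'   `creations`, `transmissions`, `evictions`) and the per-round `trace`.
#' @export
run_rounds <- function(population, rounds = 1L, start_round = 1L) {
  stopifnot(inherits(population, "ratchetr_population"), rounds >= 0L)
  if (rounds == 0L) {
    return(list(population = population,
                ledger = .empty_ledger(),
                trace = data.frame(round = integer(0), creations = integer(0),
                                   max_stage = integer(0), between_links = integer(0),
                                   mean_toolkit_size = numeric(0), mean_p = numeric(0))))
  }
  .simulate_rounds(population, as.integer(rounds), as.integer(start_round))
}

.empty_ledger <- function() {
  list(
    creations = data.frame(round = integer(0), tool = character(0),
                           creator = integer(0), partner = integer(0),
                           kind = character(0), stringsAsFactors = FALSE),
    transmissions = data.frame(round = integer(0), tool = character(0),
                               from = integer(0), to = integer(0),
                               stringsAsFactors = FALSE),
    evictions = data.frame(round = integer(0), tool = character(0),
                           agent = integer(0), stringsAsFactors = FALSE)
  )
}

#' Run one complete simulation
#'
#' Builds the kin-structured population for `config`, seeds the RNG and
#' simulates `config$rounds` rounds. Deterministic given `(config, seed)`.
#'
#' @param config a [scenario_config()].
#' @param seed integer RNG seed for this run.
#' @return an object of class `ratchetr_result`: list with the final
#'   `population`, the final `network`, the event `ledger` (creations,
#'   transmissions, evictions), the per-round `trace`, `config` and `seed`.
#' @examples
#' res <- run_simulation(scenario_config(n_groups = 2, group_size = 10,
#'                                       rounds = 10), seed = 1)
#' ledger_summaries(res)
#' @export
run_simulation <- function(config, seed) {
  stopifnot(inherits(config, "ratchetr_config"))
  set.seed(as.integer(seed))
  pop <- build_population(config)
  out <- run_rounds(pop, config$rounds, 1L)
  structure(list(population = out$population,
                 network = out$population$network,
                 ledger = out$ledger,
                 trace = out$trace,
                 config = config,
                 seed = as.integer(seed)),
            class = "ratchetr_result")
}

#' @export
print.ratchetr_result <- function(x, ...) {
  s <- ledger_summaries(x)
  cat(sprintf("ratchetr simulation (scenario %s, %d rounds, seed %d)\n",
              x$config$scenario, x$config$rounds, x$seed))
  cat(sprintf("  max stage reached: %d; crossover levels: %d\n",
              s$max_stage, s$crossover_levels))
  cat(sprintf("  tools ever: %d; tools in final population: %d\n",
              s$tools_ever, s$tools_final))
  cat(sprintf("  between-group links: %d\n", nrow(x$network$between)))
  invisible(x)
}
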